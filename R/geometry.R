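#' Convert FRET efficiency to donor-acceptor distance
#'
#' `R = R0 * (1/E - 1)^(1/6)`, with `R0` the Foerster radius (the distance at
#' which E = 0.5).
#'
#' @param E FRET efficiency, strictly inside (0, 1).
#' @param R0_nm Foerster radius in nm (default 5.1).
#' @return Distance in nm (unrounded; see [round_distance()]).
#' @examples
#' fret_to_distance(0.5, 5.1)    # = R0
#' fret_to_distance(0.781, 5.1)  # ~4.1 nm
#' @export
fret_to_distance <- function(E, R0_nm = 5.1) {
  stopifnot(all(E > 0 & E < 1), R0_nm > 0)
  R0_nm * (1 / E - 1)^(1 / 6)
}

#' @rdname fret_to_distance
#' @param distance_nm Donor-acceptor distance in nm.
#' @export
distance_to_fret <- function(distance_nm, R0_nm = 5.1) {
  stopifnot(all(distance_nm > 0), R0_nm > 0)
  1 / (1 + (distance_nm / R0_nm)^6)
}

#' @rdname fret_to_distance
#' @param x Distance in nm.
#' @export
round_distance <- function(x) round_half_up(x, 1)

#' Sampling radius of a tethered substrate-binding domain
#'
#' A domain anchored to the membrane by a flexible linker can sample a
#' half-sphere whose radius is the domain radius plus the extended linker
#' length: a polypeptide backbone in its extended conformation spans about
#' 0.35 nm per residue, and the SBD radius is about 2 nm. The result is
#' reported half-up to one decimal.
#'
#' @param linker_residues Number of linker residues (>= 0).
#' @param per_residue_nm Extension per residue (nm).
#' @param sbd_radius_nm Radius of the tethered domain (nm).
#' @return Radius in nm, rounded half-up to one decimal.
#' @examples
#' tether_radius(11)  # 2 + 11 * 0.35 = 5.85 -> 5.9 nm
#' @export
tether_radius <- function(linker_residues, per_residue_nm = 0.35,
                          sbd_radius_nm = 2.0) {
  stopifnot(all(linker_residues >= 0), per_residue_nm > 0, sbd_radius_nm >= 0)
  round_half_up(sbd_radius_nm + linker_residues * per_residue_nm, 1)
}

#' Apparent local concentration of one molecule in its sampling volume
#'
#' One molecule confined to a half-sphere of radius `r` has apparent molar
#' concentration `c = 1 / (N_A * (2/3) pi r^3)`.
#'
#' @param radius_nm Sampling radius in nm (> 0).
#' @param shape `"half"` (default, half-sphere) or `"full"` sphere.
#' @return Concentration in mM.
#' @examples
#' halfsphere_concentration(5.9)  # ~3.9 mM, i.e. ~4 mM
#' @export
halfsphere_concentration <- function(radius_nm, shape = c("half", "full")) {
  shape <- match.arg(shape)
  stopifnot(all(radius_nm > 0))
  n_a <- 6.02214076e23
  frac <- if (shape == "half") 2 / 3 else 4 / 3
  vol_l <- frac * pi * radius_nm^3 * 1e-24  # 1 nm^3 = 1e-24 L
  1000 / (n_a * vol_l)
}

#' Steady-state fluorescence anisotropy
#'
#' `G = I_HV / I_HH` compensates the instrument's polarization-dependent
#' sensitivity; the anisotropy is
#' \deqn{r = (I_{VV} - G I_{VH}) / (I_{VV} + 2 G I_{VH}).}
#'
#' @param I_VV,I_VH,I_HV,I_HH Fluorescence intensities (vertical/horizontal
#'   excitation x emission), non-negative.
#' @return Tibble with columns `G` and `r`.
#' @examples
#' anisotropy(1, 1, 1, 1)  # isotropic: r = 0
#' @export
anisotropy <- function(I_VV, I_VH, I_HV, I_HH) {
  stopifnot(all(I_VV >= 0), all(I_VH >= 0), all(I_HV >= 0), all(I_HH >= 0))
  if (any(I_HH <= 0)) stop("I_HH must be positive", call. = FALSE)
  G <- I_HV / I_HH
  den <- I_VV + 2 * G * I_VH
  if (any(den <= 0)) stop("zero denominator in anisotropy", call. = FALSE)
  tibble::tibble(G = G, r = (I_VV - G * I_VH) / den)
}

#' Condition summary table
#'
#' Collects per-condition state summaries into a table with one row per
#' measurement condition: stoichiometry, FRET efficiency and relative dwell
#' abundance of the low- and high-FRET states, the two interconversion rate
#' constants, and the number of FRET dwells.
#'
#' @param summaries Named list of `state_summary` objects (names are the
#'   condition labels), as returned by [classify_states()] or found in a
#'   [run_pipeline()] result.
#' @return Tibble with columns `condition`, `S_low`, `E_low`, `pct_low`,
#'   `S_high`, `E_high`, `pct_high`, `k_LH_s`, `k_HL_s`, `n_fret_dwells`.
#' @export
summarize_conditions <- function(summaries) {
  stopifnot(length(summaries) >= 1, !is.null(names(summaries)))
  purrr::imap_dfr(summaries, function(sm, label) {
    st <- sm$states
    lo <- st[st$class == "fret_low", , drop = FALSE]
    hi <- st[st$class == "fret_high", , drop = FALSE]
    if (nrow(lo) != 1 || nrow(hi) != 1) {
      return(tibble::tibble(condition = label, S_low = NA_real_,
                            E_low = NA_real_, pct_low = NA_real_,
                            S_high = NA_real_, E_high = NA_real_,
                            pct_high = NA_real_, k_LH_s = NA_real_,
                            k_HL_s = NA_real_,
                            n_fret_dwells = sm$n_fret_dwells))
    }
    tibble::tibble(
      condition = label,
      S_low = lo$mean_S, E_low = lo$mean_E, pct_low = lo$pct_fret_dwells,
      S_high = hi$mean_S, E_high = hi$mean_E, pct_high = hi$pct_fret_dwells,
      k_LH_s = sm$rates[lo$state, hi$state],
      k_HL_s = sm$rates[hi$state, lo$state],
      n_fret_dwells = sm$n_fret_dwells
    )
  })
}
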