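#' Correction factor set
#'
#' Container for the standard smFRET correction factors: donor leakage into
#' the acceptor detection channel (`lk`), direct excitation of the acceptor by
#' the donor laser (`dir`), the detection/quantum-yield imbalance between the
#' two channels (`gamma`), and the excitation imbalance (`beta`, applied to
#' the acceptor-excitation counts in the stoichiometry; defaults to 1).
#'
#' @param lk Donor leakage fraction, `>= 0`.
#' @param dir Acceptor direct-excitation fraction, `>= 0`.
#' @param gamma Gamma factor, `> 0`.
#' @param beta Beta factor, `> 0`.
#' @return A list of class `correction_set`.
#' @examples
#' correction_set()               # identity corrections
#' correction_set(lk = 0.05, dir = 0.08, gamma = 0.8)
#' @export
correction_set <- function(lk = 0, dir = 0, gamma = 1, beta = 1) {
  stopifnot(is.finite(lk), is.finite(dir), is.finite(gamma), is.finite(beta),
            lk >= 0, dir >= 0, gamma > 0, beta > 0)
  structure(list(lk = lk, dir = dir, gamma = gamma, beta = beta),
            class = "correction_set")
}

#' @export
print.correction_set <- function(x, ...) {
  cat(sprintf("<correction_set> lk = %.4g, dir = %.4g, gamma = %.4g, beta = %.4g\n",
              x$lk, x$dir, x$gamma, x$beta))
  invisible(x)
}

#' Apply correction factors to raw burst or dwell counts
#'
#' Given raw photon counts `F_DD` (donor excitation, donor emission), `F_DA`
#' (donor excitation, acceptor emission) and `F_AA` (acceptor excitation,
#' acceptor emission), the leakage- and direct-excitation-corrected acceptor
#' signal is
#' \deqn{F_{DA}^{cc} = F_{DA} - lk\,F_{DD} - dir\,F_{AA},}
#' and the corrected FRET efficiency and stoichiometry are
#' \deqn{E = F_{DA}^{cc} / (F_{DA}^{cc} + \gamma F_{DD}),\quad
#'       S = (F_{DA}^{cc} + \gamma F_{DD}) /
#'           (F_{DA}^{cc} + \gamma F_{DD} + F_{AA}/\beta).}
#' Negative corrected acceptor counts are clamped to zero and flagged.
#'
#' @param counts Data frame with columns `F_DD`, `F_DA`, `F_AA` (one row per
#'   burst or dwell); other columns are passed through.
#' @param corrections A [correction_set()].
#' @return The input tibble with columns `F_DA_cc`, `E_corr`, `S_corr`,
#'   `n_corr` (corrected total signal) and logical `clamped` added. Undefined
#'   ratios (zero denominators) yield `NA`, never silent `0/0`.
#' @examples
#' apply_corrections(
#'   tibble::tibble(F_DD = 80, F_DA = 28, F_AA = 100),
#'   correction_set(lk = 0.1, dir = 0.05, gamma = 1)
#' )
#' @export
apply_corrections <- function(counts, corrections = correction_set()) {
  stopifnot(all(c("F_DD", "F_DA", "F_AA") %in% names(counts)),
            inherits(corrections, "correction_set"))
  cc <- counts$F_DA - corrections$lk * counts$F_DD - corrections$dir * counts$F_AA
  clamped <- cc < 0
  cc[clamped] <- 0
  den <- cc + corrections$gamma * counts$F_DD
  tot <- den + counts$F_AA / corrections$beta
  out <- tibble::as_tibble(counts)
  out$F_DA_cc <- cc
  out$E_corr <- ifelse(den > 0, cc / den, NA_real_)
  out$S_corr <- ifelse(tot > 0, den / tot, NA_real_)
  out$n_corr <- tot
  out$clamped <- clamped
  out
}

#' Subtract expected background counts from burst counts
#'
#' Replaces the raw per-stream burst counts by background-corrected ones:
#' for each burst, the expected background contribution is the per-stream
#' rate of the background window containing the burst times the burst
#' duration. Corrected counts are clamped at zero. The raw counts are kept
#' in `F_DD_raw`, `F_DA_raw`, `F_AA_raw`. Used before pooling counts for
#' correction-factor estimation, where a few background photons per burst
#' otherwise bias the leakage/direct-excitation ratios upward.
#'
#' @param bursts Burst tibble with `start_tick`, `stop_tick` and raw counts.
#' @param bg A `bg_profile` from [estimate_background()].
#' @param clock_period Seconds per tick.
#' @return The tibble with `F_DD`, `F_DA`, `F_AA` background-corrected.
#' @export
subtract_background <- function(bursts, bg, clock_period = 25e-9) {
  stopifnot(all(c("start_tick", "stop_tick") %in% names(bursts)),
            inherits(bg, "bg_profile"))
  out <- tibble::as_tibble(bursts)
  if (nrow(out) == 0) return(out)
  dur_s <- (out$stop_tick - out$start_tick) * clock_period
  t0 <- out$start_tick * clock_period
  w <- pmin(findInterval(t0, c(bg$t_start_s, bg$t_end_s[nrow(bg)]),
                         rightmost.closed = TRUE), nrow(bg))
  out$F_DD_raw <- out$F_DD
  out$F_DA_raw <- out$F_DA
  out$F_AA_raw <- out$F_AA
  out$F_DD <- pmax(out$F_DD - bg$rate_DexDem[w] * dur_s, 0)
  out$F_DA <- pmax(out$F_DA - bg$rate_DexAem[w] * dur_s, 0)
  out$F_AA <- pmax(out$F_AA - bg$rate_AexAem[w] * dur_s, 0)
  out
}

#' Estimate donor leakage from a donor-only population
#'
#' Pools raw counts over the donor-only bursts (or dwells): with no acceptor
#' present, every photon detected in the acceptor channel during donor
#' excitation is leakage, so `lk = <E*>/(1 - <E*>) = sum(F_DA)/sum(F_DD)` on
#' the pooled counts.
#'
#' @param donor_only Data frame of donor-only bursts/dwells with raw counts
#'   `F_DD`, `F_DA`.
#' @param min_n Minimum population size required (default 50).
#' @return Leakage factor `lk`.
#' @export
estimate_leakage <- function(donor_only, min_n = 50) {
  if (is.null(donor_only) || nrow(donor_only) == 0) {
    stop("empty donor-only population", call. = FALSE)
  }
  if (nrow(donor_only) < min_n) {
    warning("donor-only population has only ", nrow(donor_only),
            " members (< ", min_n, "); leakage estimate may be unstable")
  }
  fdd <- sum(donor_only$F_DD)
  fda <- sum(donor_only$F_DA)
  if (fdd <= 0) stop("donor-only population has no DexDem photons", call. = FALSE)
  fda / fdd
}

#' Estimate acceptor direct excitation from an acceptor-only population
#'
#' With no donor present, every photon in the acceptor channel during donor
#' excitation is direct excitation: `dir = sum(F_DA)/sum(F_AA)` pooled over
#' the acceptor-only population.
#'
#' @param acceptor_only Data frame of acceptor-only bursts/dwells with raw
#'   counts `F_DA`, `F_AA`.
#' @param min_n Minimum population size required (default 50).
#' @return Direct-excitation factor `dir`.
#' @export
estimate_direct_excitation <- function(acceptor_only, min_n = 50) {
  if (is.null(acceptor_only) || nrow(acceptor_only) == 0) {
    stop("empty acceptor-only population", call. = FALSE)
  }
  if (nrow(acceptor_only) < min_n) {
    warning("acceptor-only population has only ", nrow(acceptor_only),
            " members (< ", min_n, "); direct-excitation estimate may be unstable")
  }
  faa <- sum(acceptor_only$F_AA)
  if (faa <= 0) stop("acceptor-only population has no AexAem photons", call. = FALSE)
  sum(acceptor_only$F_DA) / faa
}

#' Estimate gamma (and beta) from two FRET-state centroids
#'
#' After leakage and direct-excitation correction, the centroids of the two
#' FRET states fall on the line `1/S = Omega + Sigma * E`. Fitting that line
#' through exactly the two centroids gives
#' `gamma = (Omega - 1) / (Omega + Sigma - 1)` and
#' `beta = Omega + Sigma - 1`.
#'
#' @param centroids Data frame with two rows and columns `E`, `S`: the
#'   leakage/direct-excitation-corrected (but not yet gamma-corrected)
#'   centroids of the two FRET states.
#' @return A list with `gamma` and `beta`.
#' @examples
#' estimate_gamma(tibble::tibble(E = c(0.2, 0.75), S = c(0.5, 0.5)))
#' @export
estimate_gamma <- function(centroids) {
  if (is.null(centroids) || nrow(centroids) != 2) {
    stop("gamma estimation needs exactly two FRET-state centroids, got ",
         if (is.null(centroids)) 0 else nrow(centroids), call. = FALSE)
  }
  E <- centroids$E
  S <- centroids$S
  if (any(!is.finite(E)) || any(!is.finite(S)) || any(S <= 0)) {
    stop("non-finite or non-positive centroid coordinates", call. = FALSE)
  }
  if (abs(E[1] - E[2]) < 1e-9) {
    stop("degenerate centroids: identical E values", call. = FALSE)
  }
  sig <- (1 / S[2] - 1 / S[1]) / (E[2] - E[1])
  omg <- 1 / S[1] - sig * E[1]
  beta <- omg + sig - 1
  gamma <- (omg - 1) / beta
  if (!is.finite(gamma) || gamma <= 0) {
    stop("gamma estimate is not positive; centroids inconsistent with the E-S line",
         call. = FALSE)
  }
  list(gamma = gamma, beta = beta)
}
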