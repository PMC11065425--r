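#' Estimate the background rate in fixed time windows
#'
#' The background is estimated as a simple count/duration rate over
#' consecutive windows (default 30 s) tiling the acquisition, per photon
#' stream and in total. The final partial window uses its actual duration.
#'
#' @param stream A [photon_stream()].
#' @param window_s Window length in seconds (default 30).
#' @return A tibble of class `bg_profile` with one row per window: `window`,
#'   `t_start_s`, `t_end_s`, `rate_DexDem`, `rate_DexAem`, `rate_AexAem`,
#'   `rate_total` (Hz).
#' @export
estimate_background <- function(stream, window_s = 30) {
  stopifnot(inherits(stream, "photon_stream"))
  dur <- stream_duration(stream)
  if (dur <= 0) stop("zero-duration stream", call. = FALSE)
  edges <- seq(0, dur, by = window_s)
  if (edges[length(edges)] < dur) edges <- c(edges, dur)
  n_win <- length(edges) - 1L
  t_s <- stream$timestamp * clock_period(stream)
  win <- pmin(findInterval(t_s, edges, rightmost.closed = TRUE), n_win)
  widths <- diff(edges)
  counts <- matrix(0, n_win, 3)
  if (nrow(stream)) {
    tab <- table(factor(win, levels = seq_len(n_win)),
                 factor(stream$stream, levels = STREAM_CODES))
    counts <- matrix(as.integer(tab), n_win, 3)
  }
  out <- tibble::tibble(
    window = seq_len(n_win),
    t_start_s = edges[-length(edges)],
    t_end_s = edges[-1],
    rate_DexDem = counts[, 1] / widths,
    rate_DexAem = counts[, 2] / widths,
    rate_AexAem = counts[, 3] / widths
  )
  out$rate_total <- out$rate_DexDem + out$rate_DexAem + out$rate_AexAem
  attr(out, "window_s") <- window_s
  class(out) <- c("bg_profile", class(out))
  out
}

#' All-photon burst search (APBS)
#'
#' Slides a window of `m` consecutive photons over the stream; a window
#' starting at photon *i* qualifies when its local photon rate,
#' `m / (t[i+m-1] - t[i])`, is at least `F` times the total background rate of
#' the 30 s background window containing photon *i* (inclusive comparison).
#' Overlapping qualifying windows are merged into bursts; any non-qualifying
#' gap separates bursts. Raw counts, apparent FRET efficiency `E_star` and
#' stoichiometry `S` are computed over all photons of each burst via
#' [burst_metrics()].
#'
#' @param stream A [photon_stream()].
#' @param bg A `bg_profile` from [estimate_background()]; computed on the fly
#'   when `NULL`.
#' @param m Number of consecutive photons per sliding window (default 10).
#' @param F Rate threshold as a multiple of the background rate (default 6).
#' @return A tibble of bursts: `burst_id`, `i_start`, `i_end` (1-based photon
#'   indexes, inclusive), `start_tick`, `stop_tick`, `n_photons`, `F_DD`,
#'   `F_DA`, `F_AA`, `E_star`, `S`. Empty tibble when nothing qualifies.
#' @export
search_bursts <- function(stream, bg = NULL, m = 10, F = 6) {
  stopifnot(inherits(stream, "photon_stream"), m >= 2, F > 0)
  if (is.null(bg)) bg <- estimate_background(stream)
  n <- nrow(stream)
  empty <- tibble::tibble(
    burst_id = integer(), i_start = integer(), i_end = integer(),
    start_tick = double(), stop_tick = double(), n_photons = integer(),
    F_DD = integer(), F_DA = integer(), F_AA = integer(),
    E_star = double(), S = double()
  )
  if (n < m) return(empty)
  ts <- stream$timestamp
  cp <- clock_period(stream)
  t_s <- ts * cp

  i <- seq_len(n - m + 1L)
  span_s <- (ts[i + m - 1L] - ts[i]) * cp
  rate <- ifelse(span_s > 0, m / span_s, Inf)
  win <- pmin(findInterval(t_s[i], c(bg$t_start_s, bg$t_end_s[nrow(bg)]),
                           rightmost.closed = TRUE), nrow(bg))
  qualifies <- rate >= F * bg$rate_total[win]

  q <- which(qualifies)
  if (!length(q)) return(empty)
  # qualifying windows i and j (i < j) overlap iff j <= i + m - 1
  new_burst <- c(TRUE, diff(q) > m - 1L)
  grp <- cumsum(new_burst)
  i_start <- tapply(q, grp, min)
  i_end <- tapply(q, grp, max) + m - 1L

  res <- purrr::map_dfr(seq_along(i_start), function(b) {
    lo <- as.integer(i_start[[b]])
    hi <- as.integer(i_end[[b]])
    st <- stream$stream[lo:hi]
    tibble::tibble(
      i_start = lo, i_end = hi,
      start_tick = ts[lo], stop_tick = ts[hi],
      n_photons = hi - lo + 1L,
      F_DD = sum(st == 0L), F_DA = sum(st == 1L), F_AA = sum(st == 2L)
    )
  })
  res <- dplyr::bind_cols(tibble::tibble(burst_id = seq_len(nrow(res))), res)
  burst_metrics(res)
}

#' Apparent FRET efficiency and stoichiometry from raw counts
#'
#' Adds `E_star = F_DA / (F_DA + F_DD)` and
#' `S = (F_DA + F_DD) / (F_DA + F_DD + F_AA)` to a table of raw burst or
#' dwell counts. Undefined ratios (zero denominator) are returned as `NA`.
#'
#' @param counts Data frame with columns `F_DD`, `F_DA`, `F_AA`.
#' @return The input as a tibble with `E_star` and `S` columns added/replaced.
#' @examples
#' burst_metrics(tibble::tibble(F_DD = 25, F_DA = 75, F_AA = 100))
#' @export
burst_metrics <- function(counts) {
  stopifnot(all(c("F_DD", "F_DA", "F_AA") %in% names(counts)))
  out <- tibble::as_tibble(counts)
  dex <- out$F_DD + out$F_DA
  tot <- dex + out$F_AA
  out$E_star <- ifelse(dex > 0, out$F_DA / dex, NA_real_)
  out$S <- ifelse(tot > 0, dex / tot, NA_real_)
  out
}

#' Select bursts by minimum photon count
#'
#' Keeps bursts with at least `min_photons` photons, counting all detected
#' photons during both excitation periods. With `use_corrected = TRUE` the
#' corrected total signal (`n_corr` from [apply_corrections()]) is thresholded
#' instead, implementing the re-selection pass with the same cut-off applied
#' to corrected counts.
#'
#' @param bursts Burst tibble from [search_bursts()].
#' @param min_photons Minimum photons per burst (default 35).
#' @param use_corrected Threshold the corrected total signal instead of the
#'   raw photon count.
#' @return The surviving bursts, order preserved.
#' @export
select_bursts <- function(bursts, min_photons = 35, use_corrected = FALSE) {
  if (nrow(bursts) == 0) return(bursts)
  n <- if (use_corrected) {
    stopifnot("n_corr" %in% names(bursts))
    bursts$n_corr
  } else {
    bursts$n_photons
  }
  bursts[n >= min_photons, , drop = FALSE]
}

#' Partition bursts into FRET, donor-only and acceptor-only populations
#'
#' Doubly labeled molecules have intermediate raw stoichiometry; molecules
#' carrying only a donor appear at S ~ 1 and only an acceptor at S ~ 0. The
#' donor-only and acceptor-only partitions are retained for correction-factor
#' estimation.
#'
#' @param bursts Burst tibble with an `S` column.
#' @param s_low,s_high Raw-S thresholds: `S < s_low` is acceptor-only,
#'   `S > s_high` donor-only, the closed interval in between is FRET.
#' @param use_corrected Partition on the corrected stoichiometry `S_corr`
#'   (from [apply_corrections()]) instead of raw `S`.
#' @return Named list of tibbles `fret`, `donor_only`, `acceptor_only`.
#' @export
filter_species <- function(bursts, s_low = 0.2, s_high = 0.8,
                           use_corrected = FALSE) {
  s_col <- if (use_corrected) "S_corr" else "S"
  stopifnot(s_col %in% names(bursts))
  s <- bursts[[s_col]]
  list(
    fret = bursts[!is.na(s) & s >= s_low & s <= s_high, , drop = FALSE],
    donor_only = bursts[!is.na(s) & s > s_high, , drop = FALSE],
    acceptor_only = bursts[!is.na(s) & s < s_low, , drop = FALSE]
  )
}

#' Extract the per-photon records of a set of bursts
#'
#' Produces the photon-level table consumed by the photon-by-photon HMM and
#' by burst variance analysis: one row per photon inside a burst, with the
#' parent burst id.
#'
#' @param stream A [photon_stream()].
#' @param bursts Burst tibble from [search_bursts()] (columns `burst_id`,
#'   `i_start`, `i_end`).
#' @return Tibble `burst_id`, `timestamp`, `stream` of class `burst_photons`
#'   with the stream's `clock_period` attribute.
#' @export
burst_photons <- function(stream, bursts) {
  stopifnot(inherits(stream, "photon_stream"),
            all(c("burst_id", "i_start", "i_end") %in% names(bursts)))
  out <- purrr::map_dfr(seq_len(nrow(bursts)), function(b) {
    idx <- bursts$i_start[b]:bursts$i_end[b]
    tibble::tibble(burst_id = bursts$burst_id[b],
                   timestamp = stream$timestamp[idx],
                   stream = stream$stream[idx])
  })
  attr(out, "clock_period") <- clock_period(stream)
  class(out) <- c("burst_photons", class(out))
  out
}
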