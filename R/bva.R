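#' Expected shot-noise standard deviation of windowed FRET efficiency
#'
#' In the absence of within-burst dynamics, the FRET efficiency of a window
#' of `n` donor-excitation photons is binomial, so its standard deviation is
#' `sqrt(E (1 - E) / n)`.
#'
#' @param E_mean Mean FRET efficiency, in `[0, 1]`.
#' @param n Photons per window.
#' @return The expected standard deviation.
#' @examples
#' expected_std(0.5, 5)
#' @export
expected_std <- function(E_mean, n) {
  stopifnot(all(E_mean >= 0 & E_mean <= 1), n >= 1)
  sqrt(E_mean * (1 - E_mean) / n)
}

#' Burst variance analysis (BVA)
#'
#' Detects within-burst dynamics by comparing the spread of FRET efficiency
#' inside each burst against the shot-noise expectation. Each burst is cut
#' into consecutive non-overlapping windows of `n` donor-excitation photons
#' (DexDem + DexAem); the burst's mean FRET efficiency is plotted against the
#' standard deviation of the window values, and the data are binned at 0.1 E.
#' Bursts with fewer than two complete windows are skipped (and counted).
#' Deviation of the binned standard deviation above the expected
#' `sqrt(E(1-E)/n)` curve indicates dynamics; the comparison is qualitative.
#'
#' @param photons A `burst_photons` tibble (see [burst_photons()]).
#' @param n Donor-excitation photons per window (default 5).
#' @param corrections Optional [correction_set()]; when supplied, each
#'   window's efficiency is the corrected E of the window's raw counts
#'   (donor-excitation windows carry no AexAem photons, so the
#'   direct-excitation term is inactive within windows). `NULL` uses raw E*.
#' @return Object of class `bva_result`: list with `bursts` (tibble
#'   `burst_id`, `E_mean`, `sigma`, `n_windows`), `bins` (tibble
#'   `bin_center`, `mean_E`, `mean_sigma`, `se_sigma`, `n_bursts`,
#'   `sigma_shot`), `n`, `n_skipped`.
#' @export
burst_variance <- function(photons, n = 5, corrections = NULL) {
  stopifnot(all(c("burst_id", "stream") %in% names(photons)), n >= 1)
  dex <- photons[photons$stream %in% c(0L, 1L), , drop = FALSE]
  per_burst <- dex |>
    dplyr::group_by(.data$burst_id) |>
    dplyr::group_modify(function(df, key) {
      n_win <- nrow(df) %/% n
      if (n_win < 2) {
        return(tibble::tibble(E_mean = NA_real_, sigma = NA_real_,
                              n_windows = n_win))
      }
      win <- rep(seq_len(n_win), each = n)
      acc <- df$stream[seq_len(n_win * n)] == 1L
      f_da <- tapply(acc, win, sum)
      e_win <- if (is.null(corrections)) {
        f_da / n
      } else {
        apply_corrections(
          tibble::tibble(F_DD = n - f_da, F_DA = f_da, F_AA = 0),
          corrections
        )$E_corr
      }
      tibble::tibble(E_mean = mean(e_win), sigma = sd(e_win),
                     n_windows = n_win)
    }) |>
    dplyr::ungroup()
  n_skipped <- sum(is.na(per_burst$sigma))
  bursts <- per_burst[!is.na(per_burst$sigma), , drop = FALSE]

  breaks <- seq(0, 1, by = 0.1)
  bin <- cut(pmin(pmax(bursts$E_mean, 0), 1 - 1e-12), breaks,
             include.lowest = TRUE, labels = FALSE)
  bins <- tibble::tibble(E_mean = bursts$E_mean, sigma = bursts$sigma,
                         bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_E = mean(.data$E_mean),
                     mean_sigma = mean(.data$sigma),
                     se_sigma = sd(.data$sigma) / sqrt(dplyr::n()),
                     n_bursts = dplyr::n(), .groups = "drop")
  bins$bin_center <- breaks[bins$bin] + 0.05
  bins$sigma_shot <- expected_std(pmin(pmax(bins$mean_E, 0), 1), n)
  bins <- bins[, c("bin_center", "mean_E", "mean_sigma", "se_sigma",
                   "n_bursts", "sigma_shot")]
  structure(list(bursts = bursts, bins = bins, n = n,
                 n_skipped = n_skipped),
            class = "bva_result")
}

#' @export
print.bva_result <- function(x, ...) {
  cat("<bva_result>", nrow(x$bursts), "bursts (", x$n_skipped,
      "skipped ), window n =", x$n, "\n")
  print(x$bins)
  invisible(x)
}

#' @rdname burst_variance
#' @param x A `bva_result`.
#' @param ... Unused.
#' @export
tidy.bva_result <- function(x, ...) x$bins

#' @rdname burst_variance
#' @param object A `bva_result`.
#' @export
autoplot.bva_result <- function(object, ...) {
  curve <- tibble::tibble(E = seq(0.001, 0.999, length.out = 200))
  curve$sigma <- expected_std(curve$E, object$n)
  ggplot2::ggplot(object$bursts,
                  ggplot2::aes(x = .data$E_mean, y = .data$sigma)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$E, y = .data$sigma),
                       linetype = "dotted") +
    ggplot2::geom_point(data = object$bins,
                        ggplot2::aes(x = .data$mean_E, y = .data$mean_sigma),
                        shape = 15, size = 2.5) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "mean E per burst", y = expression(sigma(E)),
                  title = "Burst variance analysis") +
    ggplot2::theme_minimal()
}
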