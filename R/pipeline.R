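#' Pipeline settings
#'
#' Bundles every threshold and tuning parameter of [run_pipeline()] so a run
#' is fully described by (stream, settings).
#'
#' @param m,F All-photon burst search window size and rate threshold.
#' @param bg_window_s Background estimation window (s).
#' @param min_photons Burst selection cut-off, applied to raw counts in the
#'   first selection and to corrected counts in the re-selection.
#' @param s_low,s_high Stoichiometry thresholds separating acceptor-only /
#'   FRET / donor-only bursts (and classifying H2MM states).
#' @param k_range State counts fitted during model selection.
#' @param n_starts EM starts per K.
#' @param seed Seed for the jittered EM starts.
#' @param tol,max_iter EM convergence controls.
#' @param bva_n Donor-excitation photons per BVA window.
#' @return A list of class `pipeline_settings`.
#' @export
pipeline_settings <- function(m = 10, F = 6, bg_window_s = 30,
                              min_photons = 35, s_low = 0.2, s_high = 0.8,
                              k_range = 1:5, n_starts = 2, seed = 1,
                              tol = 1e-6, max_iter = 300, bva_n = 5) {
  structure(list(m = m, F = F, bg_window_s = bg_window_s,
                 min_photons = min_photons, s_low = s_low, s_high = s_high,
                 k_range = k_range, n_starts = n_starts, seed = seed,
                 tol = tol, max_iter = max_iter, bva_n = bva_n),
            class = "pipeline_settings")
}

#' Run the full burst analysis pipeline
#'
#' Orchestrates the three-pass procedure:
#' \enumerate{
#'   \item Background estimation, all-photon burst search, selection of
#'     bursts with at least `min_photons` raw photons, and partitioning into
#'     FRET / donor-only / acceptor-only populations on raw stoichiometry.
#'   \item Photon-by-photon HMM with ICL model selection on the FRET bursts;
#'     leakage from the donor-only bursts, direct excitation from the
#'     acceptor-only bursts, then gamma (and beta) from the two FRET-state
#'     dwell centroids after leakage/direct-excitation correction.
#'   \item Burst re-selection with the same cut-offs applied to fully
#'     corrected counts, a fresh model selection (warm-started from the
#'     first-pass fits), Viterbi dwell segmentation, corrected dwell E/S,
#'     state classification with transition rates, and burst variance
#'     analysis of the corrected FRET bursts.
#' }
#' Deterministic given the settings seed.
#'
#' @param stream A [photon_stream()].
#' @param settings A [pipeline_settings()].
#' @return Object of class `fret_pipeline`: list with `background`, `bursts`
#'   (all found bursts), `species` (pass-1 partition), `corrections`
#'   ([correction_set()]), `selection` (final [h2mm_select()] result),
#'   `dwells` (corrected dwell tibble), `summary` ([classify_states()]
#'   result), `bva` ([burst_variance()] result), `log` (stage messages),
#'   `settings`.
#' @export
run_pipeline <- function(stream, settings = pipeline_settings()) {
  stopifnot(inherits(stream, "photon_stream"),
            inherits(settings, "pipeline_settings"))
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  bg <- stage("background", estimate_background(stream, settings$bg_window_s))
  note("background: ", nrow(bg), " windows, mean total rate ",
       round(mean(bg$rate_total), 1), " Hz")

  bursts <- stage("burst search",
                  search_bursts(stream, bg, m = settings$m, F = settings$F))
  note("burst search (m=", settings$m, ", F=", settings$F, "): ",
       nrow(bursts), " bursts")

  sel1 <- stage("selection", select_bursts(bursts, settings$min_photons))
  note("selection >=", settings$min_photons, " photons: ", nrow(sel1),
       " bursts")

  sp <- stage("species filter",
              filter_species(sel1, settings$s_low, settings$s_high))
  note("species: ", nrow(sp$fret), " FRET, ", nrow(sp$donor_only),
       " donor-only, ", nrow(sp$acceptor_only), " acceptor-only")

  lk <- stage("leakage",
              estimate_leakage(subtract_background(sp$donor_only, bg)))
  dir <- stage("direct excitation",
               estimate_direct_excitation(
                 subtract_background(sp$acceptor_only, bg)))
  note("leakage = ", signif(lk, 4), ", direct excitation = ", signif(dir, 4))

  ph1 <- stage("burst photons", burst_photons(stream, sp$fret))
  sel_pass1 <- stage("mpH2MM pass 1",
                     h2mm_select(ph1, k_range = settings$k_range,
                                 n_starts = settings$n_starts,
                                 seed = settings$seed, tol = settings$tol,
                                 max_iter = settings$max_iter))
  note("pass-1 model selection: chose K = ", sel_pass1$chosen_K)

  vit1 <- h2mm_viterbi(ph1, sel_pass1$model)
  dwells1 <- apply_corrections(vit1$dwells, correction_set(lk, dir, gamma = 1))
  cls1 <- classify_states(sel_pass1$model, dwells1,
                          s_low = settings$s_low, s_high = settings$s_high)
  fret1 <- cls1$states[startsWith(cls1$states$class, "fret"), , drop = FALSE]
  # gamma centroids from photon-pooled per-state counts: pooling weights the
  # long, reliably classified dwells and avoids the small-dwell ratio bias
  pooled <- vit1$dwells |>
    dplyr::filter(.data$state %in% fret1$state) |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(F_DD = sum(.data$F_DD), F_DA = sum(.data$F_DA),
                     F_AA = sum(.data$F_AA), .groups = "drop") |>
    apply_corrections(correction_set(lk, dir, gamma = 1))
  gb <- if (nrow(fret1) == 2) {
    tryCatch(
      estimate_gamma(tibble::tibble(E = pooled$E_corr, S = pooled$S_corr)),
      error = function(e) {
        note("gamma estimation failed (", conditionMessage(e),
             "); using gamma = beta = 1")
        list(gamma = 1, beta = 1)
      }
    )
  } else {
    note("found ", nrow(fret1),
         " FRET state(s) in pass 1; gamma estimation needs 2, using ",
         "gamma = beta = 1")
    list(gamma = 1, beta = 1)
  }
  corrections <- correction_set(lk, dir, gamma = gb$gamma, beta = gb$beta)
  note("corrections: gamma = ", signif(gb$gamma, 4), ", beta = ",
       signif(gb$beta, 4))

  # pass 2: re-selection on corrected counts, same cut-offs
  bursts_cc <- apply_corrections(bursts, corrections)
  sel2 <- stage("re-selection",
                select_bursts(bursts_cc, settings$min_photons,
                              use_corrected = TRUE))
  sp2 <- stage("species re-filter",
               filter_species(sel2, settings$s_low, settings$s_high,
                              use_corrected = TRUE))
  note("re-selection on corrected counts: ", nrow(sp2$fret), " FRET bursts")

  ph2 <- stage("burst photons pass 2", burst_photons(stream, sp2$fret))
  sel_pass2 <- stage("mpH2MM pass 2",
                     h2mm_select(ph2, k_range = settings$k_range,
                                 n_starts = settings$n_starts,
                                 seed = settings$seed + 1L,
                                 tol = settings$tol,
                                 max_iter = settings$max_iter,
                                 init_models = sel_pass1$models))
  note("pass-2 model selection: chose K = ", sel_pass2$chosen_K)

  vit2 <- h2mm_viterbi(ph2, sel_pass2$model)
  dwells2 <- apply_corrections(vit2$dwells, corrections)
  summary <- classify_states(sel_pass2$model, dwells2,
                             s_low = settings$s_low, s_high = settings$s_high)
  note("final states: ",
       paste(summary$states$class, collapse = ", "))

  bva <- stage("BVA", burst_variance(ph2, n = settings$bva_n,
                                     corrections = corrections))

  structure(list(background = bg, bursts = bursts, species = sp,
                 corrections = corrections,
                 selection_pass1 = sel_pass1,
                 selection = sel_pass2,
                 dwells = dwells2, summary = summary, bva = bva,
                 log = log, settings = settings),
            class = "fret_pipeline")
}

#' @export
print.fret_pipeline <- function(x, ...) {
  cat("<fret_pipeline>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `fret_pipeline`.
#' @param ... Unused.
#' @export
tidy.fret_pipeline <- function(x, ...) x$summary$states

#' @rdname run_pipeline
#' @export
glance.fret_pipeline <- function(x, ...) {
  tibble::tibble(
    n_bursts = nrow(x$bursts),
    chosen_K = x$selection$chosen_K,
    lk = x$corrections$lk, dir = x$corrections$dir,
    gamma = x$corrections$gamma, beta = x$corrections$beta,
    n_fret_dwells = x$summary$n_fret_dwells
  )
}

#' Plot the corrected dwell E-S scatter of a pipeline result
#'
#' @param object A `fret_pipeline`.
#' @param ... Unused.
#' @export
autoplot.fret_pipeline <- function(object, ...) {
  d <- object$dwells
  cls <- object$summary$states[, c("state", "class")]
  d <- dplyr::left_join(d, cls, by = "state")
  cent <- object$summary$states
  ggplot2::ggplot(d, ggplot2::aes(x = .data$E_corr, y = .data$S_corr,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(data = cent,
                        ggplot2::aes(x = .data$mean_E, y = .data$mean_S),
                        colour = "black", size = 2.5) +
    ggplot2::coord_cartesian(xlim = c(-0.1, 1.1), ylim = c(-0.1, 1.1)) +
    ggplot2::labs(x = "corrected E", y = "corrected S", colour = "state",
                  title = "Corrected dwells") +
    ggplot2::theme_minimal()
}
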