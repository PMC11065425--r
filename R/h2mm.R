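#' Photon-by-photon hidden Markov model
#'
#' The hidden conformational chain is parameterized in discrete time on the
#' sync clock: `trans` is the K x K transition matrix per clock tick (25 ns at
#' a 40 MHz pulse rate), and between photons separated by a gap of `delta`
#' ticks the effective operator is `trans^delta`. Each state emits photons
#' over the three detection streams (DexDem, DexAem, AexAem) according to its
#' row of `emit`.
#'
#' @param prior Length-K initial state distribution.
#' @param trans K x K row-stochastic per-tick transition matrix.
#' @param emit K x 3 row-stochastic emission matrix over the streams.
#' @param clock_period Seconds per tick.
#' @param loglik,n_iter,converged Fit metadata (filled by [h2mm_fit()]).
#' @return An object of class `h2mm_model`.
#' @export
h2mm_model <- function(prior, trans, emit, clock_period = 25e-9,
                       loglik = NA_real_, n_iter = 0L, converged = NA) {
  K <- length(prior)
  trans <- as.matrix(trans)
  emit <- as.matrix(emit)
  stopifnot(nrow(trans) == K, ncol(trans) == K,
            nrow(emit) == K, ncol(emit) == 3,
            all(prior >= 0), all(trans >= 0), all(emit >= 0))
  prior <- prior / sum(prior)
  trans <- trans / rowSums(trans)
  emit <- emit / rowSums(emit)
  stopifnot(all(abs(rowSums(trans) - 1) < 1e-12),
            all(abs(rowSums(emit) - 1) < 1e-12),
            abs(sum(prior) - 1) < 1e-12)
  structure(list(K = K, prior = prior, trans = trans, emit = emit,
                 clock_period = clock_period, loglik = loglik,
                 n_iter = n_iter, converged = converged),
            class = "h2mm_model")
}

#' @export
print.h2mm_model <- function(x, ...) {
  cat("<h2mm_model> K =", x$K, "states, loglik =",
      format(x$loglik, digits = 8),
      if (isTRUE(x$converged)) "(converged)" else
        if (isFALSE(x$converged)) "(NOT converged)" else "", "\n")
  print(tidy(x))
  invisible(x)
}

# photons -> flat arrays for the C++ core
h2mm_prepare <- function(photons) {
  stopifnot(all(c("burst_id", "timestamp", "stream") %in% names(photons)))
  ids <- photons$burst_id
  new_burst <- c(TRUE, ids[-1] != ids[-length(ids)])
  delta <- c(0, diff(photons$timestamp))
  delta[new_burst] <- 0
  if (any(delta < 0)) {
    stop("timestamps must be non-decreasing within bursts", call. = FALSE)
  }
  offsets <- c(which(new_burst) - 1L, length(ids))
  list(delta = as.double(delta), obs = as.integer(photons$stream),
       offsets = as.integer(offsets),
       burst_ids = ids[new_burst])
}

#' Log-likelihood of burst photon data under an H2MM model
#'
#' Scaled forward algorithm with exact tick-resolved transition operators
#' (`trans^delta` between photons).
#'
#' @param photons A `burst_photons` tibble (see [burst_photons()]).
#' @param model An [h2mm_model()].
#' @return Total log-likelihood over all bursts.
#' @export
h2mm_loglik <- function(photons, model) {
  d <- h2mm_prepare(photons)
  cpp_h2mm_loglik(model$prior, model$trans, model$emit,
                  d$delta, d$obs, d$offsets)
}

#' Per-photon posterior state probabilities
#'
#' @inheritParams h2mm_loglik
#' @return List with `loglik` and `gamma`, an N x K matrix of posteriors
#'   (rows sum to 1).
#' @export
h2mm_posteriors <- function(photons, model) {
  d <- h2mm_prepare(photons)
  cpp_h2mm_posteriors(model$prior, model$trans, model$emit,
                      d$delta, d$obs, d$offsets)
}

# deterministic emission-row targets (E*, S) per K: two FRET states plus
# donor-only / acceptor-only style states as K grows, then extra mid-E states
h2mm_init_targets <- function(K) {
  base <- list(c(0.5, 0.55), c(0.2, 0.55), c(0.7, 0.55), c(0.05, 0.95),
               c(0.9, 0.05), c(0.45, 0.55), c(0.85, 0.55), c(0.3, 0.55))
  targets <- if (K == 1) base[1] else base[seq(2, K + 1)]
  do.call(rbind, lapply(targets, function(es) {
    E <- es[1]; S <- es[2]
    c(S * (1 - E), S * E, 1 - S)
  }))
}

#' Deterministic (optionally jittered) starting model
#'
#' Emission rows are built from a fixed grid of apparent (E, S) targets per
#' K; the per-tick transition matrix starts at a uniform 100 s^-1 exchange
#' rate. Jittered starts multiply emission entries by a log-normal factor.
#'
#' @param K Number of states.
#' @param clock_period Seconds per tick.
#' @param jitter_sd Log-normal jitter applied to emission rows (0 = none).
#' @return An [h2mm_model()].
#' @export
h2mm_init <- function(K, clock_period = 25e-9, jitter_sd = 0) {
  stopifnot(K >= 1, K <= 8)
  B <- h2mm_init_targets(K)
  if (jitter_sd > 0) {
    B <- B * exp(matrix(rnorm(K * 3, 0, jitter_sd), K, 3))
    B <- B / rowSums(B)
  }
  rate_tick <- 100 * clock_period
  A <- matrix(rate_tick, K, K)
  diag(A) <- 0
  diag(A) <- 1 - rowSums(A)
  h2mm_model(rep(1 / K, K), A, B, clock_period = clock_period)
}

#' Fit an H2MM model by expectation-maximization
#'
#' Exact EM for the tick-parameterized photon HMM: the E-step runs the scaled
#' forward-backward recursion with `trans^delta` gap operators and
#' accumulates interval-resolved expected transition counts over every
#' unobserved tick inside each inter-photon gap (closed form via the spectral
#' decomposition of `trans`); the M-step is the usual normalization. The
#' log-likelihood is non-decreasing across iterations; optimization stops
#' when the improvement drops below `tol` or after `max_iter` iterations (in
#' which case the model is returned with `converged = FALSE`, never an
#' error).
#'
#' @inheritParams h2mm_loglik
#' @param model0 Starting [h2mm_model()]; default is the deterministic
#'   [h2mm_init()] for `K`.
#' @param K Number of states (used when `model0` is `NULL`).
#' @param tol Absolute log-likelihood improvement below which EM stops.
#' @param max_iter Maximum EM iterations.
#' @return The fitted [h2mm_model()] with `loglik`, `n_iter`, `converged`.
#' @export
h2mm_fit <- function(photons, model0 = NULL, K = NULL, tol = 1e-7,
                     max_iter = 1000) {
  if (is.null(model0)) {
    stopifnot(!is.null(K))
    cp <- attr(photons, "clock_period")
    if (is.null(cp)) cp <- 25e-9
    model0 <- h2mm_init(K, clock_period = cp)
  }
  d <- h2mm_prepare(photons)
  cur <- model0
  ll_prev <- NULL
  prev <- NULL
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- cpp_h2mm_em_step(cur$prior, cur$trans, cur$emit,
                             d$delta, d$obs, d$offsets)
    ll <- step$loglik
    if (!is.null(ll_prev)) {
      if (ll < ll_prev - 1e-8 * (1 + abs(ll_prev))) {
        warning("log-likelihood decreased at iteration ", iter,
                "; returning previous model")
        cur <- prev
        ll <- ll_prev
        break
      }
      if (ll - ll_prev < tol) {
        converged <- TRUE
        break
      }
    }
    ll_prev <- ll
    prev <- cur
    cur <- h2mm_model(step$prior, step$trans, step$emit,
                      clock_period = cur$clock_period)
  }
  if (!converged && iter >= max_iter) {
    # last parameter update was never scored; score it now
    ll <- cpp_h2mm_loglik(cur$prior, cur$trans, cur$emit,
                          d$delta, d$obs, d$offsets)
  }
  cur$loglik <- ll
  cur$n_iter <- iter
  cur$converged <- converged
  cur
}

#' Viterbi state paths and dwell segmentation
#'
#' Computes, per burst, the jointly most probable hidden-state sequence at
#' the photon times (transition weight `trans^delta` between photons; ties
#' broken toward the lower state index), then cuts each burst into dwells:
#' maximal runs of constant Viterbi state. Dwell boundaries between states
#' are placed at the midpoint of the separating inter-photon gap; burst-edge
#' boundaries at the edge photons. Each dwell gets a position class: `whole`
#' if it spans the burst, otherwise `initial`, `mid` or `terminal`.
#'
#' @inheritParams h2mm_loglik
#' @return List with:
#'   \describe{
#'     \item{path}{the photon tibble plus a `state` column;}
#'     \item{dwells}{tibble `burst_id`, `dwell_id`, `state`, `n_photons`,
#'       `F_DD`, `F_DA`, `F_AA`, `duration_ticks`, `duration_ms`,
#'       `position`, `E_star`, `S`;}
#'     \item{logprob}{per-burst joint log-probability of the Viterbi path.}
#'   }
#' @export
h2mm_viterbi <- function(photons, model) {
  d <- h2mm_prepare(photons)
  vit <- cpp_h2mm_viterbi(model$prior, model$trans, model$emit,
                          d$delta, d$obs, d$offsets)
  path <- tibble::as_tibble(photons)
  path$state <- as.integer(vit$states)

  # vectorized dwell extraction: a dwell is a maximal run of constant state
  # within one burst
  n <- nrow(path)
  new_burst <- c(TRUE, path$burst_id[-1] != path$burst_id[-n])
  new_run <- new_burst | c(TRUE, path$state[-1] != path$state[-n])
  run_id <- cumsum(new_run)
  starts <- which(new_run)
  ends <- c(starts[-1] - 1L, n)
  ts <- path$timestamp
  burst_first <- new_burst[starts]
  burst_last <- c(burst_first[-1], TRUE)
  left <- ifelse(burst_first, ts[starts], (ts[starts] + ts[pmax(starts - 1L, 1L)]) / 2)
  right <- ifelse(burst_last, ts[ends], (ts[ends] + ts[pmin(ends + 1L, n)]) / 2)
  position <- dplyr::case_when(
    burst_first & burst_last ~ "whole",
    burst_first ~ "initial",
    burst_last ~ "terminal",
    TRUE ~ "mid"
  )
  f <- factor(run_id, levels = seq_along(starts))
  dwells <- tibble::tibble(
    burst_id = path$burst_id[starts],
    dwell_id = as.integer(stats::ave(run_id[starts], path$burst_id[starts],
                                     FUN = seq_along)),
    state = path$state[starts],
    n_photons = ends - starts + 1L,
    F_DD = as.integer(tapply(path$stream == 0L, f, sum)),
    F_DA = as.integer(tapply(path$stream == 1L, f, sum)),
    F_AA = as.integer(tapply(path$stream == 2L, f, sum)),
    duration_ticks = right - left,
    position = position
  )
  dwells$duration_ms <- dwells$duration_ticks * model$clock_period * 1e3
  dwells <- burst_metrics(dwells)
  list(path = path, dwells = dwells, logprob = as.double(vit$logprob))
}

# Viterbi joint log-probability only (no dwell table); used by model scoring.
h2mm_viterbi_logprob <- function(d, model) {
  vit <- cpp_h2mm_viterbi(model$prior, model$trans, model$emit,
                          d$delta, d$obs, d$offsets)
  list(states = as.integer(vit$states), logprob = as.double(vit$logprob))
}

#' Fit and compare H2MM models over a range of state counts
#'
#' Fits each K with a deterministic grid start plus `n_starts - 1` seeded
#' jittered starts, keeping the best final log-likelihood (ties go to the
#' earliest start). Model comparison uses
#' `BIC = -2 loglik + d_K log N` with `d_K = (K-1) + K(K-1) + 2K` free
#' parameters, the integrated complete likelihood
#' `ICL = -2 log P(photons, Viterbi path) + d_K log N`, and the relative
#' improvement `BIC' = (BIC(K-1) - BIC(K)) / BIC(K-1)` as a diagnostic. The
#' adopted model is the one with the lowest ICL.
#'
#' @inheritParams h2mm_fit
#' @param k_range Integer vector of state counts to fit.
#' @param n_starts Starts per K (1 = deterministic grid start only).
#' @param seed Seed for the jittered starts.
#' @param init_models Optional named list (by K) of warm-start models added
#'   to the start set.
#' @return An object of class `h2mm_selection`: list with `table` (per-K
#'   tibble of `K`, `loglik`, `df`, `BIC`, `ICL`, `BIC_prime`, `converged`),
#'   `models`, `chosen_K`, `model` (the adopted fit), `criterion = "ICL"`.
#' @export
h2mm_select <- function(photons, k_range = 1:6, n_starts = 3, seed = 1,
                        tol = 1e-7, max_iter = 1000, init_models = NULL) {
  stopifnot(nrow(photons) > 0)
  cp <- attr(photons, "clock_period")
  if (is.null(cp)) cp <- 25e-9
  n_photons <- nrow(photons)
  dat <- h2mm_prepare(photons)
  models <- list()
  rows <- purrr::map_dfr(k_range, function(K) {
    starts <- list(h2mm_init(K, clock_period = cp))
    if (n_starts > 1) {
      for (j in seq_len(n_starts - 1)) {
        set.seed(seed + 1000L * K + j)
        starts <- c(starts, list(h2mm_init(K, clock_period = cp,
                                           jitter_sd = 0.35)))
      }
    }
    if (!is.null(init_models) && !is.null(init_models[[as.character(K)]])) {
      starts <- c(list(init_models[[as.character(K)]]), starts)
    }
    fits <- lapply(starts, function(m0) {
      h2mm_fit(photons, model0 = m0, tol = tol, max_iter = max_iter)
    })
    lls <- vapply(fits, function(f) f$loglik, numeric(1))
    best <- fits[[which.max(lls)]]
    vit <- h2mm_viterbi_logprob(dat, best)
    occupied <- length(unique(vit$states))
    d <- (K - 1) + K * (K - 1) + 2 * K
    bic <- -2 * best$loglik + d * log(n_photons)
    icl <- -2 * sum(vit$logprob) + d * log(n_photons)
    models[[as.character(K)]] <<- best
    tibble::tibble(K = K, loglik = best$loglik, df = d, BIC = bic, ICL = icl,
                   converged = best$converged,
                   degenerate = occupied < K)
  })
  rows$BIC_prime <- c(NA_real_,
                      if (nrow(rows) > 1)
                        (head(rows$BIC, -1) - tail(rows$BIC, -1)) /
                          head(rows$BIC, -1))
  chosen <- rows$K[which.min(rows$ICL)]
  structure(list(table = rows, models = models,
                 chosen_K = chosen,
                 model = models[[as.character(chosen)]],
                 criterion = "ICL"),
            class = "h2mm_selection")
}

#' @export
print.h2mm_selection <- function(x, ...) {
  cat("<h2mm_selection> chosen K =", x$chosen_K, "(lowest ICL)\n")
  print(x$table)
  invisible(x)
}

#' Convert a fitted per-tick transition matrix to rates in s^-1
#'
#' `k_ij = A_ij / clock_period` for the off-diagonal entries (valid when
#' `A_ij << 1`, i.e. rates far below the tick rate); the diagonal holds minus
#' the row sums.
#'
#' @param model A fitted [h2mm_model()].
#' @return K x K matrix of rates (s^-1).
#' @export
transition_rates <- function(model) {
  A <- model$trans
  off <- A[row(A) != col(A)]
  if (any(off > 1e-3)) {
    warning("some per-tick transition probabilities exceed 1e-3; ",
            "the rate approximation k = A/delta is degraded")
  }
  k <- A / model$clock_period
  diag(k) <- 0
  diag(k) <- -rowSums(k)
  k
}

#' Classify H2MM states and summarize the FRET kinetics
#'
#' States are classified from their dwell-averaged corrected stoichiometry:
#' the state with the highest mean S is donor-only if its mean S exceeds
#' `s_high`, the lowest is acceptor-only if below `s_low`; the remaining
#' states are genuine FRET states ranked by corrected E (`fret_low`,
#' `fret_high`). Donor-only and acceptor-only dwells are excluded from the
#' relative-abundance percentages, which are computed over FRET dwells only,
#' and from downstream kinetics.
#'
#' @param model Fitted [h2mm_model()].
#' @param dwells Dwell tibble from [h2mm_viterbi()], already corrected with
#'   [apply_corrections()] (columns `E_corr`, `S_corr`).
#' @param s_low,s_high Classification thresholds on mean corrected S.
#' @return Object of class `state_summary`: list with `states` (tibble
#'   `state`, `class`, `mean_E`, `mean_S`, `n_dwells`, `pct_fret_dwells`),
#'   `rates` (K x K s^-1 from the fitted transition matrix), `n_fret_dwells`.
#' @export
classify_states <- function(model, dwells, s_low = 0.2, s_high = 0.8) {
  stopifnot(all(c("E_corr", "S_corr", "state") %in% names(dwells)))
  per_state <- dwells |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(mean_E = mean(.data$E_corr, na.rm = TRUE),
                     mean_S = mean(.data$S_corr, na.rm = TRUE),
                     n_dwells = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$state)
  K <- model$K
  cls <- rep(NA_character_, nrow(per_state))
  s <- per_state$mean_S
  i_max <- which.max(s)
  i_min <- which.min(s)
  if (s[i_max] > s_high) cls[i_max] <- "donor_only"
  if (i_min != i_max && s[i_min] < s_low) cls[i_min] <- "acceptor_only"
  fret_idx <- which(is.na(cls))
  if (length(fret_idx) == 0) {
    warning("no FRET state identified")
  } else if (length(fret_idx) == 1) {
    cls[fret_idx] <- "fret"
  } else if (length(fret_idx) == 2) {
    e <- per_state$mean_E[fret_idx]
    cls[fret_idx[order(e)]] <- c("fret_low", "fret_high")
  } else {
    e <- per_state$mean_E[fret_idx]
    cls[fret_idx[order(e)]] <- paste0("fret_", seq_along(fret_idx))
  }
  per_state$class <- cls
  is_fret <- startsWith(per_state$class, "fret")
  n_fret <- sum(per_state$n_dwells[is_fret])
  per_state$pct_fret_dwells <- ifelse(
    is_fret, 100 * per_state$n_dwells / n_fret, NA_real_)
  structure(list(states = per_state[, c("state", "class", "mean_E", "mean_S",
                                        "n_dwells", "pct_fret_dwells")],
                 rates = transition_rates(model),
                 fret_states = per_state$state[is_fret],
                 n_fret_dwells = n_fret),
            class = "state_summary")
}

#' @export
print.state_summary <- function(x, ...) {
  cat("<state_summary>", x$n_fret_dwells, "FRET dwells\n")
  print(x$states)
  cat("rates (s^-1):\n")
  print(round(x$rates, 1))
  invisible(x)
}

#' Dwell-based transition rate cross-check
#'
#' For each FRET state, the exit rate estimated as the reciprocal of the mean
#' duration of its `mid` dwells (dwells truncated by the burst edges are
#' excluded). Provided as a cross-check on the rates derived from the fitted
#' transition matrix.
#'
#' @param dwells Dwell tibble from [h2mm_viterbi()].
#' @param states Optional state indexes to include.
#' @return Tibble `state`, `n_mid_dwells`, `mean_duration_ms`,
#'   `exit_rate_s` (s^-1).
#' @export
dwell_rates <- function(dwells, states = NULL) {
  d <- dwells[dwells$position == "mid", , drop = FALSE]
  if (!is.null(states)) d <- d[d$state %in% states, , drop = FALSE]
  d |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(n_mid_dwells = dplyr::n(),
                     mean_duration_ms = mean(.data$duration_ms),
                     exit_rate_s = 1000 / mean(.data$duration_ms),
                     .groups = "drop")
}

#' @rdname h2mm_model
#' @param x An `h2mm_model`.
#' @param ... Unused.
#' @export
tidy.h2mm_model <- function(x, ...) {
  B <- x$emit
  dex <- B[, 1] + B[, 2]
  tibble::tibble(
    state = seq_len(x$K),
    prior = x$prior,
    p_DexDem = B[, 1], p_DexAem = B[, 2], p_AexAem = B[, 3],
    E_star = ifelse(dex > 0, B[, 2] / dex, NA_real_),
    S = dex
  )
}

#' @rdname h2mm_model
#' @export
glance.h2mm_model <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged)
}

#' @rdname h2mm_select
#' @param x An `h2mm_selection`.
#' @param ... Unused.
#' @export
tidy.h2mm_selection <- function(x, ...) x$table

#' @rdname h2mm_select
#' @export
glance.h2mm_selection <- function(x, ...) {
  tibble::tibble(chosen_K = x$chosen_K, criterion = x$criterion,
                 ICL = x$table$ICL[x$table$K == x$chosen_K])
}

#' @rdname h2mm_select
#' @param object An `h2mm_selection`.
#' @export
autoplot.h2mm_selection <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$ICL)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$K == object$chosen_K, , drop = FALSE],
                        colour = "red", shape = 8, size = 3) +
    ggplot2::labs(x = "number of states K", y = "ICL",
                  title = "Model selection (lowest ICL adopted)") +
    ggplot2::theme_minimal()
}

#' @rdname classify_states
#' @param x A `state_summary`.
#' @param ... Unused.
#' @export
tidy.state_summary <- function(x, ...) x$states
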