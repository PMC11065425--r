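#' Simulation configuration for synthetic smFRET photon streams
#'
#' Defines the generative model used throughout the test suite: single
#' molecules diffuse through the confocal volume producing millisecond photon
#' bursts (top-hat intensity profile, exponential transit duration) on top of
#' per-stream Poisson background; doubly labeled molecules carry a hidden
#' conformational state alternating between FRET levels with first-order
#' kinetics; donor-only and acceptor-only species and within-burst
#' photobleaching/blinking produce the S~1 / S~0 populations; instrument
#' distortions (leakage, direct excitation, gamma, beta) are applied to the
#' per-photon stream probabilities as the exact algebraic inverse of
#' [apply_corrections()], so the correction round-trip is an identity in
#' expectation.
#'
#' Defaults emulate the high-ionic-strength measurement condition: two FRET
#' states at corrected E 0.18 and 0.63 interconverting at 42 s^-1 (low to
#' high) and 173 s^-1 (high to low).
#'
#' @param seed Integer master seed; every stochastic stage derives from it.
#' @param duration_s Acquisition length (s).
#' @param burst_rate_hz Molecule transits per second (Poisson).
#' @param transit_ms_mean Mean transit duration (ms, exponential).
#' @param peak_rate_khz Total signal photon rate during a transit (kHz).
#' @param dex_fraction Expected fraction of a doubly labeled molecule's signal
#'   emitted during the donor excitation period; sets the designed raw
#'   stoichiometry.
#' @param species_fractions Named numeric, fractions of `doubly`,
#'   `donor_only`, `acceptor_only` molecules; must sum to 1.
#' @param states Numeric vector of true (corrected) FRET efficiencies of the
#'   hidden states, each in (0, 1).
#' @param rate_matrix_s K x K first-order interconversion rate matrix in
#'   s^-1; off-diagonals are the rates, diagonal is ignored (recomputed as
#'   minus the row sum).
#' @param bleach_rate_s Rate (s^-1) of irreversible within-burst transition of
#'   a doubly labeled molecule to a donor-only or acceptor-only emission
#'   regime (blinking/photobleaching); the lost fluorophore is chosen with
#'   equal probability.
#' @param corrections_true A [correction_set()] applied as the forward
#'   distortion.
#' @param background_hz Named per-stream Poisson background rates (Hz).
#' @param clock_period Seconds per clock tick.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 60,
                       burst_rate_hz = 5,
                       transit_ms_mean = 3,
                       peak_rate_khz = 50,
                       dex_fraction = 0.5,
                       species_fractions = c(doubly = 0.7, donor_only = 0.2,
                                             acceptor_only = 0.1),
                       states = c(0.18, 0.63),
                       rate_matrix_s = matrix(c(0, 42, 173, 0), 2, 2,
                                              byrow = TRUE),
                       bleach_rate_s = 50,
                       corrections_true = correction_set(),
                       background_hz = c(DexDem = 600, DexAem = 400,
                                         AexAem = 500),
                       clock_period = 25e-9) {
  species_fractions <- species_fractions[c("doubly", "donor_only", "acceptor_only")]
  stopifnot(
    !anyNA(species_fractions),
    abs(sum(species_fractions) - 1) < 1e-9,
    all(states > 0), all(states < 1),
    is.matrix(rate_matrix_s),
    nrow(rate_matrix_s) == length(states),
    ncol(rate_matrix_s) == length(states),
    bleach_rate_s >= 0,
    all(background_hz >= 0),
    duration_s > 0, burst_rate_hz >= 0, transit_ms_mean > 0,
    peak_rate_khz > 0, dex_fraction > 0, dex_fraction < 1,
    inherits(corrections_true, "correction_set")
  )
  off <- rate_matrix_s[row(rate_matrix_s) != col(rate_matrix_s)]
  if (any(off < 0)) stop("off-diagonal rates must be >= 0", call. = FALSE)
  structure(list(
    seed = as.integer(seed), duration_s = duration_s,
    burst_rate_hz = burst_rate_hz, transit_ms_mean = transit_ms_mean,
    peak_rate_khz = peak_rate_khz, dex_fraction = dex_fraction,
    species_fractions = species_fractions, states = states,
    rate_matrix_s = rate_matrix_s, bleach_rate_s = bleach_rate_s,
    corrections_true = corrections_true, background_hz = background_hz,
    clock_period = clock_period
  ), class = "sim_config")
}

# Per-photon stream probabilities (DexDem, DexAem, AexAem) for a molecule in
# a state with true FRET E and designed stoichiometry S, under the forward
# distortion of `cor`. Constructed as the algebraic inverse of
# apply_corrections(): corrected totals are fixed at F_DA_cc = S*E,
# gamma*F_DD = S*(1-E), F_AA/beta = 1-S, then the raw counts are recovered
# and normalised.
stream_probs <- function(E, S, cor = correction_set()) {
  f_dd <- S * (1 - E) / cor$gamma
  f_aa <- cor$beta * (1 - S)
  f_da <- S * E + cor$lk * f_dd + cor$dir * f_aa
  p <- c(f_dd, f_da, f_aa)
  p / sum(p)
}

# Stream probabilities of donor-only and acceptor-only emitters.
stream_probs_do <- function(cor) {
  p <- c(1, cor$lk, 0)
  p / sum(p)
}
stream_probs_ao <- function(cor) {
  p <- c(0, cor$dir, 1)
  p / sum(p)
}

ctmc_stationary <- function(rate_matrix_s) {
  K <- nrow(rate_matrix_s)
  if (K == 1) return(1)
  Q <- rate_matrix_s
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # solve pi Q = 0, sum(pi) = 1
  A <- rbind(t(Q), rep(1, K))
  b <- c(rep(0, K), 1)
  pi <- qr.solve(A, b)
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Simulate a continuous-time Markov chain trajectory (Gillespie)
#'
#' Exact stochastic simulation of the hidden conformational kinetics: holding
#' times are exponential with the state's total exit rate, jump targets drawn
#' proportionally to the off-diagonal rates.
#'
#' @param rate_matrix_s K x K rate matrix (s^-1); off-diagonals are the
#'   rates. A zero matrix yields a single dwell over the whole duration.
#' @param duration_s Trajectory length in seconds.
#' @param initial_state Starting state index (1-based), or `NULL` to draw
#'   from the stationary distribution.
#' @param seed Optional seed (integer); if `NULL` the current RNG state is
#'   used.
#' @return A tibble with columns `state`, `t_start`, `t_end` (seconds),
#'   covering `[0, duration_s]` exactly.
#' @export
simulate_ctmc <- function(rate_matrix_s, duration_s, initial_state = NULL,
                          seed = NULL) {
  stopifnot(is.matrix(rate_matrix_s),
            nrow(rate_matrix_s) == ncol(rate_matrix_s),
            duration_s > 0)
  off <- rate_matrix_s[row(rate_matrix_s) != col(rate_matrix_s)]
  if (any(off < 0)) stop("off-diagonal rates must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(rate_matrix_s)
  Q <- rate_matrix_s
  diag(Q) <- 0
  exit <- rowSums(Q)
  s <- if (is.null(initial_state)) {
    sample.int(K, 1, prob = ctmc_stationary(rate_matrix_s))
  } else {
    as.integer(initial_state)
  }
  stopifnot(s >= 1, s <= K)
  states <- integer(0); starts <- double(0)
  t <- 0
  repeat {
    states <- c(states, s)
    starts <- c(starts, t)
    if (exit[s] <= 0) break
    t <- t + rexp(1, exit[s])
    if (t >= duration_s) break
    s <- sample.int(K, 1, prob = Q[s, ])
  }
  tibble::tibble(
    state = states,
    t_start = starts,
    t_end = c(starts[-1], duration_s)
  )
}

#' Emit photons for one molecule transit
#'
#' Photon arrivals are a Poisson process at the configured peak signal rate
#' over the trajectory's duration; each photon's stream is drawn from the
#' state's distorted stream probabilities (see [sim_config()]).
#'
#' @param trajectory Tibble from [simulate_ctmc()]; state indexes refer to
#'   `config$states` for doubly labeled molecules. States may also carry the
#'   labels `"donor_only"`/`"acceptor_only"` (as negative codes -1/-2) for
#'   bleached segments.
#' @param config A [sim_config()].
#' @param species One of `"doubly"`, `"donor_only"`, `"acceptor_only"`.
#' @param seed Optional seed.
#' @return Tibble with columns `time_s`, `stream`, `state` (state index for
#'   FRET states, `-1` donor-only, `-2` acceptor-only).
#' @export
emit_photons <- function(trajectory, config, species = "doubly", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  duration <- max(trajectory$t_end)
  n <- rpois(1, config$peak_rate_khz * 1000 * duration)
  if (n == 0) {
    return(tibble::tibble(time_s = double(), stream = integer(),
                          state = integer()))
  }
  tt <- sort(runif(n, 0, duration))
  idx <- findInterval(tt, trajectory$t_start)
  st <- trajectory$state[idx]
  cor <- config$corrections_true
  probs <- switch(species,
    doubly = {
      P <- rbind(
        stream_probs_ao(cor),                       # -2 acceptor-only
        stream_probs_do(cor),                       # -1 donor-only
        t(vapply(config$states, function(E) {
          stream_probs(E, config$dex_fraction, cor)
        }, numeric(3)))
      )
      P[ifelse(st < 0, st + 3L, st + 2L), , drop = FALSE]
    },
    donor_only = matrix(stream_probs_do(cor), n, 3, byrow = TRUE),
    acceptor_only = matrix(stream_probs_ao(cor), n, 3, byrow = TRUE),
    stop("unknown species: ", species)
  )
  if (species != "doubly") st <- rep(if (species == "donor_only") -1L else -2L, n)
  u <- runif(n)
  cum1 <- probs[, 1]
  cum2 <- probs[, 1] + probs[, 2]
  stream <- ifelse(u < cum1, 0L, ifelse(u < cum2, 1L, 2L))
  tibble::tibble(time_s = tt, stream = as.integer(stream), state = as.integer(st))
}

#' Simulate a full smFRET acquisition with ground truth
#'
#' Places molecule transits by a Poisson process over the acquisition, runs
#' the hidden-state kinetics (plus one-way bleaching/blinking) within each
#' transit, emits signal photons with distorted stream probabilities, fills
#' the acquisition with per-stream Poisson background, and returns both the
#' photon stream and the full ground truth. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{stream}{a [photon_stream()] of the whole acquisition;}
#'     \item{bursts}{tibble of true transits: `burst_id`, `species`,
#'       `t_start_s`, `t_end_s`, `start_tick`, `stop_tick`, `overlaps`
#'       (logical: transit overlaps another transit);}
#'     \item{photons}{tibble aligned row-for-row with `stream`: `burst_id`
#'       (`NA` for background photons) and `state` (FRET state index, `-1`
#'       donor-only, `-2` acceptor-only, `NA` background).}
#'   }
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- length(config$states)

  # burst layout
  set.seed(config$seed)
  n_bursts <- rpois(1, config$burst_rate_hz * config$duration_s)
  t0 <- sort(runif(n_bursts, 0, config$duration_s))
  dur <- rexp(n_bursts, 1000 / config$transit_ms_mean)
  dur <- pmin(dur, config$duration_s - t0)
  dur <- pmax(dur, 1e-6)
  species <- sample(names(config$species_fractions), n_bursts, replace = TRUE,
                    prob = config$species_fractions)

  # background photons
  set.seed(config$seed + 1L)
  bg <- purrr::map2_dfr(STREAM_CODES, as.double(config$background_hz), function(code, rate) {
    nb <- rpois(1, rate * config$duration_s)
    tibble::tibble(time_s = runif(nb, 0, config$duration_s),
                   stream = rep(code, nb),
                   state = rep(NA_integer_, nb),
                   burst_id = rep(NA_integer_, nb))
  })

  # per-burst photons
  set.seed(config$seed + 2L)
  burst_ph <- purrr::map_dfr(seq_len(n_bursts), function(i) {
    ph <- if (species[i] == "doubly") {
      traj <- simulate_ctmc(config$rate_matrix_s, dur[i])
      if (config$bleach_rate_s > 0) {
        t_bleach <- rexp(1, config$bleach_rate_s)
        if (t_bleach < dur[i]) {
          to <- if (runif(1) < 0.5) -1L else -2L  # acceptor / donor lost
          traj <- traj[traj$t_start < t_bleach, , drop = FALSE]
          traj$t_end[nrow(traj)] <- t_bleach
          traj <- dplyr::bind_rows(
            traj,
            tibble::tibble(state = to, t_start = t_bleach, t_end = dur[i])
          )
        }
      }
      emit_photons(traj, config, "doubly")
    } else {
      traj <- tibble::tibble(state = 1L, t_start = 0, t_end = dur[i])
      emit_photons(traj, config, species[i])
    }
    ph$time_s <- ph$time_s + t0[i]
    ph$burst_id <- i
    ph
  })

  all_ph <- dplyr::bind_rows(bg, burst_ph)
  all_ph$tick <- round(all_ph$time_s / config$clock_period)
  ord <- order(all_ph$tick)
  all_ph <- all_ph[ord, ]

  stream <- photon_stream(all_ph$tick, all_ph$stream,
                          clock_period = config$clock_period,
                          duration_s = config$duration_s)

  t1 <- t0 + dur
  overlaps <- vapply(seq_len(n_bursts), function(i) {
    any(t0 < t1[i] & t1 > t0[i] & seq_len(n_bursts) != i)
  }, logical(1))

  bursts <- tibble::tibble(
    burst_id = seq_len(n_bursts),
    species = species,
    t_start_s = t0,
    t_end_s = t1,
    start_tick = round(t0 / config$clock_period),
    stop_tick = round(t1 / config$clock_period),
    overlaps = overlaps
  )

  list(
    stream = stream,
    bursts = bursts,
    photons = tibble::tibble(burst_id = all_ph$burst_id,
                             state = all_ph$state)
  )
}
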