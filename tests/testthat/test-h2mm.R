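ref_model_2 <- function() {
  h2mm_model(
    prior = c(0.6, 0.4),
    trans = matrix(c(0.92, 0.08, 0.15, 0.85), 2, 2, byrow = TRUE),
    emit = matrix(c(0.6, 0.3, 0.1, 0.1, 0.5, 0.4), 2, 3, byrow = TRUE)
  )
}

test_that("K = 1 log-likelihood is the closed-form emission sum", {
  B <- matrix(c(0.5, 0.3, 0.2), 1, 3)
  m <- h2mm_model(1, matrix(1, 1, 1), B)
  obs <- c(0L, 1L, 1L, 2L, 0L)
  ph <- make_burst_photons(1L, c(0, 100, 250, 251, 900), obs)
  expect_equal(h2mm_loglik(ph, m), sum(log(B[1, obs + 1])))
})

test_that("a frozen chain (prior (1,0), A = I) reduces to state-1 emissions", {
  B <- matrix(c(0.7, 0.2, 0.1, 0.1, 0.1, 0.8), 2, 3, byrow = TRUE)
  m <- h2mm_model(c(1, 0), diag(2), B)
  obs <- c(0L, 2L, 1L)
  ph <- make_burst_photons(1L, c(0, 7, 19), obs)
  expect_equal(h2mm_loglik(ph, m), sum(log(B[1, obs + 1])))
})

test_that("loglik, posteriors and E-step match exhaustive tick enumeration", {
  m <- ref_model_2()
  set.seed(51)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    ticks <- cumsum(c(0, sample(1:3, n - 1, replace = TRUE)))
    obs <- sample(0:2, n, replace = TRUE)
    ph <- make_burst_photons(1L, ticks, obs)
    or <- oracle_tick_enum(m$prior, m$trans, m$emit, ticks, obs)

    expect_equal(h2mm_loglik(ph, m), or$loglik, tolerance = 1e-12)
    post <- h2mm_posteriors(ph, m)
    expect_equal(max(abs(post$gamma - or$post)), 0, tolerance = 1e-10)
    expect_equal(rowSums(post$gamma), rep(1, n), tolerance = 1e-12)

    d <- fretburst:::h2mm_prepare(ph)
    st <- fretburst:::cpp_h2mm_em_step(m$prior, m$trans, m$emit,
                                       d$delta, d$obs, d$offsets)
    expect_equal(st$trans, or$xi / rowSums(or$xi), tolerance = 1e-10)
    expect_equal(as.vector(st$prior), or$pi_post, tolerance = 1e-10)
    expect_equal(st$emit, or$gamma_emit / rowSums(or$gamma_emit),
                 tolerance = 1e-9)
  }
})

test_that("Viterbi equals the exhaustive photon-skeleton argmax", {
  m <- ref_model_2()
  set.seed(52)
  for (rep in 1:5) {
    n <- sample(3:5, 1)
    ticks <- cumsum(c(0, sample(1:6, n - 1, replace = TRUE)))
    obs <- sample(0:2, n, replace = TRUE)
    ph <- make_burst_photons(1L, ticks, obs)
    v <- h2mm_viterbi(ph, m)
    or <- oracle_skeleton_viterbi(m$prior, m$trans, m$emit, ticks, obs)
    expect_equal(v$path$state, unname(or$path))
    expect_equal(v$logprob, or$logprob, tolerance = 1e-10)
    # the Viterbi path log-probability never exceeds the total loglik
    expect_lte(v$logprob, h2mm_loglik(ph, m) + 1e-12)
  }
})

test_that("near-deterministic emissions: Viterbi equals the tick-path argmax", {
  B <- matrix(c(0.98, 0.01, 0.01, 0.01, 0.01, 0.98), 2, 3, byrow = TRUE)
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  m <- h2mm_model(c(0.5, 0.5), A, B)
  ticks <- c(0, 2, 3, 6)
  obs <- c(0L, 0L, 2L, 2L)
  ph <- make_burst_photons(1L, ticks, obs)
  v <- h2mm_viterbi(ph, m)
  or <- oracle_tick_enum(m$prior, m$trans, m$emit, ticks, obs)
  expect_equal(v$path$state, unname(or$argmax_tick_path))
})

test_that("matrix powers via spectral decomposition match repeated products", {
  set.seed(53)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    A <- random_stochastic(K)
    d <- sample(1:64, 1)
    P_fast <- fretburst:::cpp_matpow(A, d)
    P_slow <- Reduce(`%*%`, replicate(d, A, simplify = FALSE))
    expect_equal(max(abs(P_fast - P_slow)), 0, tolerance = 1e-10)
  }
})

test_that("EM: K = 1 converges to the multinomial MLE in one step", {
  set.seed(54)
  obs <- sample(0:2, 400, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  ph <- make_burst_photons(rep(1:10, each = 40),
                           rep(cumsum(sample(1:50, 40, TRUE)), 10), obs)
  m <- h2mm_fit(ph, K = 1)
  expect_equal(as.vector(m$emit), tabulate(obs + 1L, 3) / 400,
               tolerance = 1e-9)
  expect_true(m$converged)
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  set.seed(55)
  cfg <- sim_config(seed = 55, duration_s = 6)
  sim <- simulate_experiment(cfg)
  sp <- filter_species(select_bursts(search_bursts(sim$stream)))
  ph <- burst_photons(sim$stream, sp$fret)
  d <- fretburst:::h2mm_prepare(ph)
  m <- h2mm_init(2)
  lls <- numeric(0)
  for (i in 1:25) {
    st <- fretburst:::cpp_h2mm_em_step(m$prior, m$trans, m$emit,
                                       d$delta, d$obs, d$offsets)
    lls <- c(lls, st$loglik)
    m <- h2mm_model(st$prior, st$trans, st$emit, m$clock_period)
  }
  expect_true(all(diff(lls) >= -1e-8 * (1 + abs(lls[-length(lls)]))))
})

test_that("dwell segmentation yields spans, durations and position classes", {
  # engineered near-deterministic model so the Viterbi path is [1,1,2,2,2]
  B <- matrix(c(0.99, 0.005, 0.005, 0.005, 0.99, 0.005), 2, 3, byrow = TRUE)
  A <- matrix(c(0.999, 0.001, 0.001, 0.999), 2, 2, byrow = TRUE)
  m <- h2mm_model(c(0.5, 0.5), A, B)
  ph <- make_burst_photons(1L, c(0, 10, 20, 30, 40),
                           c(0L, 0L, 1L, 1L, 1L))
  v <- h2mm_viterbi(ph, m)
  expect_equal(v$path$state, c(1, 1, 2, 2, 2))
  expect_equal(v$dwells$state, c(1, 2))
  expect_equal(v$dwells$n_photons, c(2, 3))
  expect_equal(v$dwells$position, c("initial", "terminal"))
  # boundary at the midpoint of the separating gap
  expect_equal(v$dwells$duration_ticks, c(15, 25))

  # K = 1: a single whole-burst dwell
  m1 <- h2mm_model(1, matrix(1, 1, 1), matrix(c(0.4, 0.3, 0.3), 1, 3))
  v1 <- h2mm_viterbi(ph, m1)
  expect_equal(v1$dwells$position, "whole")
  expect_equal(v1$dwells$n_photons, 5)
})

test_that("transition rates convert per-tick probabilities to s^-1", {
  A <- matrix(c(1 - 4.325e-6, 4.325e-6, 2e-6, 1 - 2e-6), 2, 2, byrow = TRUE)
  m <- h2mm_model(c(0.5, 0.5), A, matrix(1 / 3, 2, 3))
  k <- transition_rates(m)
  expect_equal(k[1, 2], 173, tolerance = 1e-9)
  expect_equal(diag(k), -c(k[1, 2], k[2, 1]))

  m_id <- h2mm_model(c(0.5, 0.5), diag(2), matrix(1 / 3, 2, 3))
  expect_equal(max(abs(transition_rates(m_id))), 0)

  A_fast <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2, byrow = TRUE)
  m_fast <- h2mm_model(c(0.5, 0.5), A_fast, matrix(1 / 3, 2, 3))
  expect_warning(transition_rates(m_fast), "1e-3")
})

test_that("model selection: ICL equals BIC at K = 1 and picks K by ICL", {
  set.seed(56)
  cfg <- sim_config(seed = 56, duration_s = 20, states = c(0.4),
                    rate_matrix_s = matrix(0, 1, 1), bleach_rate_s = 0)
  sim <- simulate_experiment(cfg)
  sp <- filter_species(select_bursts(search_bursts(sim$stream)))
  ph <- burst_photons(sim$stream, sp$fret)
  sel <- h2mm_select(ph, k_range = 1:2, n_starts = 1, tol = 1e-5,
                     max_iter = 100)
  tab <- sel$table
  expect_equal(tab$ICL[tab$K == 1], tab$BIC[tab$K == 1], tolerance = 1e-8)
  expect_equal(sel$chosen_K, tab$K[which.min(tab$ICL)])
  expect_true(is.na(tab$BIC_prime[1]))
  expect_equal(tab$BIC_prime[2],
               (tab$BIC[1] - tab$BIC[2]) / tab$BIC[1])
  expect_s3_class(autoplot(sel), "ggplot")
})

test_that("state classification thresholds and dwell percentages", {
  m <- h2mm_model(rep(0.25, 4),
                  diag(4) * (1 - 3e-6) + 1e-6,
                  matrix(0.25, 4, 3) + cbind(rep(0.25, 4), 0, 0) * 0.1)
  dwells <- tibble::tibble(
    state = rep(1:4, c(100, 800, 200, 50)),
    E_corr = rep(c(NA, 0.2, 0.7, 0.9), c(100, 800, 200, 50)),
    S_corr = rep(c(0.05, 0.5, 0.51, 0.97), c(100, 800, 200, 50))
  )
  cls <- classify_states(m, dwells)
  st <- cls$states
  expect_equal(st$class, c("acceptor_only", "fret_low", "fret_high",
                           "donor_only"))
  expect_equal(st$pct_fret_dwells[2:3], c(80, 20))
  expect_equal(sum(st$pct_fret_dwells, na.rm = TRUE), 100, tolerance = 1e-9)
  expect_equal(cls$n_fret_dwells, 1000)
})

test_that("two-state parameter recovery at the study-condition kinetics", {
  # moderate-scale recovery: corrected state E within 0.03 of the truth
  cfg <- sim_config(seed = 57, duration_s = 90, bleach_rate_s = 0,
                    species_fractions = c(doubly = 1, donor_only = 0,
                                          acceptor_only = 0),
                    background_hz = c(DexDem = 0, DexAem = 0, AexAem = 0))
  sim <- simulate_experiment(cfg)
  sp <- filter_species(select_bursts(search_bursts(sim$stream)))
  ph <- burst_photons(sim$stream, sp$fret)
  m <- h2mm_fit(ph, K = 2, tol = 1e-6, max_iter = 300)
  td <- tidy(m)
  e_hat <- sort(td$E_star)
  expect_lt(abs(e_hat[1] - 0.18), 0.03)
  expect_lt(abs(e_hat[2] - 0.63), 0.03)
  k <- transition_rates(m)
  i_lo <- which.min(td$E_star); i_hi <- which.max(td$E_star)
  expect_lt(abs(k[i_lo, i_hi] - 42) / 42, 0.35)
  expect_lt(abs(k[i_hi, i_lo] - 173) / 173, 0.35)
})
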