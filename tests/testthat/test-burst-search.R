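test_that("background rates are count/duration per window", {
  # 3000 uniformly spaced photons in one 30 s window -> 100 Hz total
  ts <- seq(0, 30 - 0.01, length.out = 3000) / 25e-9
  ps <- photon_stream(round(ts), rep(0:2, 1000), duration_s = 30)
  bg <- estimate_background(ps)
  expect_equal(nrow(bg), 1)
  expect_equal(bg$rate_total, 100)

  # empty window has rate 0 and remains usable; final partial window uses
  # its actual duration
  ps2 <- photon_stream(round(c(1, 2) / 25e-9), c(0L, 1L), duration_s = 75)
  bg2 <- estimate_background(ps2)
  expect_equal(nrow(bg2), 3)
  expect_equal(bg2$rate_total, c(2 / 30, 0, 0))
  expect_equal(bg2$t_end_s[3] - bg2$t_start_s[3], 15)

  # Poisson 250 Hz, 10 windows: every estimate within 3 sigma
  set.seed(31)
  n <- rpois(1, 250 * 300)
  ps3 <- photon_stream(round(sort(runif(n, 0, 300)) / 25e-9),
                       sample(0:2, n, replace = TRUE), duration_s = 300)
  bg3 <- estimate_background(ps3)
  expect_true(all(abs(bg3$rate_total - 250) <= 3 * sqrt(250 * 30) / 30))
})

test_that("APBS finds an inserted high-rate cluster as exactly one burst", {
  set.seed(32)
  cp <- 25e-9
  bg_t <- seq(0.0005, 60, by = 0.001)     # steady 1 kHz background
  ins_t <- 30 + cumsum(rexp(50, 50000))   # 50 photons at ~50 kHz
  all_t <- sort(c(bg_t, ins_t))
  ps <- photon_stream(round(all_t / cp), sample(0:2, length(all_t), TRUE),
                      duration_s = 60)
  bursts <- search_bursts(ps, m = 10, F = 6)
  expect_equal(nrow(bursts), 1)
  ins_ticks <- round(ins_t / cp)
  expect_true(all(ins_ticks >= bursts$start_tick &
                    ins_ticks <= bursts$stop_tick))
  # edges may add at most m-1 background photons on each side
  expect_lte(bursts$n_photons, 50 + 2 * 9)
})

test_that("the rate criterion is inclusive at exactly F times background", {
  # 1 tick = 1 s; 6 photons over 30 s -> bg 0.2 Hz; F = 5 -> threshold 1 Hz;
  # the pair (6, 8) spans exactly 2 s: rate 1 Hz, equal to threshold
  ps <- photon_stream(c(0, 6, 8, 15, 22, 29), rep(0L, 6),
                      clock_period = 1, duration_s = 30)
  bursts <- search_bursts(ps, m = 2, F = 5)
  expect_equal(nrow(bursts), 1)
  expect_equal(bursts$start_tick, 6)
  expect_equal(bursts$stop_tick, 8)
})

test_that("APBS equals the brute-force oracle on simulated streams", {
  for (seed in c(41, 42)) {
    cfg <- sim_config(seed = seed, duration_s = 4)
    sim <- simulate_experiment(cfg)
    expect_lt(nrow(sim$stream), 1e4 + 5000)
    bg <- estimate_background(sim$stream)
    fast <- search_bursts(sim$stream, bg, m = 10, F = 6)
    slow <- oracle_apbs(sim$stream, bg, m = 10, F = 6)
    expect_equal(nrow(fast), length(slow))
    for (i in seq_along(slow)) {
      expect_equal(c(fast$i_start[i], fast$i_end[i]), unname(slow[[i]]))
    }
  }
})

test_that("raising F shrinks burst coverage; raising m thins the burst list", {
  cfg <- sim_config(seed = 43, duration_s = 10)
  sim <- simulate_experiment(cfg)
  bg <- estimate_background(sim$stream)
  covered <- function(bursts) {
    unlist(purrr::map2(bursts$i_start, bursts$i_end, seq))
  }
  cov_by_F <- lapply(c(4, 6, 9, 15), function(F)
    covered(search_bursts(sim$stream, bg, m = 10, F = F)))
  # the qualifying-window set is monotone in F, so coverage is nested
  # (burst *counts* can rise when neighbouring bursts split)
  for (i in 2:length(cov_by_F)) {
    expect_true(all(cov_by_F[[i]] %in% cov_by_F[[i - 1]]))
  }
  n_by_m <- sapply(c(5, 10, 20), function(m)
    nrow(search_bursts(sim$stream, bg, m = m, F = 6)))
  expect_true(all(diff(n_by_m) <= 0))
})

test_that("burst metrics implement the E*/S definitions with flagged NAs", {
  out <- burst_metrics(tibble::tibble(F_DD = c(25, 100, 50, 0),
                                      F_DA = c(75, 0, 50, 0),
                                      F_AA = c(100, 50, 0, 0)))
  expect_equal(out$E_star, c(0.75, 0, 0.5, NA))
  expect_equal(out$S, c(0.5, 2 / 3, 1, NA))
})

test_that("E* and S are invariant under a uniform time shift", {
  cfg <- sim_config(seed = 44, duration_s = 5)
  sim <- simulate_experiment(cfg)
  b1 <- search_bursts(sim$stream)
  # shift by one whole background window so the window alignment (and hence
  # the local background rates) is unchanged
  shift <- 30 / clock_period(sim$stream)
  shifted <- photon_stream(sim$stream$timestamp + shift,
                           sim$stream$stream,
                           duration_s = stream_duration(sim$stream) + 30)
  b2 <- search_bursts(shifted)
  expect_equal(b2$E_star, b1$E_star)
  expect_equal(b2$S, b1$S)
})

test_that("burst selection applies the minimum-photon cut-off exactly", {
  mk <- function(n) tibble::tibble(burst_id = 1L, n_photons = n)
  expect_equal(nrow(select_bursts(mk(34))), 0)
  expect_equal(nrow(select_bursts(mk(35))), 1)
  mixed <- tibble::tibble(burst_id = 1:3, n_photons = c(10, 35, 400))
  expect_equal(select_bursts(mixed)$n_photons, c(35, 400))
  expect_equal(nrow(select_bursts(mixed[0, ])), 0)
})

test_that("species partition thresholds on stoichiometry", {
  b <- tibble::tibble(burst_id = 1:3, S = c(0.95, 0.5, 0.05))
  sp <- filter_species(b)
  expect_equal(sp$donor_only$burst_id, 1L)
  expect_equal(sp$fret$burst_id, 2L)
  expect_equal(sp$acceptor_only$burst_id, 3L)
})

test_that("burst photon spans are disjoint and every window criterion holds", {
  cfg <- sim_config(seed = 45, duration_s = 5)
  sim <- simulate_experiment(cfg)
  bursts <- search_bursts(sim$stream)
  if (nrow(bursts) > 1) {
    expect_true(all(bursts$i_start[-1] > bursts$i_end[-nrow(bursts)]))
  }
  expect_equal(bursts$F_DD + bursts$F_DA + bursts$F_AA, bursts$n_photons)
})
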