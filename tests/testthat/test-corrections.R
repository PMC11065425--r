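test_that("apply_corrections reproduces the worked algebra", {
  # identity corrections leave E*, S unchanged
  counts <- burst_metrics(tibble::tibble(F_DD = 25, F_DA = 75, F_AA = 100))
  out <- apply_corrections(counts)
  expect_equal(out$E_corr, counts$E_star)
  expect_equal(out$S_corr, counts$S)

  # lk = 0.1, dir = 0.05, gamma = 1: F_DA_cc = 28 - 8 - 5 = 15, E = 15/95
  out2 <- apply_corrections(tibble::tibble(F_DD = 80, F_DA = 28, F_AA = 100),
                            correction_set(lk = 0.1, dir = 0.05))
  expect_equal(out2$F_DA_cc, 15)
  expect_equal(out2$E_corr, 15 / 95)
  expect_false(out2$clamped)

  # negative corrected counts are clamped and flagged; zero denominators NA
  out3 <- apply_corrections(tibble::tibble(F_DD = c(100, 0), F_DA = c(1, 0),
                                           F_AA = c(0, 0)),
                            correction_set(lk = 0.1))
  expect_true(out3$clamped[1])
  expect_equal(out3$F_DA_cc[1], 0)
  expect_true(is.na(out3$E_corr[2]))
  expect_true(is.na(out3$S_corr[2]))
})

test_that("leakage is the pooled DexAem/DexDem ratio of donor-only bursts", {
  do0 <- tibble::tibble(F_DD = rep(100, 60), F_DA = 0, F_AA = 0)
  expect_equal(estimate_leakage(do0), 0)
  do1 <- tibble::tibble(F_DD = rep(90, 60), F_DA = rep(10, 60), F_AA = 0)
  expect_equal(estimate_leakage(do1), 1 / 9)   # <E*> = 0.1
  expect_error(estimate_leakage(do1[0, ]), "empty")
  expect_warning(estimate_leakage(do1[1:10, ]), "unstable")
})

test_that("direct excitation is the pooled F_DA/F_AA ratio of acceptor-only", {
  ao <- tibble::tibble(F_DD = 0, F_DA = rep(1, 50), F_AA = rep(20, 50))
  expect_equal(estimate_direct_excitation(ao), 0.05)
  ao0 <- tibble::tibble(F_DD = 0, F_DA = rep(0, 50), F_AA = rep(20, 50))
  expect_equal(estimate_direct_excitation(ao0), 0)
  expect_error(estimate_direct_excitation(ao[0, ]), "empty")
  expect_error(estimate_direct_excitation(
    tibble::tibble(F_DD = 0, F_DA = rep(1, 50), F_AA = rep(0, 50))),
    "AexAem")
})

test_that("gamma/beta from two FRET-state centroids on the 1/S vs E line", {
  gb <- estimate_gamma(tibble::tibble(E = c(0.2, 0.75), S = c(0.5, 0.5)))
  expect_equal(gb$gamma, 1)
  expect_equal(gb$beta, 1)
  expect_error(estimate_gamma(tibble::tibble(E = 0.5, S = 0.5)), "two")
  expect_error(estimate_gamma(tibble::tibble(E = c(0.4, 0.4), S = c(0.4, 0.6))),
               "degenerate")

  # synthetic centroids from a known gamma/beta distortion invert exactly:
  # place two states at true (E, S_design), push raw counts through the
  # forward model, lk/dir-correct, and recover gamma/beta
  cor <- correction_set(lk = 0.05, dir = 0.08, gamma = 0.8, beta = 1.2)
  cents <- purrr::map_dfr(c(0.18, 0.63), function(E) {
    p <- fretburst:::stream_probs(E, 0.5, cor)
    out <- apply_corrections(
      tibble::tibble(F_DD = p[1], F_DA = p[2], F_AA = p[3]),
      correction_set(lk = cor$lk, dir = cor$dir, gamma = 1, beta = 1))
    tibble::tibble(E = out$E_corr, S = out$S_corr)
  })
  gb2 <- estimate_gamma(cents)
  expect_equal(gb2$gamma, 0.8, tolerance = 1e-9)
  expect_equal(gb2$beta, 1.2, tolerance = 1e-9)
})

test_that("true corrections neutralize donor-only E and acceptor-only S", {
  cor <- correction_set(lk = 0.07, dir = 0.06, gamma = 0.9)
  p_do <- fretburst:::stream_probs_do(cor)
  out_do <- apply_corrections(
    tibble::tibble(F_DD = p_do[1] * 1e5, F_DA = p_do[2] * 1e5, F_AA = 0), cor)
  expect_equal(out_do$E_corr, 0, tolerance = 1e-12)
  p_ao <- fretburst:::stream_probs_ao(cor)
  out_ao <- apply_corrections(
    tibble::tibble(F_DD = 0, F_DA = p_ao[2] * 1e5, F_AA = p_ao[3] * 1e5), cor)
  expect_equal(out_ao$S_corr, 0, tolerance = 1e-12)
})

test_that("leakage and direct excitation recover from simulated populations", {
  cor <- correction_set(lk = 0.05, dir = 0.08, gamma = 0.8)
  # background-free so the pooled-count estimators see pure populations
  cfg <- sim_config(seed = 61, duration_s = 60, corrections_true = cor,
                    species_fractions = c(doubly = 0, donor_only = 0.5,
                                          acceptor_only = 0.5),
                    background_hz = c(DexDem = 0, DexAem = 0, AexAem = 0))
  sim <- simulate_experiment(cfg)
  sp <- filter_species(select_bursts(search_bursts(sim$stream)))
  lk_hat <- estimate_leakage(sp$donor_only)
  dir_hat <- estimate_direct_excitation(sp$acceptor_only)
  expect_lt(abs(lk_hat - 0.05), 0.005)
  expect_lt(abs(dir_hat - 0.08), 0.008)
})

test_that("background subtraction removes the expected per-stream counts", {
  bg <- estimate_background(photon_stream(
    round(seq(0.001, 29.999, length.out = 3000) / 25e-9),
    rep(0:2, 1000), duration_s = 30))
  # 100 Hz background, ~33.3 Hz per stream
  b <- tibble::tibble(burst_id = 1L,
                      start_tick = 0, stop_tick = 0.3 / 25e-9,
                      F_DD = 100, F_DA = 50, F_AA = 20)
  out <- subtract_background(b, bg)
  expect_equal(out$F_DD, 100 - 10, tolerance = 1e-6)
  expect_equal(out$F_DA, 50 - 10, tolerance = 1e-6)
  expect_equal(out$F_AA, 20 - 10, tolerance = 1e-6)
  expect_equal(out$F_DD_raw, 100)
  # clamped at zero
  b2 <- tibble::tibble(burst_id = 1L, start_tick = 0,
                       stop_tick = 30 / 25e-9,
                       F_DD = 5, F_DA = 5, F_AA = 5)
  expect_true(all(subtract_background(b2, bg)$F_DD >= 0))
})
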