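test_that("generators are deterministic under a fixed seed", {
  p <- pars_1a()
  d <- occupancy_design(seed = 99)
  expect_identical(generate_occupancy_plate(p, d),
                   generate_occupancy_plate(p, d))
  d2 <- occupancy_design(seed = 100)
  expect_false(identical(generate_occupancy_plate(p, d)$occupancy,
                         generate_occupancy_plate(p, d2)$occupancy))
  g <- gsh_design(seed = 99)
  expect_identical(generate_gsh_series(0.01, 0.05, g),
                   generate_gsh_series(0.01, 0.05, g))
  e <- exchange_design(seed = 99, replicates = 1L)
  expect_identical(generate_exchange_traces(1e-6, e),
                   generate_exchange_traces(1e-6, e))
  v <- viability_design(seed = 99, experiments = 1L)
  ics <- c(A = 10, B = 1)
  expect_identical(generate_viability_plate(ics, v),
                   generate_viability_plate(ics, v))
})

test_that("generator RNG does not leak into the session RNG state", {
  withr::with_seed(123, {
    before <- .Random.seed
    generate_occupancy_plate(pars_1a(), occupancy_design(seed = 5))
    expect_identical(.Random.seed, before)
  })
})

test_that("noiseless occupancy plates equal the analytic curve", {
  p <- pars_1a()
  d <- occupancy_design(noise_sd = 0, plateau = 0.9, seed = 1)
  plate <- generate_occupancy_plate(p, d)
  mu <- 0.9 *
    (1 - exp(-analytic_kobs(p, uM_to_M(plate$conc_uM)) * plate$time_s))
  expect_equal(plate$occupancy, mu, tolerance = 1e-12)
})

test_that("every generator-fitter pair closes the loop without noise", {
  # occupancy -> two-stage fit
  p <- pars_1a()
  f <- fit_covalent_kinetics(
    generate_occupancy_plate(p, occupancy_design(noise_sd = 0, seed = 2)))
  expect_rel(f$K_I, p$K_I, 1e-3)
  expect_rel(f$k_inact, p$k_inact, 1e-3)
  # GSH series -> corrected half-life (reference acrylamide: 19 h)
  g <- generate_gsh_series(0.01, log(2) / 19,
                           gsh_design(noise_sdlog = 0, seed = 2))
  d1 <- g[g$replicate == 1, ]
  res <- fit_gsh_reactivity(d1$time_h[d1$arm == "blank"],
                            d1$auc[d1$arm == "blank"],
                            d1$auc[d1$arm == "gsh"])
  expect_rel(res$t_half_gsh_h, 19, 1e-3)
  # zero GSH rate: the pipeline reports a censored half-life
  g0 <- generate_gsh_series(0.01, 0, gsh_design(noise_sdlog = 0, seed = 2))
  d0 <- g0[g0$replicate == 1, ]
  expect_true(fit_gsh_reactivity(d0$time_h[d0$arm == "blank"],
                                 d0$auc[d0$arm == "blank"],
                                 d0$auc[d0$arm == "gsh"])$censored)
  # exchange traces -> normalized rates -> IC50 (reference: 0.305 uM)
  tr <- generate_exchange_traces(
    0.305e-6, exchange_design(noise_frac = 0, replicates = 1L, seed = 2))
  expect_rel(analyze_exchange(tr)$ic50_M, 0.305e-6, 1e-3)
  # zero-concentration control wells are fully active
  expect_true(all(tr$conc_uM[tr$role == "ras_sos"] == 0))
  # viability plate -> per-line IC50s -> selectivity factor
  v <- generate_viability_plate(
    c(`LCLC-103H` = 82.0, MiaPaca2 = 0.53),
    viability_design(noise_sd = 0, experiments = 1L, seed = 2), "1b")
  av <- analyze_viability(v)
  expect_rel(av$selectivity$selectivity[1], 154.7, 0.01)
  vi <- generate_viability_plate(
    c(`LCLC-103H` = 5, MiaPaca2 = 5),
    viability_design(noise_sd = 0, experiments = 1L, seed = 2))
  expect_rel(analyze_viability(vi)$selectivity$selectivity[1], 1, 1e-6)
})

test_that("noisy recovery stays inside the expected envelopes", {
  # GSH half-life within 15% (median over seeds)
  th <- vapply(1:60, function(s) {
    g <- generate_gsh_series(0.01, log(2) / 19, gsh_design(seed = s))
    d <- g[g$replicate == 1, ]
    fit_gsh_reactivity(d$time_h[d$arm == "blank"],
                       d$auc[d$arm == "blank"],
                       d$auc[d$arm == "gsh"])$t_half_gsh_h
  }, numeric(1))
  expect_lt(median(abs(th - 19) / 19), 0.15)
  # exchange IC50 within 20% (median over seeds)
  ic <- vapply(1:20, function(s) {
    tr <- generate_exchange_traces(0.305e-6,
                                   exchange_design(seed = s,
                                                   replicates = 1L))
    analyze_exchange(tr)$ic50_M
  }, numeric(1))
  expect_lt(median(abs(ic - 0.305e-6) / 0.305e-6), 0.20)
  # viability selectivity factor within 30% (median over seeds)
  sf <- vapply(1:40, function(s) {
    v <- generate_viability_plate(c(`LCLC-103H` = 82.0, MiaPaca2 = 0.53),
                                  viability_design(seed = s), "1b")
    analyze_viability(v)$selectivity$selectivity[1]
  }, numeric(1))
  expect_lt(abs(median(sf) - 154.7) / 154.7, 0.30)
})
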