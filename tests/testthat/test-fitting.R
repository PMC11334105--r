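test_that("one-phase fit recovers noiseless parameters exactly", {
  tt <- c(0, 300, 600, 1200, 2400, 4800, 9600, 19200)
  y <- occupancy_curve(2e-4, 0.95, tt)
  f <- fit_one_phase(tt, y)
  expect_rel(f$k_obs, 2e-4, 1e-6)
  expect_rel(f$plateau, 0.95, 1e-6)
  expect_true(f$converged)
  expect_error(fit_one_phase(c(0, 1, 2), c(0, .1, .2)), "insufficient")
  expect_error(fit_one_phase(tt, y + 1), "\\[0, 1\\]")
})

test_that("one-phase fit is accurate under assay-level noise", {
  tt <- c(0, 300, 600, 1200, 2400, 4800, 9600, 19200)
  mu <- occupancy_curve(2e-4, 0.95, tt)
  ks <- withr::with_seed(42, vapply(1:100, function(i) {
    y <- pmin(pmax(mu + rnorm(length(tt), 0, 0.02), 0), 1)
    fit_one_phase(tt, y)$k_obs
  }, numeric(1)))
  expect_rel(median(ks), 2e-4, 0.05)
})

test_that("all-zero occupancy gives a flagged zero-rate fit", {
  f <- fit_one_phase(c(0, 10, 20, 40, 80), rep(0, 5))
  expect_identical(f$k_obs, 0)
  expect_true(f$degenerate)
})

test_that("hyperbolic stage recovers (K_I, k_inact) exactly from clean
           k_obs", {
  p <- pars_1a()
  cc <- study_concs_M()
  f <- fit_kobs_vs_conc(cc, analytic_kobs(p, cc))
  expect_rel(f$K_I, p$K_I, 1e-6)
  expect_rel(f$k_inact, p$k_inact, 1e-6)
  expect_false(f$poorly_determined)
  expect_error(fit_kobs_vs_conc(cc[1:2], analytic_kobs(p, cc[1:2])),
               "3 distinct")
})

test_that("hyperbolic stage is unbiased under 3% relative k_obs noise", {
  p <- pars_1a()
  cc <- study_concs_M()
  k0 <- analytic_kobs(p, cc)
  est <- withr::with_seed(7, t(vapply(1:200, function(i) {
    f <- fit_kobs_vs_conc(cc, k0 * (1 + rnorm(4, 0, 0.03)))
    c(f$K_I, f$k_inact)
  }, numeric(2))))
  expect_lt(abs(median(est[, 1]) - p$K_I) / p$K_I, 0.10)
  expect_lt(abs(median(est[, 2]) - p$k_inact) / p$k_inact, 0.05)
})

test_that("a linear k_obs-concentration relation is flagged unidentifiable", {
  cc <- study_concs_M()
  f <- fit_kobs_vs_conc(cc, 50 * cc)   # pure second-order regime
  expect_true(f$poorly_determined)
})

test_that("hyperbolic stage is invariant to concentration ordering", {
  p <- pars_1a()
  cc <- study_concs_M()
  k0 <- analytic_kobs(p, cc) * c(1.02, 0.98, 1.01, 0.99)
  f1 <- fit_kobs_vs_conc(cc, k0)
  o <- c(3, 1, 4, 2)
  f2 <- fit_kobs_vs_conc(cc[o], k0[o])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("two-stage fit roundtrips the generator (noiseless and noisy)", {
  p <- pars_1a()
  plate <- generate_occupancy_plate(p, occupancy_design(noise_sd = 0,
                                                        seed = 1))
  f <- fit_covalent_kinetics(plate)
  expect_rel(f$K_I, p$K_I, 1e-6)
  expect_rel(f$k_inact, p$k_inact, 1e-6)
  expect_equal(f$n_replicates, 2L)
  # time-unit invariance: the same data expressed through the h-based
  # helpers converts back to identical seconds
  plate2 <- plate
  plate2$time_s <- h_to_s(s_to_h(plate$time_s))
  expect_equal(coef(fit_covalent_kinetics(plate2)), coef(f))
})

test_that("log-linear AUC regression recovers pseudo-first-order rates", {
  tt <- c(0, 1, 2, 4, 8, 12, 24, 48, 72)
  expect_rel(fit_log_linear_rate(tt, 100 * exp(-0.05 * tt)), 0.05, 1e-9)
  expect_equal(fit_log_linear_rate(tt, rep(7, 9)), 0, tolerance = 1e-12)
  noisy <- withr::with_seed(3, vapply(1:200, function(i)
    fit_log_linear_rate(tt, 100 * exp(-0.05 * tt +
                                        rnorm(9, 0, 0.05))), numeric(1)))
  expect_rel(median(noisy), 0.05, 0.10)
  expect_error(fit_log_linear_rate(tt, c(-1, rep(1, 8))), "nonpositive")
})

test_that("degradation correction and censoring follow k_app = k_deg + k_GSH", {
  r <- correct_gsh_rate(k_app = log(2) / 19 + 0.013, k_deg = 0.013)
  expect_rel(r$t_half_gsh_h, 19, 1e-9)
  expect_false(r$censored)
  r2 <- correct_gsh_rate(k_app = 0.2, k_deg = 0)
  expect_rel(r2$t_half_gsh_h, log(2) / 0.2, 1e-12)
  # no GSH reaction at all: censored beyond the sampling window
  r3 <- correct_gsh_rate(k_app = 0.013, k_deg = 0.013)
  expect_true(r3$censored)
  expect_true(is.na(r3$t_half_gsh_h))
  expect_warning(correct_gsh_rate(k_app = 0.1, k_deg = -5e-4), "clamped")
})

test_that("gsh pipeline reproduces generator rates on noiseless series", {
  g <- generate_gsh_series(0.01, log(2) / 19,
                           gsh_design(noise_sdlog = 0, seed = 1))
  d <- g[g$replicate == 1, ]
  res <- fit_gsh_reactivity(d$time_h[d$arm == "blank"],
                            d$auc[d$arm == "blank"],
                            d$auc[d$arm == "gsh"])
  expect_rel(res$k_deg, 0.01, 1e-9)
  expect_rel(res$k_GSH, log(2) / 19, 1e-9)
  expect_rel(res$t_half_gsh_h, 19, 1e-9)
})

test_that("single-exponential trace fit recovers the exchange rate", {
  tt <- seq(0, 3600, by = 30)
  y <- 200 + 800 * exp(-1e-3 * tt)
  f <- fit_exponential_trace(tt, y)
  expect_rel(f$k, 1e-3, 1e-6)
  flat <- fit_exponential_trace(tt, rep(500, length(tt)))
  expect_identical(flat$k, 0)
  expect_true(flat$degenerate)
  ks <- withr::with_seed(11, vapply(1:50, function(i)
    fit_exponential_trace(tt, y + rnorm(length(tt), 0, 8))$k, numeric(1)))
  expect_rel(median(ks), 1e-3, 0.05)
})

test_that("exchange-rate normalization maps the control window to [0, 1]", {
  expect_equal(normalize_exchange_rates(2e-3, 2e-3, 2e-4), 1)
  expect_equal(normalize_exchange_rates(2e-4, 2e-3, 2e-4), 0)
  expect_equal(normalize_exchange_rates(1.1e-3, 2e-3, 2e-4), 0.5)
  expect_error(normalize_exchange_rates(1e-3, 2e-4, 2e-4), "dynamic range")
})

test_that("4PL dose-response fit recovers IC50", {
  cc <- uM_to_M(c(100, 20, 4, 0.8, 0.16, 0.032))
  y <- 1 / (1 + (cc / 2.9e-6))
  f <- fit_ic50(cc, y)
  expect_rel(f$ic50, 2.9e-6, 1e-6)
  expect_rel(f$hill, 1, 1e-4)
  # symmetric curve: fitted IC50 sits at the half-response concentration
  expect_rel(predict(f, f$ic50), (f$top + f$bottom) / 2, 1e-6)
  expect_error(fit_ic50(cc[1:3], y[1:3]), "4 distinct")
})

test_that("4PL fit has small geometric bias under 5% noise", {
  cc <- rep(uM_to_M(c(100, 20, 4, 0.8, 0.16, 0.032)), each = 3)
  mu <- 1 / (1 + (cc / 2.9e-6))
  ics <- withr::with_seed(5, vapply(1:200, function(i) {
    fit_ic50(cc, pmax(mu + rnorm(length(cc), 0, 0.05), 0))$ic50
  }, numeric(1)))
  expect_lt(abs(exp(mean(log(ics))) - 2.9e-6) / 2.9e-6, 0.15)
})

test_that("dose-response with no transition is censored, not invented", {
  cc <- uM_to_M(c(100, 20, 4, 0.8, 0.16, 0.032))
  # IC50 far above the tested range: responses stay near the top
  f <- fit_ic50(cc, 1 / (1 + cc / 5e-3))
  expect_true(f$censored)
  expect_identical(f$censor_side, "above")
})

test_that("replicate aggregation reports mean and n-1 SD, absent for n = 1", {
  a <- aggregate_replicates(290.2)
  expect_equal(a$mean, 290.2)
  expect_true(is.na(a$sd))
  expect_equal(aggregate_replicates(c(9.8, 9.8))$sd, 0)
  b <- aggregate_replicates(c(6, 12))
  expect_equal(b$mean, 9)
  expect_equal(b$sd, sqrt(18), tolerance = 1e-12)  # 4.2426...
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})
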