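test_that("analytic k_obs follows the saturating hyperbola", {
  p <- pars_1a()
  # c = K_I gives half-maximal rate
  expect_equal(analytic_kobs(p, 34.8e-6), 10.1e-3 / 2, tolerance = 1e-12)
  expect_identical(analytic_kobs(p, 0), 0)
  # direct arithmetic at the top study concentration
  expect_equal(analytic_kobs(p, 160e-6),
               10.1e-3 * 160e-6 / (34.8e-6 + 160e-6), tolerance = 1e-12)
  expect_error(analytic_kobs(p, -1e-6), "conc")
})

test_that("k_obs is monotone, concave and bounded by k_inact", {
  p <- pars_1a()
  cc <- seq(0, 1e-3, length.out = 200)
  k <- analytic_kobs(p, cc)
  expect_true(all(diff(k) >= 0))
  expect_true(all(k <= p$k_inact))
  # saturates toward k_inact
  expect_rel(analytic_kobs(p, 1), p$k_inact, 1e-4)
  # concave: second differences nonpositive
  expect_true(all(diff(diff(k)) <= 1e-15))
})

test_that("two_step_params enforces invariants", {
  expect_error(two_step_params(-1e-6, 1e-3), "K_I")
  expect_error(two_step_params(1e-6, -1), "k_inact")
  # microscopic constants must be consistent with K_I = k_-1/k_1
  expect_error(two_step_params(34.8e-6, 1e-2, k_1 = 1e6, k_minus1 = 40),
               "inconsistent")
  p <- two_step_params(34.8e-6, 1e-2, k_1 = 1e6, k_minus1 = 34.8)
  expect_equal(p$k_minus1 / p$k_1, p$K_I, tolerance = 1e-12)
})

test_that("occupancy curve is a one-phase association from zero", {
  expect_identical(occupancy_curve(5e-3, 0.8, 0), 0)
  # half-life identity at plateau 1
  tau <- 1234
  expect_equal(occupancy_curve(log(2) / tau, 1, tau), 0.5, tolerance = 1e-12)
  expect_equal(occupancy_curve(1e-3, 0.9, 1000), 0.9 * (1 - exp(-1)),
               tolerance = 1e-12)
  tt <- seq(0, 5000, by = 100)
  expect_true(all(diff(occupancy_curve(1e-3, 0.5, tt)) > 0))
  expect_error(occupancy_curve(1e-3, 0, 10), "plateau")
  expect_error(occupancy_curve(1e-3, 1.2, 10), "plateau")
})

test_that("mass-action ODE conserves enzyme and has the no-chemistry limit", {
  tr <- simulate_two_step_ode(1e6, 34.8, 0, E0 = 2e-6, I0 = 160e-6,
                              times = seq(0, 100, by = 1))
  total <- tr$E_M + tr$EI_M + tr$EI_cov_M
  expect_true(all(abs(total - 2e-6) <= 1e-6 * 2e-6))
  # k_inact = 0: no covalent adduct ever forms
  expect_true(all(tr$EI_cov_M == 0))
  # and E, EI settle to the noncovalent equilibrium E * I / EI = K_d
  n <- nrow(tr)
  expect_rel(tr$E_M[n] * tr$I_M[n] / tr$EI_M[n], 34.8 / 1e6, 1e-6)
  expect_error(simulate_two_step_ode(Inf, 1, 1, 1e-6, 1e-5, 0:10), "finite")
})

test_that("ODE adduct fraction matches the analytic curve under rapid
           pre-equilibrium and excess inhibitor", {
  p <- pars_1a()
  kobs <- analytic_kobs(p, 160e-6)
  times <- seq(0, 600, by = 10)
  tr <- simulate_two_step_ode(1e6, 34.8, p$k_inact, 2e-6, 160e-6, times)
  af <- adduct_fraction(tr)
  an <- occupancy_curve(kobs, 1, tr$time_s)
  sel <- tr$time_s >= 30   # past the millisecond binding transient
  expect_true(all(abs(af[sel] - an[sel]) / an[sel] < 0.02))
})

test_that("ODE converges to the analytic limit as binding gets faster", {
  p <- pars_1a()
  kobs <- analytic_kobs(p, 160e-6)
  times <- seq(0, 600, by = 20)
  an <- occupancy_curve(kobs, 1, times)
  err <- vapply(c(1e5, 1e6, 1e7), function(k1) {
    tr <- simulate_two_step_ode(k1, k1 * p$K_I, p$k_inact, 2e-6, 160e-6,
                                times)
    af <- adduct_fraction(tr)
    sel <- times >= 60
    max(abs(af[sel] - an[sel]) / an[sel])
  }, numeric(1))
  expect_true(all(diff(err) < 0))        # stiffer binding, smaller error
  # residual floor set by 1.25% inhibitor depletion, not by binding speed
  expect_lt(err[3], 2e-3)
})
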