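test_that("binding free energy is RT ln K_I", {
  expect_equal(round_half_even(binding_free_energy(34.8e-6), 1), -6.1)
  expect_equal(binding_free_energy(1), 0)
  # independent arithmetic for compound 2b's K_I
  expect_equal(binding_free_energy(147.9e-6),
               1.98720425e-3 * 298.15 * log(147.9e-6), tolerance = 1e-12)
  expect_error(binding_free_energy(0), "K_I")
  # roundtrip through exp-inversion
  ctx <- thermo_context()
  for (K in c(1e-7, 34.8e-6, 2e-3)) {
    dG <- binding_free_energy(K, ctx)
    expect_rel(exp(dG / (ctx$R_kcal * ctx$T_K)), K, 1e-12)
  }
})

test_that("Eyring barrier matches the transition-state relation", {
  ctx <- thermo_context()
  expect_equal(round_half_even(eyring_barrier(31.7e-3), 1), 19.5)
  # barrierless limit: k = k_B T / h
  expect_equal(eyring_barrier(ctx$k_B * ctx$T_K / ctx$h), 0,
               tolerance = 1e-10)
  expect_equal(eyring_barrier(14.9e-3),
               ctx$R_kcal * 298.15 * log(ctx$k_B * 298.15 /
                                           (ctx$h * 14.9e-3)),
               tolerance = 1e-12)
  # strictly decreasing in k
  ks <- 10^seq(-5, 2, length.out = 30)
  expect_true(all(diff(eyring_barrier(ks)) < 0))
  expect_error(eyring_barrier(0), "rate")
})

test_that("thiolate fraction follows Henderson-Hasselbalch", {
  expect_equal(thiolate_fraction(8.7, 8.7), 0.5)
  expect_gt(thiolate_fraction(11.7, 8.7), 0.999)
  expect_equal(thiolate_fraction(7.4, 8.7), 1 / (1 + 10^1.3),
               tolerance = 1e-12)
  expect_equal(round(thiolate_fraction(7.4, 8.7), 4), 0.0477)
})

test_that("GSH barrier reproduces measured half-life transforms", {
  expect_equal(round_half_even(gsh_barrier(19)$dG_kcal, 1), 19.3)
  expect_equal(round_half_even(gsh_barrier(44)$dG_kcal, 1), 19.8)
  b <- gsh_barrier(72, censored = TRUE)
  expect_true(b$censored)
  expect_equal(round_half_even(b$dG_kcal, 1), 20.1)
  # strictly increasing in half-life
  th <- c(1, 5, 19, 44, 72, 200)
  dg <- vapply(th, function(t) gsh_barrier(t)$dG_kcal, numeric(1))
  expect_true(all(diff(dg) > 0))
  expect_error(gsh_barrier(0), "t_half")
})

test_that("efficiency and selectivity ratios are plain quotients", {
  expect_equal(round_half_even(efficiency(10.1e-3, 34.8e-6), 1), 290.2)
  expect_equal(round(efficiency(26e-3, 17e-6)), 1529)
  expect_equal(efficiency(1, 1), 1)
  expect_error(efficiency(1, 0), "K_I")
  expect_equal(round_half_even(selectivity_factor(82.0, 0.53), 1), 154.7)
  expect_equal(round_half_even(selectivity_factor(34.0, 16.2), 1), 2.1)
  expect_equal(selectivity_factor(5, 5), 1)
  expect_error(selectivity_factor(-1, 1), "IC50")
})

test_that("derived columns are consistent across the whole compound panel", {
  kin <- kras_panel_kinetics()
  en <- kras_panel_energies()
  # efficiency from the measured K_I / k_inact matches the reported
  # efficiency column at its printed precision for all nine compounds
  eff <- efficiency(kin$kinact_s, uM_to_M(kin$KI_uM))
  dec <- ifelse(kin$eff_printed >= 1000, 0, 1)
  expect_equal(round_half_even(eff, dec), kin$eff_printed,
               tolerance = 1e-9)
  # binding free energy from measured K_I matches the energy table to
  # one decimal for all nine compounds
  dG <- binding_free_energy(uM_to_M(kin$KI_uM))
  expect_equal(round_half_even(dG, 1), en$dG_bind, tolerance = 1e-9)
})
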