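# shared test helpers

expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}

# reference parameters of the lead acrylamide (compound 1a)
pars_1a <- function() two_step_params(K_I = 34.8e-6, k_inact = 10.1e-3)

study_concs_M <- function() uM_to_M(c(20, 40, 80, 160))
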