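test_that("Boltzmann conversion has the closed-form scale and identities", {
  expect_equal(boltzmann_delta_phi(1, 1), 0)
  # e-fold conductance ratio at 25 degC equals kT/e = 25.69 mV
  expect_equal(boltzmann_delta_phi(exp(1), 1, 298.15), 25.69, tolerance = 1e-3)
  # additivity over intermediate conductances (log identity)
  g <- c(0.8, 1.7, 5.2)
  expect_equal(boltzmann_delta_phi(g[3], g[1]),
               boltzmann_delta_phi(g[2], g[1]) +
                 boltzmann_delta_phi(g[3], g[2]))
  # strict monotonicity in the conductance ratio
  ratios <- seq(0.5, 4, by = 0.25)
  vals <- boltzmann_delta_phi(ratios, 1)
  expect_true(all(diff(vals) > 0))
  expect_error(boltzmann_delta_phi(-1, 1), "positive")
  expect_error(boltzmann_delta_phi(1, 0), "positive")
})

test_that("Langmuir fits recover noiseless parameters exactly", {
  s <- gen_adsorption_series(adsorption_model(118, 32))
  for (method in c("nonlinear", "linearized")) {
    fit <- fit_langmuir(s, method)
    expect_true(fit$converged)
    expect_lt(abs(fit$dphi_max - 118) / 118, 1e-6)
    expect_lt(abs(fit$k_desorption - 32) / 32, 1e-6)
  }
  lin <- fit_langmuir(s, "linearized")
  expect_lt(abs(lin$intercept_diagnostic - 1), 1e-6)
})

test_that("Langmuir fit covaries correctly with concentration units", {
  s <- gen_adsorption_series(adsorption_model(60, 25))
  s10 <- s
  s10$concentrations <- s$concentrations * 10
  f1 <- fit_langmuir(s); f10 <- fit_langmuir(s10)
  expect_equal(f10$k_desorption, 10 * f1$k_desorption, tolerance = 1e-6)
  expect_equal(f10$dphi_max, f1$dphi_max, tolerance = 1e-6)
})

test_that("nonlinear and linearized fits agree under multiplicative noise", {
  set.seed(401)
  rel_err <- replicate(40, {
    s <- gen_adsorption_series(adsorption_model(118, 32))
    s$dphi_b <- s$dphi_b * (1 + rnorm(length(s$dphi_b), sd = 0.05))
    fn <- fit_langmuir(s, "nonlinear")
    abs(fn$k_desorption - 32) / 32
  })
  expect_lte(stats::median(rel_err), 0.15)
})

test_that("degenerate adsorption series fail loudly with a reason", {
  flat <- adsorption_series(c(5, 10, 20, 40), dphi_b = rep(30, 4))
  f <- fit_langmuir(flat)
  expect_false(f$converged)
  expect_match(f$reason, "equal")
  expect_true(is.na(f$k_desorption))
  # straight line through the origin: K unidentifiable
  lin <- adsorption_series(c(5, 10, 20, 40), dphi_b = c(5, 10, 20, 40) * 0.3)
  fl <- fit_langmuir(lin)
  expect_false(fl$converged)
  # too few points
  f2 <- fit_langmuir(adsorption_series(c(5, 10), dphi_b = c(3, 5)))
  expect_false(f2$converged)
  expect_match(f2$reason, "3")
})

test_that("weighted fits accept per-point standard deviations", {
  s <- gen_adsorption_series(adsorption_model(118, 32))
  s$sd <- rep(2, length(s$dphi_b))
  fit <- fit_langmuir(s)
  expect_true(fit$converged)
  expect_lt(abs(fit$k_desorption - 32) / 32, 1e-6)
})

test_that("langmuir_fit methods behave like a model object", {
  s <- gen_adsorption_series(adsorption_model(118, 32))
  fit <- fit_langmuir(s)
  expect_named(coef(fit), c("dphi_max", "k_desorption"))
  expect_equal(unname(predict(fit, 32)), 59, tolerance = 1e-5)
  expect_output(print(fit), "Langmuir")
  expect_output(print(summary(fit)), "RMSE")
})

test_that("ratio-to-dipole conversion is linear and guarded", {
  cal <- dipole_calibration(1.0, -0.005)
  rs <- list(concentrations = c(10, 100), ratio = c(1.0, 1.0 - 0.005 * 40),
             compound = "x")
  out <- ratio_to_dipole_shift(rs, cal)
  expect_equal(out$dphi_b, c(0, 40))
  rs2 <- rs; rs2$ratio <- 1.0 + 2 * (rs$ratio - 1.0)
  expect_equal(ratio_to_dipole_shift(rs2, cal)$dphi_b, c(0, 80))
  expect_error(dipole_calibration(1, 0), "slope")
})

test_that("compound summary mirrors the detectability convention", {
  weak <- gen_adsorption_series(adsorption_model(2, 30), compound = "weak")
  # noiseless weak series: K is fit but flagged na below the 10 mV floor
  fw <- fit_langmuir(weak)
  rec <- summarize_compound(fw)
  expect_true(rec$k_na)
  expect_true(is.na(rec$k_uM))
  strong <- gen_adsorption_series(adsorption_model(118, 32),
                                  compound = "strong")
  fs <- fit_langmuir(strong)
  rec2 <- summarize_compound(fs)
  expect_false(rec2$k_na)
  expect_equal(rec2$k_uM, 32, tolerance = 1e-5)
  # missing dipole series stays absent, not zero
  expect_true(is.na(rec2$dphi_d_max))
})
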