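test_that("noiseless unfiltered gating trace takes exactly two levels", {
  tr <- gen_channel_trace(gating_model(open_rate = 5, close_rate = 5,
                                       unit_current = 4.5, voltage = 200,
                                       noise_sd = 0, filter_cutoff = NULL,
                                       duration = 5, seed = 11))
  expect_setequal(unique(tr$current), c(0, 4.5))
})

test_that("gating sojourn statistics follow the exponential law", {
  # mean open dwell = 1/close_rate: close_rate = 1/3 targets the 3.0 s regime
  tr <- gen_channel_trace(gating_model(open_rate = 1, close_rate = 1 / 3,
                                       unit_current = 4.5, voltage = 200,
                                       noise_sd = 0, filter_cutoff = NULL,
                                       sampling_rate = 500, duration = 1200,
                                       seed = 42))
  ev <- tr$true_events
  open_d <- ev$dwell[ev$state == "open"]
  open_d <- open_d[-length(open_d)]      # last sojourn may be truncated
  n <- length(open_d)
  expect_gt(n, 100)
  se <- 3 / sqrt(n)
  expect_lt(abs(mean(open_d) - 3), 3 * se)

  # long-run open fraction ~ k_open/(k_open + k_close)
  frac <- sum(ev$dwell[ev$state == "open"]) / sum(ev$dwell)
  expect_lt(abs(frac - 1 / (1 + 1 / 3)), 0.08)

  # Kolmogorov-Smirnov on true pre-noise sojourns at n >= 2000
  tr2 <- gen_channel_trace(gating_model(open_rate = 20, close_rate = 20,
                                        unit_current = 4.5, voltage = 200,
                                        noise_sd = 0, filter_cutoff = NULL,
                                        sampling_rate = 500, duration = 220,
                                        seed = 7))
  d <- tr2$true_events
  open2 <- d$dwell[d$state == "open"]
  open2 <- open2[-length(open2)]
  expect_gt(length(open2), 2000)
  ks <- suppressWarnings(stats::ks.test(open2, "pexp", rate = 20))
  expect_gt(ks$p.value, 0.01)
})

test_that("generators are bit-reproducible for a fixed seed", {
  gm <- gating_model(10, 10, 4.5, 200, noise_sd = 0.5, duration = 2, seed = 5)
  expect_identical(gen_channel_trace(gm), gen_channel_trace(gm))
  tm <- list(melting_component(41.3, 6e6, 36400))
  expect_identical(gen_thermogram(tm, noise_sd = 30, seed = 3),
                   gen_thermogram(tm, noise_sd = 30, seed = 3))
  lk <- leakage_model(57, 10, noise_sd = 5, seed = 9)
  expect_identical(gen_leakage_series(lk), gen_leakage_series(lk))
  am <- adsorption_model(118, 32, noise_sd = 2, seed = 13)
  expect_identical(gen_adsorption_series(am), gen_adsorption_series(am))
  cal <- dipole_calibration(1, -0.005)
  expect_identical(gen_ratio_series(am, cal, noise_sd = 0.01, seed = 2),
                   gen_ratio_series(am, cal, noise_sd = 0.01, seed = 2))
})

test_that("gating model rejects invalid configurations by field name", {
  expect_error(gating_model(-1, 5, 4.5, 200), "open_rate")
  expect_error(gating_model(5, 0, 4.5, 200), "close_rate")
  expect_error(gating_model(5, 5, 4.5, 200, sampling_rate = 300,
                            filter_cutoff = 200), "sampling_rate")
  expect_error(gating_model(5, 5, 4.5, 200, duration = -2), "duration")
})

test_that("thermogram generator peaks at t_m and integrates to the enthalpy", {
  dh_cal <- 36400
  comp <- melting_component(41.3, vant_hoff_dh_for_fwhm(41.3, 0.4), dh_cal)
  tg <- gen_thermogram(list(comp), grid = seq(35, 47, by = 0.01))
  expect_lt(abs(tg$temperature[which.max(tg$cp_excess)] - 41.3), 0.011)
  # independent trapezoid: mean of adjacent heights times step
  integral <- sum(diff(tg$temperature) *
                    (head(tg$cp_excess, -1) + tail(tg$cp_excess, -1)) / 2)
  expect_lt(abs(integral - dh_cal) / dh_cal, 0.01)
})

test_that("van't Hoff half-width matches the closed form", {
  # dH_vH = 3.5255 R Tm^2 / 0.4 gives a 0.4 degC wide endotherm
  tm <- 41.3
  dh <- 3.5255 * 8.314462618 * (tm + 273.15)^2 / 0.4
  tg <- gen_thermogram(list(melting_component(tm, dh, 36400)),
                       grid = seq(38, 45, by = 0.005))
  y <- tg$cp_excess
  half <- max(y) / 2
  above <- range(which(y > half))
  # linear interpolation of the two crossings
  xs <- tg$temperature
  xl <- stats::approx(y[(above[1] - 1):above[1]],
                      xs[(above[1] - 1):above[1]], xout = half)$y
  xr <- stats::approx(y[above[2]:(above[2] + 1)],
                      xs[above[2]:(above[2] + 1)], xout = half)$y
  expect_lt(abs((xr - xl) - 0.4) / 0.4, 0.02)
  expect_lt(abs(vant_hoff_fwhm(tm, dh) - 0.4) / 0.4, 0.001)
})

test_that("thermogram components are additive and grids must cover them", {
  c1 <- melting_component(39, vant_hoff_dh_for_fwhm(39, 1), 18000)
  c2 <- melting_component(41, vant_hoff_dh_for_fwhm(41, 1), 18000)
  grid <- seq(33, 47, by = 0.02)
  t12 <- gen_thermogram(list(c1, c2), grid = grid)
  t1 <- gen_thermogram(list(c1), grid = grid)
  t2 <- gen_thermogram(list(c2), grid = grid)
  expect_equal(t12$cp_excess, t1$cp_excess + t2$cp_excess, tolerance = 1e-12)
  expect_error(gen_thermogram(list(c1), grid = seq(38.5, 47, by = 0.02)),
               "component 1")
})

test_that("leakage generator follows the saturating exponential", {
  m <- leakage_model(57, 10, times = c(0, 1, 5, 20, 40, 60, 80))
  s <- gen_leakage_series(m)
  rf <- compute_rf(s)
  expect_equal(rf[1], 0)
  expect_lt(abs(rf[7] - 57 * (1 - exp(-8))), 0.1)
  m2 <- leakage_model(57, 10, times = c(0, 10, 1e5))
  expect_lt(abs(compute_rf(gen_leakage_series(m2))[3] - 57), 1e-6)
})

test_that("adsorption generator obeys the Langmuir identities", {
  m <- adsorption_model(118, 32, concentrations = c(0, 16, 32, 96))
  s <- gen_adsorption_series(m)
  expect_equal(s$dphi_b[1], 0)
  expect_equal(s$dphi_b[3], 118 / 2)
  expect_equal(s$dphi_b[4], 118 * 96 / 128)   # = 88.5
  # emitted conductance ratios invert exactly through the Boltzmann stage
  back <- boltzmann_delta_phi(s$g_ratio[-1], 1, temperature = m$temperature)
  expect_equal(back, s$dphi_b[-1], tolerance = 1e-12)
})

test_that("ratio series composes with its inverse and recovers under noise", {
  cal <- dipole_calibration(r_ref = 1.1, slope = -0.004)
  m <- adsorption_model(92, 32)
  rs <- gen_ratio_series(m, cal)
  expect_equal(rs$ratio[m$concentrations == 0], numeric(0))  # no zero in grid
  rs0 <- gen_ratio_series(adsorption_model(92, 32,
                                           concentrations = c(0, 10, 100)),
                          cal)
  expect_equal(rs0$ratio[1], 1.1)
  rec <- ratio_to_dipole_shift(rs, cal)
  expect_equal(rec$dphi_b, 92 * m$concentrations / (m$concentrations + 32),
               tolerance = 1e-12)
  # Monte-Carlo: mean recovered plateau response within 3 SE over replicates
  cmax <- max(m$concentrations)
  truth <- 92 * cmax / (cmax + 32)
  rec_max <- vapply(1:50, function(i) {
    r <- gen_ratio_series(m, cal, noise_sd = 0.01, seed = i)
    tail(ratio_to_dipole_shift(r, cal)$dphi_b, 1)
  }, 0)
  se <- stats::sd(rec_max) / sqrt(length(rec_max))
  expect_lt(abs(mean(rec_max) - truth), 3 * se)
  expect_error(dipole_calibration(1, 0), "slope")
})
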