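test_that("baseline preprocessing is stable, removes trends, keeps zeros", {
  tg <- gen_thermogram(control_components(), grid = seq(25, 50, by = 0.02))
  p1 <- dsc_preprocess(tg)
  p2 <- dsc_preprocess(p1)
  peak <- max(p1$cp_excess)
  # idempotence: a second pass changes nothing appreciable
  expect_lt(max(abs(p2$cp_excess - p1$cp_excess)), 1e-6 * peak)
  # add-then-remove: a linear baseline (slope 0.01/degC) is recovered
  tb <- gen_thermogram(control_components(), baseline = c(5, 0.01),
                       grid = seq(25, 50, by = 0.02))
  pb <- dsc_preprocess(tb)
  expect_lt(max(abs(pb$cp_excess - p1$cp_excess)), 0.01 * peak)
  # flat zero scan passes through untouched
  flat <- thermogram(seq(25, 50, by = 0.1), rep(0, 251))
  expect_equal(dsc_preprocess(flat)$cp_excess, rep(0, 251))
})

test_that("control thermogram features are recovered", {
  tg <- gen_thermogram(control_components(), grid = seq(25, 50, by = 0.02))
  f <- dsc_features(dsc_preprocess(tg))
  expect_lt(abs(f$t_m - 41.3), 0.021)
  expect_lt(abs(f$t_p - 33.9), 0.1)
  expect_false(f$pretransition_abolished)
  expect_lt(abs(f$t_half - 0.40), 0.02)
})

test_that("single-component scans report an abolished pretransition", {
  tg <- gen_thermogram(list(melting_component(
    41.3, vant_hoff_dh_for_fwhm(41.3, 0.4), 36400)),
    grid = seq(25, 50, by = 0.02))
  f <- dsc_features(dsc_preprocess(tg))
  expect_true(f$pretransition_abolished)
  expect_true(is.na(f$t_p))
})

test_that("features are scale-equivariant", {
  tg <- gen_thermogram(list(melting_component(
    41.3, vant_hoff_dh_for_fwhm(41.3, 0.4), 36400)),
    grid = seq(35, 47, by = 0.02))
  f1 <- dsc_features(tg)
  tg2 <- tg; tg2$cp_excess <- tg$cp_excess / 2
  f2 <- dsc_features(tg2)
  expect_equal(f2$t_m, f1$t_m, tolerance = 1e-6)
  expect_equal(f2$t_half, f1$t_half, tolerance = 1e-3)
  expect_equal(f2$enthalpy, f1$enthalpy / 2, tolerance = 1e-6)
})

test_that("extracted half-width matches the van't Hoff closed form", {
  for (w in c(0.2, 0.5, 1, 2, 4)) {
    dh <- vant_hoff_dh_for_fwhm(41.3, w)
    tg <- gen_thermogram(list(melting_component(41.3, dh, 36400)),
                         grid = seq(25, 55, by = 0.005))
    f <- dsc_features(tg)
    expect_lt(abs(f$t_half - vant_hoff_fwhm(41.3, dh)) / w, 0.02,
              label = sprintf("width %.1f degC", w))
  }
})

test_that("deconvolution selects the right component count", {
  # one component: count 1, midpoint within the grid step
  t1 <- gen_thermogram(list(melting_component(
    41.3, vant_hoff_dh_for_fwhm(41.3, 0.8), 36400)),
    grid = seq(33, 47, by = 0.02))
  d1 <- dsc_deconvolve(t1)
  expect_equal(d1$n_components, 1L)
  expect_lt(abs(d1$components$t_m - 41.3), 0.021)
  # two equal-area components 2 degC apart, 1 degC wide: resolved
  t2 <- gen_thermogram(list(
    melting_component(39, vant_hoff_dh_for_fwhm(39, 1), 18000),
    melting_component(41, vant_hoff_dh_for_fwhm(41, 1), 18000)),
    grid = seq(33, 47, by = 0.02))
  d2 <- dsc_deconvolve(t2)
  expect_equal(d2$n_components, 2L)
  expect_lt(abs(d2$components$t_m[1] - 39), 0.1)
  expect_lt(abs(d2$components$t_m[2] - 41), 0.1)
  # separation far below the width is unresolvable: collapses to 1
  t3 <- gen_thermogram(list(
    melting_component(40.00, vant_hoff_dh_for_fwhm(40, 1), 18000),
    melting_component(40.05, vant_hoff_dh_for_fwhm(40.05, 1), 18000)),
    grid = seq(33, 47, by = 0.02))
  d3 <- dsc_deconvolve(t3)
  expect_equal(d3$n_components, 1L)
})

test_that("fitted component enthalpies conserve the total integral", {
  t2 <- gen_thermogram(list(
    melting_component(39, vant_hoff_dh_for_fwhm(39, 1), 18000),
    melting_component(41.5, vant_hoff_dh_for_fwhm(41.5, 0.6), 14000)),
    grid = seq(33, 47, by = 0.02))
  d <- dsc_deconvolve(t2)
  total <- sum(diff(t2$temperature) *
                 (head(t2$cp_excess, -1) + tail(t2$cp_excess, -1)) / 2)
  expect_lt(abs(sum(d$components$calorimetric_enthalpy) - total) / total,
            0.05)
})

test_that("feature errors degrade monotonically with noise", {
  grid <- seq(25, 50, by = 0.02)
  comps <- control_components()
  ladder <- c(10, 80, 400, 1600)
  med_err <- vapply(ladder, function(ns) {
    errs <- vapply(1:30, function(s) {
      tg <- gen_thermogram(comps, grid = grid, noise_sd = ns, seed = s)
      f <- dsc_features(dsc_preprocess(tg))
      abs(f$t_half - 0.4)
    }, 0)
    stats::median(errs)
  }, 0)
  expect_true(all(diff(med_err) >= 0))
})

test_that("shifts versus control use the reporting conventions", {
  grid <- seq(25, 50, by = 0.02)
  ctrl <- dsc_features(dsc_preprocess(gen_thermogram(control_components(),
                                                     grid = grid)))
  expect_equal(dsc_shifts(ctrl, ctrl)$delta_t_m, 0, tolerance = 1e-9)
  expect_equal(dsc_shifts(ctrl, ctrl)$delta_t_half, 0, tolerance = 1e-9)
  # capsaicin-like: main transition down to 36.5 -> -dT_m = 4.8, abolished
  trt <- dsc_features(dsc_preprocess(gen_thermogram(
    list(melting_component(36.5, vant_hoff_dh_for_fwhm(36.5, 4), 30000)),
    grid = grid)))
  sh <- dsc_shifts(ctrl, trt)
  expect_equal(sh$delta_t_m, 4.8, tolerance = 0.03)
  expect_true(sh$pretransition_abolished)
  expect_true(is.na(sh$delta_t_p))
})
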