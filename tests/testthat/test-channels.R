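test_that("noiseless square events are detected exactly", {
  tr <- square_trace(n_events = 20, amp = 4.5, open_s = 0.05)
  ev <- idealize(tr, dead_time = 0)
  open <- ev$events[ev$events$state == "open", ]
  expect_equal(nrow(open), 20)
  expect_true(all(abs(open$mean_amplitude - 4.5) < 1e-9))
  # dwell conservation holds by construction
  expect_equal(sum(ev$events$dwell), ev$duration, tolerance = 1e-12)
})

test_that("idealization recovers simulated gating ground truth", {
  tr <- gen_channel_trace(gating_model(
    open_rate = 1 / 0.15, close_rate = 1 / 0.114, unit_current = 4.5,
    voltage = 200, noise_sd = 0.5, duration = 90, seed = 31))
  ev <- idealize(tr, dead_time = 0.3321 / 200)
  true_open <- tr$true_events[tr$true_events$state == "open", ]
  det_open <- ev$events[ev$events$state == "open", ]
  expect_lt(abs(nrow(det_open) - nrow(true_open)) / nrow(true_open), 0.10)
  expect_lt(abs(sum(det_open$dwell) - sum(true_open$dwell)) /
              sum(true_open$dwell), 0.05)
})

test_that("traces without resolvable openings yield a reasoned no-event result", {
  set.seed(5)
  flat <- structure(list(time = (0:9999) / 5000,
                         current = rnorm(10000, 0, 0.5), voltage = 200,
                         sampling_rate = 5000, filter_cutoff = NULL,
                         temperature = 298.15),
                    class = "current_trace")
  ev <- idealize(flat)
  expect_match(ev$reason, "unimodal")
  expect_equal(nrow(ev$events), 0)
  # events all shorter than the dead time are merged away
  brief <- square_trace(n_events = 10, amp = 4.5, open_s = 0.001,
                        closed_s = 0.1)
  ev2 <- idealize(brief, dead_time = 0.003)
  expect_equal(sum(ev2$events$state == "open"), 0)
})

test_that("conductance follows i/V at the reporting voltage", {
  ev <- event_list(rep(c("closed", "open"), 60), rep(0.05, 120),
                   mean_amplitude = rep(c(NA, 4.5), 60), voltage = 200)
  cs <- conductance_stats(ev, min_events = 30)
  expect_equal(cs$g_sc, 22.5)          # 4.5 pA / 200 mV
  ev2 <- event_list(rep(c("closed", "open"), 60), rep(0.05, 120),
                    mean_amplitude = rep(c(NA, 9.8), 60), voltage = 200)
  expect_equal(conductance_stats(ev2, min_events = 30)$g_sc, 49)
})

test_that("normal amplitude fits pass their goodness-of-fit check", {
  ev <- sim_event_list(1200, 0.05, 0.05, amp_mean = 4.5, amp_sd = 0.12,
                       seed = 8)
  cs <- conductance_stats(ev, min_events = 1000)
  se <- 0.12 / sqrt(1200)
  expect_lt(abs(cs$g_sc - 22.5), 3 * se / 0.2)
  expect_gte(cs$chi2$p_value, 0.05)
  expect_true(cs$accepted)
  few <- sim_event_list(10, 0.05, 0.05)
  expect_match(conductance_stats(few, min_events = 1000)$reason,
               "insufficient")
})

test_that("dwell estimation is unbiased, including under truncation", {
  # paper-scale: mean 3.0 s, n = 2000, no dead time
  ev <- sim_event_list(2000, 3.0, 1.0, seed = 12)
  ds <- dwell_stats(ev, "open", min_events = 1500)
  expect_lt(abs(ds$tau - 3.0), 3 * 3.0 / sqrt(2000))
  expect_true(ds$accepted)
  # truncated at 3 ms with mean 114 ms: E[X | X > d] = tau + d, so the
  # truncation-corrected MLE is unbiased while the naive mean is high
  taus <- vapply(1:40, function(s) {
    evt <- sim_event_list(1500, 0.114, 0.05, dead_time = 0.003, seed = 100 + s)
    d <- evt$events$dwell[evt$events$state == "open"]
    c(mle = dwell_stats(evt, "open", min_events = 1000)$tau,
      naive = mean(d))
  }, c(mle = 0, naive = 0))
  se_mean <- 0.114 / sqrt(1500 * 40)
  expect_lt(abs(mean(taus["mle", ]) - 0.114), 3 * se_mean)
  expect_gt(mean(taus["naive", ]), 0.114 + 0.002)
  # degenerate equal dwells reject the exponential model
  evd <- event_list(rep(c("closed", "open"), 200), rep(0.05, 400),
                    voltage = 200)
  dd <- dwell_stats(evd, "open", min_events = 100)
  expect_false(dd$accepted)
})

test_that("dead-time bias stays small when dead time << tau", {
  errs <- vapply(1:20, function(s) {
    ev <- sim_event_list(1000, 1.0, 0.5, dead_time = 0.01, seed = 200 + s)
    dwell_stats(ev, "open", min_events = 500)$tau
  }, 0)
  expect_lt(abs(mean(errs) - 1.0), 0.02)
})

test_that("estimates converge to simulator truth with trace duration", {
  med_err <- vapply(c(15, 45, 135), function(dur) {
    errs <- vapply(1:12, function(s) {
      tr <- gen_channel_trace(gating_model(
        open_rate = 1 / 0.08, close_rate = 1 / 0.05, unit_current = 4.5,
        voltage = 200, noise_sd = 0.4, duration = dur, seed = 300 + s))
      ev <- idealize(tr, dead_time = 0.3321 / 200)
      ds <- dwell_stats(ev, "open", min_events = 20)
      abs(ds$tau - 0.05) / 0.05
    }, 0)
    stats::median(errs)
  }, 0)
  expect_true(all(diff(med_err) <= 0))
})

test_that("G(V) curves normalize away pure scale factors", {
  mk_stats <- function(g) structure(list(g_sc = g, g_sc_sd = 0.05 * g),
                                    class = "channel_stats")
  v <- c(-200, -100, -50, 50, 100, 200)
  g <- c(21, 22, 22.5, 22.5, 22, 21)
  a <- gv_curve(lapply(g, mk_stats), v)
  b <- gv_curve(lapply(g * 1.15, mk_stats), v)
  expect_equal(a$voltage, sort(v))
  expect_lt(gv_shape_deviation(a, b), 1e-12)
  # an ohmic channel has a flat normalized curve
  flat <- gv_curve(lapply(rep(22.5, 6), mk_stats), v)
  expect_lt(gv_shape_deviation(flat, flat), 1e-12)
})

test_that("macroscopic current ratios recover scaling factors", {
  set.seed(9)
  base <- structure(list(time = (0:4999) / 1000,
                         current = -50 + rnorm(5000, 0, 1), voltage = 50,
                         sampling_rate = 1000, filter_cutoff = NULL),
                    class = "current_trace")
  expect_equal(macroscopic_ratio(base, base, c(1, 4))$ratio, 1.0)
  scaled <- base; scaled$current <- base$current * 0.2
  expect_equal(macroscopic_ratio(base, scaled, c(1, 4))$ratio, 0.2,
               tolerance = 1e-12)
  # 9.8-fold increase with independent 5% noise, 50 seeds
  ratios <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    before <- base
    before$current <- -50 * (1 + rnorm(5000, 0, 0.05))
    after <- base
    after$current <- -50 * 9.8 * (1 + rnorm(5000, 0, 0.05))
    macroscopic_ratio(before, after, c(0.5, 4.5))$ratio
  }, 0)
  expect_lt(abs(stats::median(ratios) - 9.8) / 9.8, 0.02)
  expect_error(macroscopic_ratio(base, base, c(10, 20)), "window")
})
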