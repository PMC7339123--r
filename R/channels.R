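#' Idealize a current trace into open/closed events
#'
#' Half-amplitude threshold idealization. The baseline level is the dominant
#' mode of the all-points amplitude histogram, the open level the most
#' prominent secondary mode; transitions are taken at crossings of the
#' midpoint between the two levels. Note the convention: for a channel that
#' is open more than half the time the dominant mode is the open level, so
#' state labels follow occupancy, not current level — traces should be long
#' enough, or gating slow enough, that the closed state dominates, or labels
#' checked against `open_level`. Events shorter than the dead time
#' (default twice the low-pass filter rise time, `T_r = 0.3321/f_c`) are
#' merged into their neighbours, so the event list alternates states and its
#' dwells sum exactly to the trace duration.
#'
#' @param trace A `"current_trace"` (or list with `current`, `time`,
#'   `sampling_rate`, `voltage`, optionally `filter_cutoff`).
#' @param dead_time Shortest resolvable event, s. Default
#'   `2 * 0.3321 / filter_cutoff` (0 when unfiltered).
#' @param min_mode_separation Minimal separation of the two amplitude modes,
#'   in units of the robust noise SD, below which the histogram is declared
#'   unimodal (default 3).
#' @return An object of class `"event_list"`: data.frame-like list with
#'   `events` (state, start, dwell, mean_amplitude), `baseline`, `open_level`,
#'   `dead_time`, `duration`, or a no-events result with a `reason` code when
#'   the amplitude histogram is unimodal.
#' @export
idealize <- function(trace, dead_time = NULL, min_mode_separation = 3) {
  cur <- trace$current
  fs <- trace$sampling_rate
  if (is.null(dead_time)) {
    fc <- trace$filter_cutoff
    dead_time <- if (is.null(fc) || !is.finite(fc)) 0 else 2 * 0.3321 / fc
  }
  no_events <- function(reason) {
    structure(list(events = data.frame(state = character(0), start = numeric(0),
                                       dwell = numeric(0),
                                       mean_amplitude = numeric(0)),
                   baseline = NA_real_, open_level = NA_real_,
                   dead_time = dead_time, duration = length(cur) / fs,
                   voltage = trace$voltage, reason = reason),
              class = "event_list")
  }
  # all-points histogram: dominant mode = baseline, secondary mode = open level
  dens <- stats::density(cur, n = 1024)
  peaks <- .local_maxima(dens$y)
  peaks <- peaks[order(dens$y[peaks], decreasing = TRUE)]
  baseline <- dens$x[peaks[1]]
  spread <- stats::mad(cur - baseline)
  noise_sd <- if (spread > 0)
    stats::mad(cur[abs(cur - baseline) < 2 * spread]) else 0
  if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- stats::sd(cur) / 10
  # secondary mode: separated from baseline and with real occupancy (density
  # bumps in the Gaussian noise tails are rejected by the prominence floor)
  cand <- peaks[-1]
  cand <- cand[abs(dens$x[cand] - baseline) >
                 min_mode_separation * max(noise_sd, 1e-12) &
                 dens$y[cand] > 0.03 * dens$y[peaks[1]]]
  if (!length(cand)) {
    # noiseless two-level traces have delta-like modes; fall back to the
    # range midpoint when exactly two distinct levels dominate
    lv <- unique(round(cur, 9))
    if (length(lv) == 2) {
      # exact two-level trace: snap both levels to the sample values
      baseline <- lv[which.min(abs(lv - baseline))]
      open_level <- lv[which.max(abs(lv - baseline))]
    } else {
      return(no_events("unimodal amplitude histogram: no open level resolved"))
    }
  } else {
    open_level <- dens$x[cand[which.max(dens$y[cand])]]
  }
  thr <- (baseline + open_level) / 2
  is_open <- if (open_level > baseline) cur > thr else cur < thr
  r <- rle(is_open)
  dw <- r$lengths / fs
  st <- ifelse(r$values, "open", "closed")
  # dead-time merging: drop the shortest sub-dead-time event, fuse neighbours
  while (length(dw) > 1) {
    short <- which(dw < dead_time)
    if (!length(short)) break
    i <- short[which.min(dw[short])]
    if (i == 1) {
      dw[2] <- dw[2] + dw[1]; dw <- dw[-1]; st <- st[-1]
    } else if (i == length(dw)) {
      dw[i - 1] <- dw[i - 1] + dw[i]; dw <- dw[-i]; st <- st[-i]
    } else {
      dw[i - 1] <- dw[i - 1] + dw[i] + dw[i + 1]
      dw <- dw[-c(i, i + 1)]; st <- st[-c(i, i + 1)]
    }
  }
  starts <- cumsum(c(0, dw[-length(dw)]))
  # per-event mean amplitude relative to baseline; a guard band of one
  # filter rise time is trimmed from each event edge so the filter's
  # settling samples do not bias the level estimate
  ends <- cumsum(dw)
  fc <- trace$filter_cutoff
  guard <- if (is.null(fc) || !is.finite(fc)) 0L else
    ceiling(0.3321 / fc * fs)
  amp <- vapply(seq_along(dw), function(i) {
    i0 <- max(1L, ceiling(starts[i] * fs) + 1L)
    i1 <- min(length(cur), floor(ends[i] * fs))
    if (i1 - i0 > 3 * guard) { i0 <- i0 + guard; i1 <- i1 - guard }
    if (i1 < i0) return(NA_real_)
    mean(cur[i0:i1]) - baseline
  }, 0)
  # refine the baseline from the closed events themselves (the density-grid
  # mode is only accurate to the kernel bandwidth)
  cl <- st == "closed" & is.finite(amp) & dw >= dead_time
  if (any(cl)) {
    delta <- stats::weighted.mean(amp[cl], dw[cl])
    amp <- amp - delta
    baseline <- baseline + delta
  }
  structure(list(events = data.frame(state = st, start = starts, dwell = dw,
                                     mean_amplitude = amp,
                                     stringsAsFactors = FALSE),
                 baseline = baseline, open_level = open_level,
                 dead_time = dead_time, duration = length(cur) / fs,
                 voltage = trace$voltage, reason = NULL),
            class = "event_list")
}

#' Construct an event list from pre-idealized events
#'
#' For events produced by external idealization software or simulated
#' directly at the event level. States must alternate; dwells must be at
#' least the dead time.
#'
#' @param state Character vector of `"open"`/`"closed"` states, alternating.
#' @param dwell Dwell times, s.
#' @param mean_amplitude Per-event amplitudes relative to baseline, pA
#'   (`NA` allowed for closed events).
#' @param baseline Baseline current, pA.
#' @param dead_time Dead time of the idealization, s.
#' @param voltage Trace voltage, mV.
#' @return An object of class `"event_list"`.
#' @export
event_list <- function(state, dwell, mean_amplitude = NULL, baseline = 0,
                       dead_time = 0, voltage = NULL) {
  stopifnot(length(state) == length(dwell), all(dwell >= 0),
            all(state %in% c("open", "closed")))
  if (length(state) > 1 && any(state[-1] == state[-length(state)]))
    stop("events must alternate between open and closed", call. = FALSE)
  if (any(dwell < dead_time))
    stop("all dwells must be at least the dead time", call. = FALSE)
  if (is.null(mean_amplitude)) mean_amplitude <- rep(NA_real_, length(state))
  starts <- cumsum(c(0, dwell[-length(dwell)]))
  structure(list(events = data.frame(state = state, start = starts,
                                     dwell = dwell,
                                     mean_amplitude = mean_amplitude,
                                     stringsAsFactors = FALSE),
                 baseline = baseline, open_level = NA_real_,
                 dead_time = dead_time, duration = sum(dwell),
                 voltage = voltage, reason = NULL),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat("Event list: no events (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  n_open <- sum(x$events$state == "open")
  cat(sprintf("Event list: %d events (%d open) over %.1f s; dead time %.2f ms\n",
              nrow(x$events), n_open, x$duration, 1000 * x$dead_time))
  cat(sprintf("  baseline %.2f pA, open level %.2f pA\n", x$baseline,
              x$open_level))
  invisible(x)
}

# pool histogram bins with expected counts < 5 (from both ends inward)
.chisq_gof <- function(observed, expected, n_fitted_par) {
  keep_o <- observed; keep_e <- expected
  repeat {
    i <- which(keep_e < 5)
    if (!length(i) || length(keep_e) <= max(2, n_fitted_par + 2)) break
    j <- i[1]
    tgt <- if (j == length(keep_e)) j - 1 else j + 1
    keep_e[tgt] <- keep_e[tgt] + keep_e[j]
    keep_o[tgt] <- keep_o[tgt] + keep_o[j]
    keep_e <- keep_e[-j]; keep_o <- keep_o[-j]
  }
  stat <- sum((keep_o - keep_e)^2 / keep_e)
  df <- max(1L, length(keep_e) - 1L - n_fitted_par)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Single-channel conductance from an event amplitude histogram
#'
#' Per-event conductances `|i/V|` are binned (Freedman-Diaconis) and a normal
#' density is fitted; the fitted mean is the single-channel conductance
#' `G_SC` and the fitted SD its spread. A chi-squared goodness-of-fit test of
#' the normal model is reported; acceptance uses `p >= 0.05`.
#'
#' @param events An `"event_list"` (open events supply the amplitudes).
#' @param voltage Transmembrane voltage, mV; defaults to the trace voltage.
#' @param min_events Minimal number of amplitude events (default 50; studies
#'   of single channels typically accumulate 1000-1500).
#' @return An object of class `"channel_stats"`: list with `g_sc` (pS),
#'   `g_sc_sd`, `n_events`, `chi2` (statistic, df, p_value), `accepted`.
#' @export
conductance_stats <- function(events, voltage = NULL, min_events = 50) {
  stopifnot(inherits(events, "event_list"))
  voltage <- voltage %||% events$voltage
  if (is.null(voltage) || voltage == 0)
    stop("a nonzero voltage is required", call. = FALSE)
  amp <- events$events$mean_amplitude[events$events$state == "open"]
  amp <- amp[is.finite(amp)]
  if (length(amp) < min_events) {
    return(structure(list(g_sc = NA_real_, g_sc_sd = NA_real_,
                          n_events = length(amp), chi2 = NULL, accepted = NA,
                          reason = sprintf("insufficient events (%d < %d)",
                                           length(amp), min_events)),
                     class = "channel_stats"))
  }
  g <- abs(amp / voltage) * 1000      # pA/mV -> pS
  mu <- mean(g); sg <- stats::sd(g)
  if (sg == 0) {
    return(structure(list(g_sc = mu, g_sc_sd = 0, n_events = length(g),
                          chi2 = NULL, accepted = TRUE, reason = NULL),
                     class = "channel_stats"))
  }
  brk <- .fd_breaks(g)
  h <- graphics::hist(g, breaks = brk, plot = FALSE)
  # the normal density is fitted to the histogram itself (minimum chi
  # squared over the binned counts, started at the sample moments); this
  # keeps the goodness-of-fit statistic chi squared with k - 1 - 2 df
  chi_of <- function(p) {
    if (p[2] <= 0) return(Inf)
    expected <- length(g) * diff(stats::pnorm(h$breaks, p[1], p[2]))
    .chisq_gof(h$counts, pmax(expected, 1e-12), n_fitted_par = 2)$statistic
  }
  opt <- stats::optim(c(mu, sg), chi_of)
  mu_fit <- opt$par[1]; sg_fit <- opt$par[2]
  expected <- length(g) * diff(stats::pnorm(h$breaks, mu_fit, sg_fit))
  chi2 <- .chisq_gof(h$counts, pmax(expected, 1e-12), n_fitted_par = 2)
  structure(list(g_sc = mu_fit, g_sc_sd = sg_fit, n_events = length(g),
                 chi2 = chi2, accepted = chi2$p_value >= 0.05, reason = NULL),
            class = "channel_stats")
}

.fd_breaks <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr == 0) return(10)
  w <- 2 * iqr / length(x)^(1 / 3)
  max(5L, min(60L, ceiling(diff(range(x)) / w)))
}

#' @export
print.channel_stats <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat("Channel stats:", x$reason, "\n")
    return(invisible(x))
  }
  if (!is.null(x$g_sc) && !is.na(x$g_sc))
    cat(sprintf("G_SC = %.2f +/- %.2f pS (n = %d)\n", x$g_sc, x$g_sc_sd,
                x$n_events))
  if (!is.null(x$tau) && !is.na(x$tau))
    cat(sprintf("tau = %.4g +/- %.2g s (n = %d)\n", x$tau, x$tau_err,
                x$n_events))
  if (!is.null(x$chi2))
    cat(sprintf("  chi2 = %.2f (df %d), p = %.3f -> %s\n", x$chi2$statistic,
                x$chi2$df, x$chi2$p_value,
                if (isTRUE(x$accepted)) "accepted" else "rejected"))
  invisible(x)
}

#' Dwell-time statistics of open or closed events
#'
#' Point estimate of the mean dwell `tau` by the maximum-likelihood estimator
#' for an exponential distribution left-truncated at the dead time,
#' `tau_hat = mean(dwell) - dead_time` (from `E[X | X > d] = tau + d`), with
#' standard error `tau_hat/sqrt(n)`. A histogram chi-squared test against
#' the truncated-exponential model is reported for acceptance (the classical
#' histogram-fitting route), with optional logarithmic binning.
#'
#' Events that touch the trace edges are excluded (their dwells are
#' censored).
#'
#' @param events An `"event_list"`.
#' @param state `"open"` (default) or `"closed"`.
#' @param min_events Minimal event count (default 50; dwell analyses
#'   typically use 1500-2000).
#' @param log_binning Use logarithmically spaced dwell bins (default TRUE).
#' @param missed_event_correction Apply the first-order correction for
#'   sojourns of the complementary state shorter than the dead time, which
#'   fuse flanking events and inflate the apparent dwell: the estimate is
#'   multiplied by `exp(-dead_time/tau_other)` (default FALSE; useful when
#'   analysing idealized filtered traces rather than pre-resolved events).
#' @return An object of class `"channel_stats"`: list with `tau` (s),
#'   `tau_err`, `n_events`, `chi2`, `accepted`.
#' @export
dwell_stats <- function(events, state = c("open", "closed"), min_events = 50,
                        log_binning = TRUE, missed_event_correction = FALSE) {
  state <- match.arg(state)
  stopifnot(inherits(events, "event_list"))
  ev <- events$events
  if (nrow(ev) > 2) ev <- ev[-c(1, nrow(ev)), ]       # censored edge events
  d <- ev$dwell[ev$state == state]
  dead <- events$dead_time %||% 0
  if (length(d) < min_events) {
    return(structure(list(tau = NA_real_, tau_err = NA_real_,
                          n_events = length(d), chi2 = NULL, accepted = NA,
                          reason = sprintf("insufficient events (%d < %d)",
                                           length(d), min_events)),
                     class = "channel_stats"))
  }
  tau <- mean(d) - dead
  if (missed_event_correction && dead > 0) {
    other <- ev$dwell[ev$state != state]
    tau_other <- mean(other) - dead
    if (is.finite(tau_other) && tau_other > 0)
      tau <- tau * exp(-dead / tau_other)
  }
  if (tau <= 0)
    return(structure(list(tau = NA_real_, tau_err = NA_real_,
                          n_events = length(d), chi2 = NULL, accepted = NA,
                          reason = "mean dwell does not exceed the dead time"),
                     class = "channel_stats"))
  tau_err <- tau / sqrt(length(d))
  # histogram GOF vs the truncated exponential
  if (stats::sd(d) == 0) {
    chi2 <- list(statistic = Inf, df = 1L, p_value = 0)
  } else {
    brk <- if (log_binning) {
      exp(seq(log(max(min(d), 1e-9)), log(max(d) * (1 + 1e-9)),
              length.out = .fd_breaks(log(d)) + 1))
    } else {
      n_b <- .fd_breaks(d)
      seq(min(d), max(d) * (1 + 1e-9), length.out = n_b + 1)
    }
    brk[1] <- min(brk[1], min(d)); brk[length(brk)] <- max(brk[length(brk)], max(d))
    h <- graphics::hist(d, breaks = brk, plot = FALSE)
    # histogram acceptance: the truncated exponential is fitted to the
    # binned counts by minimum chi squared (the fitted-histogram convention,
    # keeping the statistic chi squared with k - 1 - 1 df)
    chi_of <- function(tt) {
      pfun <- function(x) 1 - exp(-pmax(x - dead, 0) / tt)
      expected <- length(d) * diff(pfun(h$breaks)) /
        (1 - pfun(h$breaks[1]) + 1e-300)
      .chisq_gof(h$counts, pmax(expected, 1e-12), n_fitted_par = 1)$statistic
    }
    tau_hist <- stats::optimize(chi_of, c(tau / 3, tau * 3))$minimum
    pfun <- function(x) 1 - exp(-pmax(x - dead, 0) / tau_hist)
    expected <- length(d) * diff(pfun(h$breaks)) /
      (1 - pfun(h$breaks[1]) + 1e-300)
    chi2 <- .chisq_gof(h$counts, pmax(expected, 1e-12), n_fitted_par = 1)
  }
  structure(list(tau = tau, tau_err = tau_err, n_events = length(d),
                 chi2 = chi2, accepted = chi2$p_value >= 0.05, reason = NULL),
            class = "channel_stats")
}

#' Conductance-voltage curve and shape comparison
#'
#' Orders per-voltage conductance statistics into a G(V) table, and
#' [gv_shape_deviation()] reports the maximum relative deviation between two
#' curves after normalizing each by its mean conductance — the standard check
#' that a modifier rescales channel conductance without changing the shape of
#' the G-V relation.
#'
#' @param stats_by_voltage Named or unnamed list of `"channel_stats"`;
#'   `voltages` supplies the matching voltages (mV).
#' @param voltages Numeric vector of voltages, mV (>= 3, spanning both signs).
#' @return A data.frame `(voltage, g_sc, g_sc_sd)` ordered by voltage, class
#'   `"gv_curve"`.
#' @export
gv_curve <- function(stats_by_voltage, voltages) {
  stopifnot(length(stats_by_voltage) == length(voltages),
            length(voltages) >= 3)
  if (!any(voltages > 0) || !any(voltages < 0))
    warning("G(V) voltages do not span both signs")
  g <- vapply(stats_by_voltage, function(s) s$g_sc, 0)
  sdv <- vapply(stats_by_voltage, function(s) s$g_sc_sd, 0)
  o <- order(voltages)
  structure(data.frame(voltage = voltages[o], g_sc = g[o], g_sc_sd = sdv[o]),
            class = c("gv_curve", "data.frame"))
}

#' @rdname gv_curve
#' @param a,b `"gv_curve"` objects on the same voltage grid.
#' @return `gv_shape_deviation`: maximum relative deviation between the
#'   amplitude-normalized curves.
#' @export
gv_shape_deviation <- function(a, b) {
  stopifnot(nrow(a) == nrow(b), all(a$voltage == b$voltage))
  na <- a$g_sc / mean(a$g_sc)
  nb <- b$g_sc / mean(b$g_sc)
  max(abs(na - nb) / pmax(abs(na), 1e-12))
}

#' Macroscopic current ratio before/after modifier addition
#'
#' Steady-state currents are windowed means of the before and after traces;
#' the reported ratio is `I_inf / I_inf0` (after/before) with the error
#' propagated from the windowed standard errors.
#'
#' @param before,after `"current_trace"` objects at the same voltage.
#' @param window Length-2 numeric `(t0, t1)` in seconds delimiting the
#'   steady-state window; must lie inside both traces.
#' @return An object of class `"macroscopic_result"`: list with `i_inf`,
#'   `i_inf0` (pA), `ratio`, `ratio_err`.
#' @export
macroscopic_ratio <- function(before, after, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (!is.null(before$voltage) && !is.null(after$voltage) &&
      before$voltage != after$voltage)
    stop("before/after traces must share the same voltage", call. = FALSE)
  win_mean <- function(tr) {
    sel <- tr$time >= window[1] & tr$time <= window[2]
    if (!any(sel)) stop("window lies outside the trace", call. = FALSE)
    x <- tr$current[sel]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  b <- win_mean(before); a <- win_mean(after)
  if (b["mean"] == 0) stop("before-trace steady-state current is zero",
                           call. = FALSE)
  ratio <- unname(a["mean"] / b["mean"])
  ratio_err <- abs(ratio) *
    sqrt((a["se"] / a["mean"])^2 + (b["se"] / b["mean"])^2)
  structure(list(i_inf = unname(a["mean"]), i_inf0 = unname(b["mean"]),
                 ratio = ratio, ratio_err = unname(ratio_err)),
            class = "macroscopic_result")
}

#' @export
print.macroscopic_result <- function(x, ...) {
  cat(sprintf("Macroscopic current ratio I_inf/I_inf0 = %.3f +/- %.3f (%.2f / %.2f pA)\n",
              x$ratio, x$ratio_err, x$i_inf, x$i_inf0))
  invisible(x)
}
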