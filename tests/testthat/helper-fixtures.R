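# shared fixture builders (all generated in code; no stored data)

# standard control melting components: pretransition at 33.9 degC plus a
# sharp main transition at 41.3 degC with 0.4 degC half-width
control_components <- function(dh_cal = 36400) {
  list(melting_component(33.9, vant_hoff_dh_for_fwhm(33.9, 1.2),
                         0.12 * dh_cal, weight = 0.11),
       melting_component(41.3, vant_hoff_dh_for_fwhm(41.3, 0.4),
                         dh_cal, weight = 0.89))
}

# alternating open/closed event list with exponential dwells and normal
# open amplitudes, simulated directly at the event level
sim_event_list <- function(n_open, tau_open, tau_closed, amp_mean = 4.5,
                           amp_sd = 0.12, dead_time = 0, seed = 1) {
  set.seed(seed)
  state <- rep(c("closed", "open"), n_open)
  dwell <- numeric(2 * n_open)
  dwell[state == "open"] <- dead_time + stats::rexp(n_open, 1 / tau_open)
  dwell[state == "closed"] <- dead_time + stats::rexp(n_open, 1 / tau_closed)
  amp <- rep(NA_real_, 2 * n_open)
  amp[state == "open"] <- stats::rnorm(n_open, amp_mean, amp_sd)
  event_list(state, dwell, amp, dead_time = dead_time, voltage = 200)
}

# square-pulse current trace with n open events of given amplitude/length
square_trace <- function(n_events = 20, amp = 4.5, open_s = 0.05,
                         closed_s = 0.05, fs = 5000) {
  per_open <- round(open_s * fs); per_closed <- round(closed_s * fs)
  one <- c(rep(0, per_closed), rep(amp, per_open))
  cur <- c(rep(one, n_events), rep(0, per_closed))
  structure(list(time = (seq_along(cur) - 1) / fs, current = cur,
                 voltage = 200, sampling_rate = fs, filter_cutoff = NULL,
                 temperature = 298.15, true_events = NULL, model = NULL),
            class = "current_trace")
}
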