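# 4th-order Bessel analog prototype poles, normalized so the -3 dB point
# falls at omega = 1 (standard filter-design table values).
.bessel4_poles <- c(complex(real = -0.65721173, imaginary =  0.83016120),
                    complex(real = -0.65721173, imaginary = -0.83016120),
                    complex(real = -0.90476063, imaginary =  0.27091873),
                    complex(real = -0.90476063, imaginary = -0.27091873))

#' Causal 4-pole Bessel low-pass filter
#'
#' Digital approximation of the analog 4-pole Bessel filter used by
#' patch-clamp amplifiers, obtained by scaling the normalized analog
#' prototype to the prewarped cutoff and applying the bilinear transform.
#' Applied causally (single pass), as during acquisition.
#'
#' @param x Numeric signal.
#' @param cutoff -3 dB cutoff frequency, Hz.
#' @param sampling_rate Sampling frequency, Hz; must exceed `2 * cutoff`.
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_bessel4 <- function(x, cutoff, sampling_rate) {
  stopifnot(sampling_rate > 2 * cutoff, cutoff > 0)
  w_pre <- 2 * sampling_rate * tan(pi * cutoff / sampling_rate)  # prewarp
  sp <- .bessel4_poles * w_pre
  sg <- Re(prod(-sp))                    # unity DC gain
  zpg <- signal::bilinear(Sz = numeric(0), Sp = sp, Sg = sg,
                          T = 1 / sampling_rate)
  arma <- signal::as.Arma(signal::Zpg(zero = zpg$zero, pole = zpg$pole,
                                      gain = zpg$gain))
  # prepend a reflected pad so the filter starts settled at the signal level
  npad <- min(length(x), ceiling(4 * sampling_rate / cutoff))
  xp <- c(rep(x[1], npad), x)
  as.numeric(signal::filter(signal::Arma(b = Re(arma$b), a = Re(arma$a)),
                            xp))[-seq_len(npad)]
}

#' Simulate a single-channel current trace
#'
#' Continuous-time two-state gating: alternating exponentially distributed
#' sojourns in the closed (`baseline_current`) and open
#' (`baseline_current + unit_current`) levels, sampled at `sampling_rate`.
#' White Gaussian noise of SD `noise_sd` is added before low-pass filtering
#' (instrument-like ordering). The exact pre-noise event sequence is kept in
#' the result for ground-truth comparisons.
#'
#' @param model A [gating_model()].
#' @return An object of class `"current_trace"`: list with `time` (s),
#'   `current` (pA), acquisition metadata, and `true_events`
#'   (data.frame of state/start/dwell for the simulated sojourns, last one
#'   truncated at `duration`).
#' @examples
#' tr <- gen_channel_trace(gating_model(open_rate = 10, close_rate = 10,
#'                                      unit_current = 4.5, voltage = 200,
#'                                      duration = 2, seed = 1))
#' range(tr$current)
#' @export
gen_channel_trace <- function(model) {
  stopifnot(inherits(model, "gating_model"))
  m <- model
  with_seed(m$seed, {
    p_open <- m$open_rate / (m$open_rate + m$close_rate)
    first <- if (stats::runif(1) < p_open) "open" else "closed"
    # draw alternating exponential sojourns in vectorized blocks until the
    # trace duration is covered
    states <- character(0); dwells <- numeric(0)
    while (sum(dwells) < m$duration) {
      nblk <- max(64L, ceiling(1.3 * (m$duration - sum(dwells)) *
                                 m$open_rate * m$close_rate /
                                 (m$open_rate + m$close_rate)))
      odd_state <- if (length(states) %% 2 == 0) first else
        setdiff(c("open", "closed"), first)
      blk_states <- rep(c(odd_state, setdiff(c("open", "closed"), odd_state)),
                        length.out = 2 * nblk)
      rates <- ifelse(blk_states == "open", m$close_rate, m$open_rate)
      blk_dwells <- stats::rexp(2 * nblk, rates)
      states <- c(states, blk_states); dwells <- c(dwells, blk_dwells)
    }
    starts <- cumsum(c(0, dwells[-length(dwells)]))
    keep <- starts < m$duration
    states <- states[keep]; dwells <- dwells[keep]; starts <- starts[keep]
    dwells[length(dwells)] <- m$duration - starts[length(starts)]

    n <- floor(m$duration * m$sampling_rate)
    tgrid <- (seq_len(n) - 1) / m$sampling_rate
    idx <- findInterval(tgrid, starts)
    level <- ifelse(states[idx] == "open",
                    m$baseline_current + m$unit_current, m$baseline_current)
    cur <- level
    if (m$noise_sd > 0) cur <- cur + stats::rnorm(n, sd = m$noise_sd)
    if (!is.null(m$filter_cutoff) && is.finite(m$filter_cutoff)) {
      cur <- lowpass_bessel4(cur, m$filter_cutoff, m$sampling_rate)
    }
    structure(list(time = tgrid, current = cur, voltage = m$voltage,
                   sampling_rate = m$sampling_rate,
                   filter_cutoff = m$filter_cutoff,
                   temperature = m$temperature,
                   true_events = data.frame(state = states, start = starts,
                                            dwell = dwells,
                                            stringsAsFactors = FALSE),
                   model = m),
              class = "current_trace")
  })
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Single-channel current trace: %.1f s at %g Hz (%d samples)\n",
              max(x$time) + 1 / x$sampling_rate, x$sampling_rate,
              length(x$current)))
  cat(sprintf("  voltage %g mV; filter %s Hz; %d true gating events\n",
              x$voltage,
              if (is.null(x$filter_cutoff) || !is.finite(x$filter_cutoff))
                "none" else format(x$filter_cutoff),
              nrow(x$true_events)))
  invisible(x)
}

#' Two-state van't Hoff excess heat capacity curve
#'
#' `Cp(T) = dH_cal * (dH_vH / (R T^2)) * Theta (1 - Theta)` with
#' `Theta = Keq/(1+Keq)` and `ln Keq = -(dH_vH/R)(1/T - 1/Tm)`; the peak sits
#' at `t_m` and the curve integrates to the calorimetric enthalpy.
#'
#' @param temp_C Temperature grid, degC.
#' @param t_m Midpoint, degC.
#' @param dh_vh van't Hoff enthalpy, J/mol.
#' @param dh_cal Calorimetric enthalpy, J/mol.
#' @return Excess heat capacity, J/(mol K), per grid point.
#' @export
vant_hoff_cp <- function(temp_C, t_m, dh_vh, dh_cal) {
  TK <- celsius_to_kelvin(temp_C)
  Tm <- celsius_to_kelvin(t_m)
  lnK <- -(dh_vh / .Rgas) * (1 / TK - 1 / Tm)
  theta <- 1 / (1 + exp(-lnK))
  dh_cal * (dh_vh / (.Rgas * TK^2)) * theta * (1 - theta)
}

#' Full width at half maximum of a two-state endotherm
#'
#' Closed form from solving `Theta(1-Theta) = 1/8`:
#' `FWHM = 3.5255 R Tm^2 / dH_vH` (Tm in kelvin), exact up to the narrow-peak
#' approximation. Inverting it gives the van't Hoff enthalpy that produces a
#' requested half-width.
#'
#' @param t_m Midpoint, degC.
#' @param dh_vh van't Hoff enthalpy, J/mol.
#' @return Width at half height, degC.
#' @export
vant_hoff_fwhm <- function(t_m, dh_vh) {
  Tm <- celsius_to_kelvin(t_m)
  2 * log(3 + 2 * sqrt(2)) * .Rgas * Tm^2 / dh_vh
}

#' van't Hoff enthalpy giving a requested peak half-width
#' @param t_m Midpoint, degC.
#' @param fwhm Desired full width at half maximum, degC.
#' @return van't Hoff enthalpy, J/mol.
#' @rdname vant_hoff_fwhm
#' @export
vant_hoff_dh_for_fwhm <- function(t_m, fwhm) {
  Tm <- celsius_to_kelvin(t_m)
  2 * log(3 + 2 * sqrt(2)) * .Rgas * Tm^2 / fwhm
}

#' Simulate a DSC thermogram
#'
#' Sum of two-state van't Hoff melting components plus a polynomial baseline
#' plus white Gaussian noise. A lipid pretransition is represented as an
#' additional low-enthalpy component below the main transition.
#'
#' @param components List of [melting_component()] objects.
#' @param baseline Polynomial baseline coefficients (intercept first),
#'   evaluated in degC; default none.
#' @param grid Strictly increasing temperature grid, degC; must span each
#'   component's `t_m` by at least two half-widths.
#' @param noise_sd Heat-capacity noise SD, J/(mol K).
#' @param scan_rate Scan rate metadata, degC/min (default 0.2).
#' @param label Identifier carried into the result.
#' @param seed Integer seed.
#' @return An object of class `"thermogram"`: list with `temperature`,
#'   `cp_excess`, `scan_rate`, `label`, and the generating `components`.
#' @export
gen_thermogram <- function(components, baseline = NULL,
                           grid = seq(25, 50, by = 0.02), noise_sd = 0,
                           scan_rate = 0.2, label = "synthetic", seed = NULL) {
  if (inherits(components, "melting_component")) components <- list(components)
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, TRUE, "melting_component")))
  stopifnot(all(diff(grid) > 0))
  for (i in seq_along(components)) {
    cm <- components[[i]]
    w <- vant_hoff_fwhm(cm$t_m, cm$vant_hoff_enthalpy)
    if (cm$t_m - 2 * w < grid[1] || cm$t_m + 2 * w > grid[length(grid)]) {
      stop(sprintf("temperature grid does not cover component %d (t_m = %.2f degC, FWHM = %.2f degC)",
                   i, cm$t_m, w), call. = FALSE)
    }
  }
  cp <- Reduce(`+`, lapply(components, function(cm)
    vant_hoff_cp(grid, cm$t_m, cm$vant_hoff_enthalpy, cm$calorimetric_enthalpy)))
  if (!is.null(baseline)) {
    cp <- cp + drop(outer(grid, seq_along(baseline) - 1, `^`) %*% baseline)
  }
  with_seed(seed, {
    if (noise_sd > 0) cp <- cp + stats::rnorm(length(grid), sd = noise_sd)
    structure(list(temperature = grid, cp_excess = cp, scan_rate = scan_rate,
                   label = label, components = components),
              class = "thermogram")
  })
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("Thermogram '%s': %d points, %.2f-%.2f degC, scan rate %g degC/min\n",
              x$label, length(x$temperature), min(x$temperature),
              max(x$temperature), x$scan_rate))
  invisible(x)
}

#' Simulate a calcein-leakage fluorescence time course
#'
#' Fluorescence `I(t)` such that the noiseless relative fluorescence
#' (see [compute_rf()]) follows `rf_max * (1 - exp(-t/rise_time))`.
#'
#' @param model A [leakage_model()].
#' @return An object of class `"leakage_series"`: list with `times` (min),
#'   `intensity` (a.u.), `i0`, `i_max`, `dilution_factor`, and the generating
#'   `model`.
#' @export
gen_leakage_series <- function(model) {
  stopifnot(inherits(model, "leakage_model"))
  m <- model
  span <- m$i_max / m$dilution_factor - m$i0
  rf <- m$rf_max * (1 - exp(-m$times / m$rise_time))
  intensity <- m$i0 + rf / 100 * span
  with_seed(m$seed, {
    if (m$noise_sd > 0)
      intensity <- intensity + stats::rnorm(length(intensity), sd = m$noise_sd)
    structure(list(times = m$times, intensity = intensity, i0 = m$i0,
                   i_max = m$i_max, dilution_factor = m$dilution_factor,
                   model = m),
              class = "leakage_series")
  })
}

#' Simulate a boundary-potential adsorption series
#'
#' For each concentration, the potential reduction follows the Langmuir
#' isotherm `dphi(C) = dphi_max * C/(C + K)` plus additive noise. The
#' equivalent carrier-conductance ratios `G_m/G_m0 = exp(dphi / (kT/e))`
#' are emitted alongside so the Boltzmann conversion stage can be exercised
#' end to end (converting the ratios back reproduces `dphi` exactly).
#'
#' @param model An [adsorption_model()].
#' @param compound Identifier carried into the result.
#' @return An object of class `"adsorption_series"`: list with
#'   `concentrations` (uM), `dphi_b` (mV, positive = reduction), `g_ratio`,
#'   `temperature`, `compound`, and the generating `model`.
#' @export
gen_adsorption_series <- function(model, compound = "synthetic") {
  stopifnot(inherits(model, "adsorption_model"))
  m <- model
  with_seed(m$seed, {
    dphi <- m$dphi_max * m$concentrations / (m$concentrations + m$k_desorption)
    if (m$noise_sd > 0)
      dphi <- dphi + stats::rnorm(length(dphi), sd = m$noise_sd)
    structure(list(concentrations = m$concentrations, dphi_b = dphi,
                   g_ratio = exp(dphi / thermal_voltage(m$temperature)),
                   temperature = m$temperature, compound = compound,
                   sd = if (m$noise_sd > 0) rep(m$noise_sd, length(dphi)) else NULL,
                   model = m),
              class = "adsorption_series")
  })
}

#' Simulate a ratiometric dye excitation-ratio series
#'
#' Excitation ratios `R(C) = r_ref + slope * dphi_d(C)` plus noise, with the
#' dipole-potential reduction `dphi_d(C)` following the Langmuir isotherm of
#' `adsorption`.
#'
#' @param adsorption An [adsorption_model()] describing `dphi_d(C)`.
#' @param calibration A [dipole_calibration()].
#' @param noise_sd Additive noise SD on R, ratio units.
#' @param seed Integer seed.
#' @param compound Identifier.
#' @return An object of class `"ratio_series"`: list with `concentrations`,
#'   `ratio`, the `calibration`, and the generating `model`.
#' @export
gen_ratio_series <- function(adsorption, calibration, noise_sd = 0,
                             seed = NULL, compound = "synthetic") {
  stopifnot(inherits(adsorption, "adsorption_model"),
            inherits(calibration, "dipole_calibration"))
  m <- adsorption
  dphi <- m$dphi_max * m$concentrations / (m$concentrations + m$k_desorption)
  with_seed(seed, {
    r <- calibration$r_ref + calibration$slope * dphi
    if (noise_sd > 0) r <- r + stats::rnorm(length(r), sd = noise_sd)
    structure(list(concentrations = m$concentrations, ratio = r,
                   calibration = calibration, compound = compound, model = m),
              class = "ratio_series")
  })
}
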