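#' Two-state gating model for a single ion channel
#'
#' Ground-truth description of a channel that alternates between a closed and
#' an open level. `open_rate` is the rate of opening transitions out of the
#' closed state (so the mean closed dwell is `1/open_rate`) and `close_rate`
#' the rate of closing transitions out of the open state (mean open dwell
#' `1/close_rate`). The long-run open probability is
#' `open_rate / (open_rate + close_rate)`.
#'
#' @param open_rate Closed-to-open transition rate, 1/s.
#' @param close_rate Open-to-closed transition rate, 1/s.
#' @param unit_current Single-channel current step i at the trace voltage, pA.
#' @param voltage Transmembrane voltage, mV.
#' @param baseline_current Closed-level current, pA.
#' @param noise_sd Standard deviation of additive white Gaussian instrument
#'   noise, pA (applied before filtering).
#' @param sampling_rate Sampling frequency, Hz (default 5000, the usual
#'   acquisition rate for planar-bilayer records).
#' @param filter_cutoff Low-pass filter cutoff, Hz (default 200); `NULL` or
#'   `Inf` disables filtering.
#' @param duration Trace length, s.
#' @param temperature Bath temperature, K.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `"gating_model"`.
#' @seealso [gen_channel_trace()]
#' @export
gating_model <- function(open_rate, close_rate, unit_current, voltage,
                         baseline_current = 0, noise_sd = 0.5,
                         sampling_rate = 5000, filter_cutoff = 200,
                         duration = 60, temperature = 298.15, seed = NULL) {
  .check_field(is.numeric(open_rate) && open_rate > 0, "open_rate", "must be > 0")
  .check_field(is.numeric(close_rate) && close_rate > 0, "close_rate", "must be > 0")
  .check_field(is.numeric(unit_current) && unit_current != 0, "unit_current",
               "must be nonzero")
  .check_field(is.numeric(sampling_rate) && sampling_rate > 0, "sampling_rate",
               "must be > 0")
  if (!is.null(filter_cutoff) && is.finite(filter_cutoff)) {
    .check_field(filter_cutoff > 0, "filter_cutoff", "must be > 0")
    .check_field(sampling_rate > 2 * filter_cutoff, "sampling_rate",
                 "must exceed twice the filter cutoff")
  }
  .check_field(is.numeric(duration) && duration > 0, "duration", "must be > 0")
  .check_field(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  structure(list(open_rate = open_rate, close_rate = close_rate,
                 unit_current = unit_current, voltage = voltage,
                 baseline_current = baseline_current, noise_sd = noise_sd,
                 sampling_rate = sampling_rate, filter_cutoff = filter_cutoff,
                 duration = duration, temperature = temperature, seed = seed),
            class = "gating_model")
}

#' Two-state van't Hoff melting component
#'
#' One cooperative melting unit of a lipid phase transition. The excess heat
#' capacity is `dH_cal * dTheta/dT` with the two-state fraction converted
#' `Theta(T) = Keq/(1+Keq)`, `ln Keq = -(dH_vH/R) (1/T - 1/Tm)` (temperatures
#' in kelvin). The van't Hoff enthalpy sets the peak sharpness
#' (FWHM = 3.5255 R Tm^2 / dH_vH) and the calorimetric enthalpy the peak area.
#'
#' @param t_m Transition midpoint, degC.
#' @param vant_hoff_enthalpy van't Hoff enthalpy, J/mol (> 0).
#' @param calorimetric_enthalpy Calorimetric (area) enthalpy, J/mol (> 0).
#' @param weight Fractional weight of the component (weights across the
#'   components of one thermogram should sum to 1).
#' @return An object of class `"melting_component"`.
#' @seealso [gen_thermogram()], [vant_hoff_cp()], [vant_hoff_fwhm()]
#' @export
melting_component <- function(t_m, vant_hoff_enthalpy, calorimetric_enthalpy,
                              weight = 1) {
  .check_field(is.numeric(t_m) && is.finite(t_m), "t_m", "must be finite")
  .check_field(is.numeric(vant_hoff_enthalpy) && vant_hoff_enthalpy > 0,
               "vant_hoff_enthalpy", "must be > 0")
  .check_field(is.numeric(calorimetric_enthalpy) && calorimetric_enthalpy > 0,
               "calorimetric_enthalpy", "must be > 0")
  .check_field(is.numeric(weight) && weight > 0 && weight <= 1, "weight",
               "must be in (0, 1]")
  structure(list(t_m = t_m, vant_hoff_enthalpy = vant_hoff_enthalpy,
                 calorimetric_enthalpy = calorimetric_enthalpy, weight = weight),
            class = "melting_component")
}

#' Calcein-leakage kinetics model
#'
#' Mono-exponential dye-release kinetics from large unilamellar vesicles:
#' the noiseless relative fluorescence follows
#' `RF(t) = rf_max * (1 - exp(-t/rise_time))` on the normalized scale
#' `RF = 100 (I - I0) / (Imax/0.9 - I0)`, where the 0.9 factor accounts for
#' dilution of the sample by the detergent used for full lysis.
#'
#' @param rf_max Plateau leakage, percent (0-100).
#' @param rise_time Exponential rise time, min.
#' @param i0 Initial fluorescence, a.u.
#' @param i_max Post-detergent (total lysis) fluorescence, a.u.
#' @param dilution_factor Detergent dilution factor (default 0.9).
#' @param times Sampling grid, min.
#' @param noise_sd Additive fluorescence noise SD, a.u.
#' @param seed Integer seed.
#' @return An object of class `"leakage_model"`.
#' @seealso [gen_leakage_series()], [compute_rf()]
#' @export
leakage_model <- function(rf_max, rise_time, i0 = 10, i_max = 900,
                          dilution_factor = 0.9, times = seq(0, 80, by = 0.5),
                          noise_sd = 0, seed = NULL) {
  .check_field(is.numeric(rf_max) && rf_max >= 0 && rf_max <= 100, "rf_max",
               "must be in [0, 100]")
  .check_field(is.numeric(rise_time) && rise_time > 0, "rise_time", "must be > 0")
  .check_field(is.numeric(i0) && i0 >= 0, "i0", "must be >= 0")
  .check_field(is.numeric(i_max) && i_max > i0, "i_max", "must exceed i0")
  .check_field(is.numeric(dilution_factor) && dilution_factor > 0 &&
                 dilution_factor <= 1, "dilution_factor", "must be in (0, 1]")
  .check_field(!is.unsorted(times), "times", "must be nondecreasing")
  structure(list(rf_max = rf_max, rise_time = rise_time, i0 = i0, i_max = i_max,
                 dilution_factor = dilution_factor, times = times,
                 noise_sd = noise_sd, seed = seed),
            class = "leakage_model")
}

#' Langmuir adsorption model for boundary/dipole potential shifts
#'
#' Saturating potential reduction upon modifier adsorption:
#' `dphi(C) = dphi_max * C / (C + K)` with `K` the desorption constant.
#' Reductions are carried as positive numbers (the field's plotting
#' convention).
#'
#' @param dphi_max Maximal potential reduction at infinite concentration, mV.
#' @param k_desorption Desorption constant K, uM.
#' @param concentrations Strictly increasing concentration grid, uM
#'   (default spans the usual 5 uM - 1 mM dosing range).
#' @param temperature Bath temperature, K.
#' @param noise_sd Additive noise SD on dphi, mV.
#' @param seed Integer seed.
#' @return An object of class `"adsorption_model"`.
#' @seealso [gen_adsorption_series()], [fit_langmuir()]
#' @export
adsorption_model <- function(dphi_max, k_desorption,
                             concentrations = c(5, 10, 20, 40, 80, 160, 320,
                                                640, 1000),
                             temperature = 298.15, noise_sd = 0, seed = NULL) {
  .check_field(is.numeric(k_desorption) && k_desorption > 0, "k_desorption",
               "must be > 0")
  .check_field(is.numeric(concentrations) && all(concentrations >= 0) &&
                 all(diff(concentrations) > 0), "concentrations",
               "must be nonnegative and strictly increasing")
  .check_field(is.numeric(temperature) && temperature > 0, "temperature",
               "must be > 0")
  structure(list(dphi_max = dphi_max, k_desorption = k_desorption,
                 concentrations = concentrations, temperature = temperature,
                 noise_sd = noise_sd, seed = seed),
            class = "adsorption_model")
}

#' Calibration mapping a ratiometric dye signal to dipole potential
#'
#' Linear calibration of the dual-wavelength excitation ratio R of a
#' potential-sensitive styryl dye (420 nm / 520 nm excitation) against the
#' membrane dipole potential: `R(C) = r_ref + slope * dphi_d(C)`. The
#' numerical constants are instrument- and protocol-specific and are supplied
#' as configuration, not hard-coded.
#'
#' @param r_ref Control (modifier-free) excitation ratio, dimensionless.
#' @param slope Sensitivity, ratio units per mV; must be nonzero.
#' @return An object of class `"dipole_calibration"`.
#' @seealso [gen_ratio_series()], [ratio_to_dipole_shift()]
#' @export
dipole_calibration <- function(r_ref = 1.0, slope = -0.005) {
  .check_field(is.numeric(slope) && slope != 0, "slope", "must be nonzero")
  .check_field(is.numeric(r_ref) && is.finite(r_ref), "r_ref", "must be finite")
  structure(list(r_ref = r_ref, slope = slope), class = "dipole_calibration")
}
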