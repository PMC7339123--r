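#' Boundary-potential change from carrier-mediated conductance
#'
#' Converts the ratio of steady-state, cation-carrier-mediated membrane
#' conductances with (`g_m`) and without (`g_m0`) a modifier to the change
#' in membrane boundary potential via the Boltzmann relation
#' `dphi_b = (kT/e) ln(g_m / g_m0)`.
#'
#' Sign convention: an increased cation-carrier conductance reflects a
#' boundary-potential reduction, and reductions are reported as positive
#' numbers throughout the package (the convention used for adsorption plots
#' and tables). The return value is therefore the reported reduction.
#'
#' @param g_m Conductance with modifier, nS (any unit; only the ratio enters).
#' @param g_m0 Conductance without modifier, same unit.
#' @param temperature Absolute temperature, K (default 298.15).
#' @return Potential change in mV (positive = reduction of the boundary
#'   potential).
#' @examples
#' boltzmann_delta_phi(2, 1)          # e-fold ratio ~ 17.8 mV
#' boltzmann_delta_phi(exp(1), 1)     # exactly kT/e = 25.69 mV
#' @export
boltzmann_delta_phi <- function(g_m, g_m0, temperature = 298.15) {
  if (any(!is.finite(g_m)) || any(g_m <= 0))
    stop("g_m must be positive and finite", call. = FALSE)
  if (any(!is.finite(g_m0)) || any(g_m0 <= 0))
    stop("g_m0 must be positive and finite", call. = FALSE)
  thermal_voltage(temperature) * log(g_m / g_m0)
}

#' Construct an adsorption series from measured data
#'
#' Either supply `dphi_b` directly (mV, positive = reduction) or conductance
#' pairs `g_m`/`g_m0`, which are converted through [boltzmann_delta_phi()].
#'
#' @param concentrations Strictly increasing modifier concentrations, uM.
#' @param dphi_b Potential reductions, mV (optional if conductances given).
#' @param g_m,g_m0 Conductances with/without modifier (optional).
#' @param sd Per-point standard deviations, mV (optional; used as weights in
#'   fitting).
#' @param compound Identifier.
#' @param temperature Bath temperature, K.
#' @return An object of class `"adsorption_series"`.
#' @export
adsorption_series <- function(concentrations, dphi_b = NULL, g_m = NULL,
                              g_m0 = NULL, sd = NULL, compound = "unknown",
                              temperature = 298.15) {
  stopifnot(all(diff(concentrations) > 0))
  if (is.null(dphi_b)) {
    if (is.null(g_m) || is.null(g_m0))
      stop("supply either dphi_b or both g_m and g_m0", call. = FALSE)
    dphi_b <- boltzmann_delta_phi(g_m, g_m0, temperature)
  }
  stopifnot(length(dphi_b) == length(concentrations))
  if (!is.null(sd)) stopifnot(length(sd) == length(dphi_b), all(sd >= 0))
  structure(list(concentrations = concentrations, dphi_b = dphi_b, sd = sd,
                 g_ratio = exp(dphi_b / thermal_voltage(temperature)),
                 temperature = temperature, compound = compound),
            class = "adsorption_series")
}

#' @export
print.adsorption_series <- function(x, ...) {
  cat(sprintf("Adsorption series '%s': %d concentrations (%g-%g uM), max dphi %.1f mV\n",
              x$compound, length(x$concentrations), min(x$concentrations),
              max(x$concentrations), max(x$dphi_b)))
  invisible(x)
}

#' Fit a Langmuir adsorption isotherm
#'
#' Fits `dphi(C) = dphi_max * C / (C + K)` to a concentration series of
#' potential reductions. The default is nonlinear least squares
#' (Levenberg-Marquardt); the classical linearization is retained as a
#' validation mode: a double-reciprocal regression of `1/dphi` on `1/C`
#' supplies `dphi_max`, then the regression of `dphi_max/dphi(C)` on `1/C`
#' yields `K` as its slope with an intercept that should be ~1 (reported as
#' a diagnostic). Points are weighted by `1/sd^2` when per-point standard
#' deviations are present.
#'
#' Degenerate series (zero spread, no saturation curvature) return a
#' non-converged fit carrying a `reason` code rather than a silent number.
#'
#' @param series An `"adsorption_series"` (or any list with `concentrations`
#'   and `dphi_b`, optionally `sd`).
#' @param method `"nonlinear"` (default) or `"linearized"`.
#' @return An object of class `"langmuir_fit"` with elements `dphi_max`,
#'   `k_desorption`, `dphi_max_err`, `k_err`, `method`, `converged`,
#'   `reason`, `intercept_diagnostic` (linearized only), `fitted`,
#'   `residuals`, `data`.
#' @examples
#' s <- gen_adsorption_series(adsorption_model(118, 32))
#' fit <- fit_langmuir(s)
#' coef(fit)
#' @export
fit_langmuir <- function(series, method = c("nonlinear", "linearized")) {
  method <- match.arg(method)
  conc <- series$concentrations
  dphi <- series$dphi_b
  sd <- series$sd
  fail <- function(reason) {
    structure(list(dphi_max = NA_real_, k_desorption = NA_real_,
                   dphi_max_err = NA_real_, k_err = NA_real_, method = method,
                   converged = FALSE, reason = reason, fitted = NULL,
                   residuals = NULL, data = list(concentrations = conc,
                                                 dphi_b = dphi, sd = sd),
                   compound = series$compound %||% "unknown"),
              class = "langmuir_fit")
  }
  pos <- conc > 0
  if (sum(pos) < 3) return(fail("fewer than 3 nonzero-concentration points"))
  if (stats::sd(dphi[pos]) < 1e-12 * max(abs(dphi[pos]), 1))
    return(fail("degenerate series: all responses equal"))
  cp <- conc[pos]; yp <- dphi[pos]
  if (any(yp <= 0) && all(dphi[pos] <= 0))
    return(fail("non-positive responses; check the sign convention"))
  # curvature screen: a pure straight line through the origin has no
  # identifiable K
  linfit <- stats::lm(yp ~ 0 + cp)
  rel_dev <- sqrt(mean(stats::residuals(linfit)^2)) / max(abs(yp))
  nlfit_start <- {
    w <- if (!is.null(sd)) 1 / pmax(sd[pos], 1e-9)^2 else rep(1, length(cp))
    ok <- yp > 0
    if (sum(ok) >= 3) {
      lr <- stats::lm(I(1 / yp[ok]) ~ I(1 / cp[ok]), weights = w[ok] * yp[ok]^4)
      b <- unname(stats::coef(lr))
      if (is.finite(b[1]) && b[1] > 0 && b[2] > 0)
        c(dmax = 1 / b[1], k = b[2] / b[1])
      else c(dmax = max(yp) * 1.2, k = stats::median(cp))
    } else c(dmax = max(yp) * 1.2, k = stats::median(cp))
  }
  if (method == "linearized") {
    ok <- yp > 0
    if (sum(ok) < 3) return(fail("too few positive responses to linearize"))
    dmax <- nlfit_start[["dmax"]]
    if (!is.finite(dmax) || dmax <= 0)
      return(fail("double-reciprocal stage produced no positive plateau"))
    lin2 <- stats::lm(I(dmax / yp[ok]) ~ I(1 / cp[ok]))
    sm <- suppressWarnings(summary(lin2))  # noiseless data fit perfectly
    k <- unname(stats::coef(lin2)[2])
    if (!is.finite(k) || k <= 0) return(fail("nonpositive slope: no curvature"))
    fitted <- dmax * conc / (conc + k)
    # plateau uncertainty propagated from the double-reciprocal intercept
    lr <- stats::lm(I(1 / yp[ok]) ~ I(1 / cp[ok]))
    b0 <- stats::coef(lr)[1]
    se_b0 <- suppressWarnings(summary(lr))$coefficients[1, 2]
    out <- list(dphi_max = dmax, k_desorption = k,
                dphi_max_err = unname(se_b0 / b0^2),
                k_err = unname(sm$coefficients[2, 2]), method = method,
                converged = TRUE, reason = NULL,
                intercept_diagnostic = unname(stats::coef(lin2)[1]),
                fitted = fitted, residuals = dphi - fitted,
                data = list(concentrations = conc, dphi_b = dphi, sd = sd),
                compound = series$compound %||% "unknown")
    return(structure(out, class = "langmuir_fit"))
  }
  # nonlinear least squares
  if (rel_dev < 1e-10)
    return(fail("no saturation curvature: K not identifiable"))
  w <- if (!is.null(sd)) 1 / pmax(sd[pos], 1e-9)^2 else NULL
  df <- data.frame(C = cp, y = yp)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ dmax * C / (C + k), data = df,
                      start = list(dmax = nlfit_start[["dmax"]],
                                   k = nlfit_start[["k"]]),
                      weights = if (is.null(w)) rep(1, nrow(df)) else w,
                      lower = c(dmax = -Inf, k = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear fit did not converge"))
  cf <- summary(fit)$coefficients
  fitted <- cf["dmax", 1] * conc / (conc + cf["k", 1])
  structure(list(dphi_max = unname(cf["dmax", 1]),
                 k_desorption = unname(cf["k", 1]),
                 dphi_max_err = unname(cf["dmax", 2]),
                 k_err = unname(cf["k", 2]), method = method,
                 converged = TRUE, reason = NULL,
                 fitted = fitted, residuals = dphi - fitted,
                 data = list(concentrations = conc, dphi_b = dphi, sd = sd),
                 compound = series$compound %||% "unknown"),
            class = "langmuir_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.langmuir_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("Langmuir fit (%s) FAILED: %s\n", x$method, x$reason))
    return(invisible(x))
  }
  cat(sprintf("Langmuir adsorption fit (%s), compound '%s'\n", x$method,
              x$compound))
  cat(sprintf("  dphi(max) = %.2f +/- %.2f mV\n", x$dphi_max, x$dphi_max_err))
  cat(sprintf("  K         = %.2f +/- %.2f uM\n", x$k_desorption, x$k_err))
  if (!is.null(x$intercept_diagnostic))
    cat(sprintf("  linearization intercept = %.4f (expected ~1)\n",
                x$intercept_diagnostic))
  invisible(x)
}

#' @export
coef.langmuir_fit <- function(object, ...) {
  c(dphi_max = object$dphi_max, k_desorption = object$k_desorption)
}

#' @export
summary.langmuir_fit <- function(object, ...) {
  res <- object$residuals
  structure(list(fit = object,
                 rmse = if (is.null(res)) NA_real_ else sqrt(mean(res^2)),
                 n = length(object$data$concentrations)),
            class = "summary.langmuir_fit")
}

#' @export
print.summary.langmuir_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  n = %d points, residual RMSE = %.3g mV\n", x$n, x$rmse))
  invisible(x)
}

#' @export
predict.langmuir_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentrations
          else if (is.list(newdata)) newdata$concentrations else newdata
  object$dphi_max * conc / (conc + object$k_desorption)
}

#' @export
plot.langmuir_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$concentrations, d$dphi_b, xlab = "concentration (uM)",
                 ylab = "potential reduction (mV)",
                 main = sprintf("Langmuir fit (%s)", x$method), ...)
  if (x$converged) {
    cc <- seq(min(d$concentrations), max(d$concentrations), length.out = 200)
    graphics::lines(cc, predict(x, cc))
  }
  invisible(x)
}

#' Convert dye excitation ratios to dipole-potential changes
#'
#' Inverts the linear ratiometric calibration:
#' `dphi_d(C) = (R(C) - r_ref) / slope`.
#'
#' @param series A `"ratio_series"` (or list with `concentrations`, `ratio`).
#' @param calibration A [dipole_calibration()]; defaults to the calibration
#'   stored in the series, if any.
#' @return An `"adsorption_series"` whose `dphi_b` slot carries the
#'   dipole-potential reductions (mV), ready for [fit_langmuir()].
#' @export
ratio_to_dipole_shift <- function(series, calibration = NULL) {
  cal <- calibration %||% series$calibration
  if (is.null(cal)) stop("no dipole calibration supplied", call. = FALSE)
  stopifnot(inherits(cal, "dipole_calibration"))
  if (cal$slope == 0) stop("calibration slope must be nonzero", call. = FALSE)
  dphi <- (series$ratio - cal$r_ref) / cal$slope
  adsorption_series(series$concentrations, dphi_b = dphi,
                    compound = series$compound %||% "unknown")
}

#' Assemble a per-compound electrostatics record
#'
#' Combines the boundary-potential and (optional) dipole-potential Langmuir
#' fits into one record. Compounds whose fitted maximum reduction falls below
#' the detectability floor (default 10 mV, the usual screening threshold for
#' a distinguishable dipole-modifying effect) get their desorption constant
#' flagged not-available, since K is meaningless when no saturating effect is
#' resolved.
#'
#' @param phi_b_fit A `"langmuir_fit"` of the boundary-potential series.
#' @param phi_d_fit Optional `"langmuir_fit"` of the dipole-potential series.
#' @param compound Identifier (defaults to the fit's).
#' @param detectability_floor Minimal resolvable maximum reduction, mV.
#' @return A one-row data.frame with columns `compound`, `dphi_b_max`,
#'   `dphi_b_max_err`, `k_uM`, `k_err`, `k_na`, `dphi_d_max`,
#'   `dphi_d_max_err` (the dipole columns are `NA` when no fit is supplied).
#' @export
summarize_compound <- function(phi_b_fit, phi_d_fit = NULL, compound = NULL,
                               detectability_floor = 10) {
  stopifnot(inherits(phi_b_fit, "langmuir_fit"))
  compound <- compound %||% phi_b_fit$compound
  below <- !phi_b_fit$converged || !is.finite(phi_b_fit$dphi_max) ||
    phi_b_fit$dphi_max < detectability_floor
  rec <- data.frame(
    compound = compound,
    dphi_b_max = phi_b_fit$dphi_max,
    dphi_b_max_err = phi_b_fit$dphi_max_err,
    k_uM = if (below) NA_real_ else phi_b_fit$k_desorption,
    k_err = if (below) NA_real_ else phi_b_fit$k_err,
    k_na = below,
    dphi_d_max = NA_real_,
    dphi_d_max_err = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(phi_d_fit)) {
    stopifnot(inherits(phi_d_fit, "langmuir_fit"))
    rec$dphi_d_max <- phi_d_fit$dphi_max
    rec$dphi_d_max_err <- phi_d_fit$dphi_max_err
  }
  rec
}
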