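#' Construct a thermogram from measured data
#'
#' @param temperature Strictly increasing temperature grid, degC.
#' @param cp_excess Excess heat capacity per grid point.
#' @param scan_rate Scan rate metadata, degC/min (default 0.2).
#' @param label Identifier.
#' @return An object of class `"thermogram"`.
#' @export
thermogram <- function(temperature, cp_excess, scan_rate = 0.2,
                       label = "scan") {
  stopifnot(length(temperature) == length(cp_excess),
            all(diff(temperature) > 0))
  structure(list(temperature = temperature, cp_excess = cp_excess,
                 scan_rate = scan_rate, label = label),
            class = "thermogram")
}

# robust noise estimate from the flanking 10% of grid points at each end
.flank_noise <- function(t) {
  n <- length(t$cp_excess)
  k <- max(5L, floor(0.1 * n))
  flanks <- c(t$cp_excess[seq_len(k)], t$cp_excess[seq(n - k + 1, n)])
  stats::mad(flanks)
}

#' Subtract a polynomial baseline from a thermogram
#'
#' Fits a polynomial of order `baseline_order` to the scan regions outside
#' detected peaks (points are flagged as peak by iterative exclusion of
#' upward outliers) and subtracts it, so the flanks of the returned scan sit
#' near zero. Already-baselined scans pass through unchanged.
#'
#' @param raw A `"thermogram"`.
#' @param baseline_order Polynomial order (default 1, linear).
#' @return A baselined `"thermogram"`.
#' @export
dsc_preprocess <- function(raw, baseline_order = 1) {
  stopifnot(inherits(raw, "thermogram"))
  n <- length(raw$temperature)
  if (n < 50)
    stop("at least 50 grid points are required", call. = FALSE)
  x <- raw$temperature; y <- raw$cp_excess
  # point noise from first differences (insensitive to peaks and trends)
  s_noise <- stats::mad(diff(y)) / sqrt(2)
  ys <- if (n > 25) signal::sgolayfilt(y, p = 3, n = 21) else y
  pred <- rep(0, n)
  for (iter in 1:3) {
    dev <- ys - pred
    thr <- max(2 * s_noise, 1e-3 * max(dev), 1e-12 * max(abs(y), 1))
    excl0 <- dev > thr
    # dilate each excluded run by half its length so peak tails do not pull
    # the baseline upward; fall back to the undilated mask when broad peaks
    # leave too few baseline points
    excl <- excl0
    r <- rle(excl0)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      pad <- ceiling(r$lengths[j] / 2)
      excl[max(1, starts[j] - pad):min(n, ends[j] + pad)] <- TRUE
    }
    if (sum(!excl) < n %/% 10) excl <- excl0
    if (sum(!excl) < n %/% 10)
      stop("baseline failure: peaks occupy the entire scan", call. = FALSE)
    fit <- stats::lm(y ~ poly(x, degree = baseline_order, raw = TRUE),
                     subset = !excl)
    pred <- unname(stats::predict(fit, newdata = data.frame(x = x)))
  }
  thermogram(x, y - pred, scan_rate = raw$scan_rate, label = raw$label)
}

# 3-point parabolic interpolation of a peak apex around grid index i
.parabolic_apex <- function(x, y, i) {
  if (i <= 1 || i >= length(x)) return(c(x = unname(x[i]), y = unname(y[i])))
  y1 <- unname(y[i - 1]); y2 <- unname(y[i]); y3 <- unname(y[i + 1])
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(c(x = unname(x[i]), y = unname(y[i])))
  d <- 0.5 * (y1 - y3) / denom
  d <- max(-1, min(1, d))
  h <- x[i + 1] - x[i]
  c(x = unname(x[i] + d * h), y = y2 - 0.25 * (y1 - y3) * d)
}

# indices of local maxima of y
.local_maxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

# apex of a peak by quadratic regression over imax +/- half_window points
.quadratic_apex <- function(x, y, imax, half_window) {
  sel <- max(1, imax - half_window):min(length(x), imax + half_window)
  if (length(sel) < 5) return(.parabolic_apex(x, y, imax))
  xs <- x[sel] - x[imax]
  b <- stats::coef(stats::lm(y[sel] ~ xs + I(xs^2)))
  if (!is.finite(b[3]) || b[3] >= 0) return(.parabolic_apex(x, y, imax))
  v <- -b[2] / (2 * b[3])
  c(x = unname(x[imax] + v), y = unname(b[1] + b[2] * v + b[3] * v^2))
}

# full width of the peak at index imax at half its height; the first
# crossings (walked out from the apex) are refined by local linear fits of
# y_refine (the raw curve) so residual noise does not bias them inward
.half_width_at <- function(x, y, imax, y_refine = y, half_level = NULL) {
  half <- if (is.null(half_level)) .parabolic_apex(x, y, imax)[["y"]] / 2
          else half_level
  left <- imax; while (left > 1 && y[left] > half) left <- left - 1
  right <- imax; while (right < length(y) && y[right] > half) right <- right + 1
  refine <- function(i) {
    w <- max(2L, as.integer(round(abs(i - imax) / 8)))
    sel <- max(1, i - w):min(length(x), i + w)
    if (length(sel) < 3 || stats::sd(y_refine[sel]) == 0) return(x[i])
    b <- stats::coef(stats::lm(y_refine[sel] ~ x[sel]))
    if (!is.finite(b[2]) || b[2] == 0) return(x[i])
    unname((half - b[1]) / b[2])
  }
  xl <- if (left == imax) x[imax] else refine(left)
  xr <- if (right == imax) x[imax] else refine(right)
  xr - xl
}

#' Extract melting features from a thermogram
#'
#' Identifies the main transition as the global maximum (sub-grid location
#' by 3-point parabolic interpolation), the half-width `t_half` as the full
#' width of the main peak at half its height (linear interpolation of the
#' crossings), the enthalpy as the trapezoidal integral over the main
#' transition window, and the pretransition as the most prominent secondary
#' peak below the main transition. A pretransition is called abolished when
#' no secondary peak exceeds `prominence_factor` times the robust flank
#' noise.
#'
#' @param t A preprocessed `"thermogram"`.
#' @param min_separation Minimal separation between pretransition and main
#'   peak, degC (default 1).
#' @param prominence_factor Pretransition detection threshold in flank-noise
#'   units (default 3).
#' @param window_frac Fraction of peak height delimiting the main-transition
#'   integration window (default 0.01).
#' @return An object of class `"thermogram_features"`: list with `t_p`
#'   (degC or `NA`), `t_m`, `t_half`, `enthalpy`, `peak_height`,
#'   `pretransition_abolished`, `reason` (when featureless).
#' @export
dsc_features <- function(t, min_separation = 1, prominence_factor = 3,
                         window_frac = 0.01) {
  stopifnot(inherits(t, "thermogram"))
  x <- t$temperature; y_raw <- t$cp_excess
  noise <- .flank_noise(t)
  step <- stats::median(diff(x))
  # adaptive Savitzky-Golay smoothing for peak location and crossings only:
  # a light first pass estimates the width, the second pass scales the
  # window to ~FWHM/5 so noise is suppressed without flattening the peak
  sg <- function(v, n) {
    n <- max(5L, min(101L, as.integer(n)))
    if (n %% 2 == 0) n <- n + 1L
    if (length(v) <= n + 1) return(v)
    signal::sgolayfilt(v, p = 3, n = n)
  }
  y <- sg(y_raw, 7)
  fw1 <- .half_width_at(x, y, which.max(y))
  if (is.finite(fw1) && fw1 > 0) y <- sg(y_raw, round(fw1 / step / 5))
  imax <- which.max(y)
  if (!is.finite(fw1) || fw1 <= 0) fw1 <- 10 * step
  if (!is.finite(y[imax]) || y[imax] <= prominence_factor * max(noise, 1e-12)) {
    return(structure(list(t_p = NA_real_, t_m = NA_real_, t_half = NA_real_,
                          enthalpy = NA_real_, peak_height = NA_real_,
                          pretransition_abolished = NA,
                          reason = "no detectable peak"),
                     class = "thermogram_features"))
  }
  # apex from a quadratic fit of the raw curve over +/- FWHM/4 around the
  # smoothed argmax (noise-robust, exact by symmetry on noiseless peaks)
  apex <- .quadratic_apex(x, y_raw, imax, half_window =
                            max(2L, as.integer(round(fw1 / step / 4))))
  if (!is.finite(apex[["x"]]) || abs(apex[["x"]] - x[imax]) > fw1)
    apex <- .parabolic_apex(x, y, imax)
  t_half <- .half_width_at(x, y, imax, y_refine = y_raw,
                           half_level = apex[["y"]] / 2)
  # main-transition window: contiguous region above window_frac of the peak
  # (bounds from the smoothed curve; the integral uses the raw curve)
  thr <- window_frac * apex[["y"]]
  lo <- imax; while (lo > 1 && y[lo] > thr) lo <- lo - 1
  hi <- imax; while (hi < length(y) && y[hi] > thr) hi <- hi + 1
  enthalpy <- pracma::trapz(x[lo:hi], pmax(y_raw[lo:hi], 0))
  # pretransition: local maximum below the main window whose height exceeds
  # the locally interpolated background (+/- 1 degC) -- absolute height
  # would accept noise bumps riding the main peak's tail
  pre_idx <- .local_maxima(y)
  pre_idx <- pre_idx[x[pre_idx] < apex[["x"]] - min_separation & pre_idx < lo]
  t_p <- NA_real_; abolished <- TRUE
  if (length(pre_idx)) {
    wp <- max(2L, as.integer(round(1 / step)))
    n_pts <- length(y)
    excess <- vapply(pre_idx, function(b) {
      y[b] - (y[max(1L, b - wp)] + y[min(n_pts, b + wp)]) / 2
    }, 0)
    best <- pre_idx[which.max(excess)]
    if (max(excess) > prominence_factor * max(noise, 1e-12)) {
      t_p <- unname(.parabolic_apex(x, y, best)["x"])
      abolished <- FALSE
    }
  }
  structure(list(t_p = t_p, t_m = unname(apex["x"]), t_half = t_half,
                 enthalpy = enthalpy, peak_height = unname(apex["y"]),
                 pretransition_abolished = abolished, reason = NULL),
            class = "thermogram_features")
}

#' @export
print.thermogram_features <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat("Thermogram features: ", x$reason, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Thermogram features: t_m = %.2f degC, t_half = %.3f degC, enthalpy = %.3g\n",
              x$t_m, x$t_half, x$enthalpy))
  if (x$pretransition_abolished) cat("  pretransition: abolished/not detected\n")
  else cat(sprintf("  pretransition: t_p = %.2f degC\n", x$t_p))
  invisible(x)
}

# sum of van't Hoff components given a flat parameter vector
.vh_mixture <- function(temp_C, par, k) {
  cp <- 0
  for (j in seq_len(k)) {
    cp <- cp + vant_hoff_cp(temp_C, par[3 * j - 2], exp(par[3 * j - 1]),
                            exp(par[3 * j]))
  }
  cp
}

#' Deconvolve a thermogram into van't Hoff melting components
#'
#' Fits sums of 1..`max_components` two-state van't Hoff curves by nonlinear
#' least squares and selects the component count by the small-sample AIC
#' (AICc), with a resolvability rule: candidate solutions containing a
#' component pair closer than `min_separation_factor` times the pair's mean
#' half-width are considered unresolvable and discarded in favour of fewer
#' components. A Gaussian mixture is offered as an alternative component
#' shape for sensitivity analysis.
#'
#' @param t A preprocessed `"thermogram"`.
#' @param max_components Largest component count tried (default 3).
#' @param model `"vant_hoff"` (default) or `"gaussian"`.
#' @param min_separation_factor Resolvability threshold as a fraction of the
#'   mean pair FWHM (default 0.25).
#' @return An object of class `"dsc_deconvolution"`: list with `components`
#'   (data.frame of `t_m`, `vant_hoff_enthalpy`, `calorimetric_enthalpy`,
#'   `weight`, sorted by `t_m`), `n_components`, `aicc` per count,
#'   `converged`, `reason`.
#' @export
dsc_deconvolve <- function(t, max_components = 3,
                           model = c("vant_hoff", "gaussian"),
                           min_separation_factor = 0.25) {
  model <- match.arg(model)
  stopifnot(inherits(t, "thermogram"))
  x <- t$temperature; y <- t$cp_excess
  n <- length(x)
  total_area <- pracma::trapz(x, pmax(y, 0))
  if (total_area <= 0) {
    return(structure(list(components = NULL, n_components = 0L, aicc = NULL,
                          converged = FALSE, reason = "no positive area"),
                     class = "dsc_deconvolution"))
  }
  feats <- dsc_features(t)
  fwhm0 <- if (is.finite(feats$t_half)) feats$t_half else diff(range(x)) / 10
  fits <- list(); aiccs <- rep(NA_real_, max_components)
  for (k in seq_len(max_components)) {
    # initial midpoints at the quantiles of the cumulative positive area
    cum <- cumsum(pmax(y, 0)); cum <- cum / cum[n]
    qs <- (seq_len(k) - 0.5) / k
    tm0 <- vapply(qs, function(q) x[which.min(abs(cum - q))], 0)
    par0 <- as.numeric(rbind(tm0,
                             log(vant_hoff_dh_for_fwhm(tm0, fwhm0)),
                             log(total_area / k)))
    shape <- if (model == "vant_hoff") .vh_mixture else function(tc, p, kk) {
      cp <- 0
      for (j in seq_len(kk)) {
        mu <- p[3 * j - 2]; sig <- exp(p[3 * j - 1]); a <- exp(p[3 * j])
        cp <- cp + a * stats::dnorm(tc, mu, sig)
      }
      cp
    }
    if (model == "gaussian")
      par0 <- as.numeric(rbind(tm0, log(fwhm0 / 2.3548), log(total_area / k)))
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0,
                         fn = function(p) y - shape(x, p, k),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    p <- 3 * k + 1                    # parameters + residual variance
    if (n - p - 1 <= 0) next
    aiccs[k] <- n * log(max(rss, 1e-300) / n) + 2 * p +
      2 * p * (p + 1) / (n - p - 1)
    fits[[k]] <- res
  }
  if (all(is.na(aiccs))) {
    return(structure(list(components = NULL, n_components = 0L, aicc = aiccs,
                          converged = FALSE,
                          reason = "no component count converged"),
                     class = "dsc_deconvolution"))
  }
  order_k <- order(aiccs, na.last = NA)
  chosen <- NULL
  for (k in order_k) {
    pp <- fits[[k]]$par
    tm <- pp[seq(1, 3 * k, by = 3)]
    if (model == "vant_hoff") {
      fw <- vant_hoff_fwhm(tm, exp(pp[seq(2, 3 * k, by = 3)]))
    } else {
      fw <- 2.3548 * exp(pp[seq(2, 3 * k, by = 3)])
    }
    resolvable <- TRUE
    if (k > 1) {
      o <- order(tm)
      sep <- diff(tm[o]); mw <- (fw[o][-k] + fw[o][-1]) / 2
      if (any(sep < min_separation_factor * mw)) resolvable <- FALSE
    }
    if (resolvable) { chosen <- k; break }
  }
  if (is.null(chosen)) chosen <- order_k[1]
  pp <- fits[[chosen]]$par
  k <- chosen
  tm <- pp[seq(1, 3 * k, by = 3)]
  if (model == "vant_hoff") {
    dhvh <- exp(pp[seq(2, 3 * k, by = 3)])
    dhcal <- exp(pp[seq(3, 3 * k, by = 3)])
  } else {
    dhvh <- rep(NA_real_, k)
    dhcal <- exp(pp[seq(3, 3 * k, by = 3)])
  }
  o <- order(tm)
  comps <- data.frame(t_m = tm[o], vant_hoff_enthalpy = dhvh[o],
                      calorimetric_enthalpy = dhcal[o],
                      weight = dhcal[o] / sum(dhcal))
  structure(list(components = comps, n_components = k, aicc = aiccs,
                 model = model, converged = TRUE, reason = NULL),
            class = "dsc_deconvolution")
}

#' @export
print.dsc_deconvolution <- function(x, ...) {
  if (!x$converged) {
    cat("DSC deconvolution FAILED:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("DSC deconvolution (%s model): %d component(s)\n", x$model,
              x$n_components))
  print(x$components, digits = 4)
  invisible(x)
}

#' Melting-feature shifts of a treated scan relative to a control
#'
#' Reports shifts with the conventional signs: `delta_t_p` and `delta_t_m`
#' are positive for downshifts (pretransition/main transition moving to
#' lower temperatures), `delta_t_half` positive for broadening. When the
#' treated scan's pretransition is abolished, `delta_t_p` is `NA` and
#' `pretransition_abolished` is `TRUE` (abolition is a categorical outcome,
#' not a zero shift).
#'
#' @param control,treated `"thermogram_features"` objects.
#' @return An object of class `"melting_shifts"`: list with `delta_t_p`,
#'   `delta_t_m` (positive = downshift, i.e. the reported `-dT_m`),
#'   `delta_t_half`, `pretransition_abolished`.
#' @export
dsc_shifts <- function(control, treated) {
  stopifnot(inherits(control, "thermogram_features"),
            inherits(treated, "thermogram_features"))
  if (!is.null(control$reason) || !is.null(treated$reason))
    stop("both feature sets must contain a detected main transition",
         call. = FALSE)
  abolished <- isTRUE(treated$pretransition_abolished) &&
    !isTRUE(control$pretransition_abolished)
  delta_t_p <- if (abolished || is.na(treated$t_p) || is.na(control$t_p))
    NA_real_ else control$t_p - treated$t_p
  structure(list(delta_t_p = delta_t_p,
                 delta_t_m = control$t_m - treated$t_m,
                 delta_t_half = treated$t_half - control$t_half,
                 pretransition_abolished = abolished),
            class = "melting_shifts")
}

#' @export
print.melting_shifts <- function(x, ...) {
  cat("Melting shifts vs control:\n")
  cat(sprintf("  -dT_m   = %.2f degC\n", x$delta_t_m))
  cat(sprintf("  dT_1/2  = %.2f degC\n", x$delta_t_half))
  if (x$pretransition_abolished) cat("  dT_p    : pretransition abolished\n")
  else cat(sprintf("  dT_p    = %.2f degC\n", x$delta_t_p))
  invisible(x)
}
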