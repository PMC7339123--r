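#' Pearson correlation with a Fisher-transform confidence interval
#'
#' Pearson's r between two vectors (pairwise deletion of incomplete pairs)
#' with the confidence interval obtained through the Fisher transformation:
#' `z = atanh(r)`, `z +/- z_crit(alpha) / sqrt(n - 3)`, back-transformed with
#' `tanh`. `z_crit` is the two-sided normal quantile (no small-sample t
#' adjustment). The coefficient is flagged significant when the interval
#' excludes 0.
#'
#' @param x,y Numeric vectors of equal length; `NA` pairs are dropped.
#' @param alpha Confidence parameter (default 0.1, i.e. a 90% interval).
#' @return An object of class `"cor_fisher"`: list with `r`, `n`, `ci_low`,
#'   `ci_high`, `alpha`, `significant`, or an undefined-correlation result
#'   with a `reason` when either variable has zero variance or fewer than 4
#'   complete pairs exist.
#' @examples
#' pearson_fisher(1:10, (1:10) * 2 + 1)
#' @export
pearson_fisher <- function(x, y, alpha = 0.1) {
  stopifnot(length(x) == length(y), alpha > 0, alpha < 1)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  undef <- function(reason) {
    structure(list(r = NA_real_, n = n, ci_low = NA_real_, ci_high = NA_real_,
                   alpha = alpha, significant = NA, reason = reason),
              class = "cor_fisher")
  }
  if (n < 4) return(undef("fewer than 4 complete pairs"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(undef("zero variance"))
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    hw <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  structure(list(r = r, n = n, ci_low = ci[1], ci_high = ci[2], alpha = alpha,
                 significant = ci[1] > 0 || ci[2] < 0, reason = NULL),
            class = "cor_fisher")
}

#' @export
print.cor_fisher <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat("Correlation undefined:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("Pearson r = %.3f (n = %d), %d%% CI [%.3f, %.3f]%s\n",
              x$r, x$n, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties, used to confirm significant
#' Pearson correlations without assuming linearity.
#'
#' @param x,y Numeric vectors of equal length; `NA` pairs are dropped.
#' @return The rank correlation coefficient, or `NA` when fewer than 4
#'   complete pairs exist or either rank variance is zero.
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Screen physicochemical descriptors against membrane effects
#'
#' Computes the full matrix of Pearson correlations (with Fisher-transform
#' confidence intervals) between per-compound descriptors (lipophilicity
#' `logd`, `logp`; polarity `dipole_moment`) and measured membrane effects.
#' Missing entries are pairwise-deleted, so the pair count `n` varies across
#' cells. Spearman confirmation is computed for every cell except dipole
#' moment versus the potential-reduction maxima (`dphi_b_max`, `dphi_d_max`):
#' a parallel-plate-capacitor argument makes that relationship linear by
#' construction, so rank confirmation is not informative there and the cell
#' is left absent.
#'
#' @param descriptors data.frame keyed by `compound` with any of `logd`,
#'   `logp`, `dipole_moment`.
#' @param effects data.frame keyed by `compound`; remaining numeric columns
#'   are treated as effect measures (e.g. `dphi_b_max`, `dphi_d_max`, `k_uM`,
#'   `delta_t_m`, `delta_t_half`, `rf_max`).
#' @param alpha Confidence parameter for the Fisher intervals (default 0.1).
#' @return data.frame of class `"descriptor_screen"` with one row per
#'   descriptor x effect cell: `descriptor`, `effect`, `r`, `n`, `ci_low`,
#'   `ci_high`, `significant`, `spearman_rho`, `computable`.
#' @export
effect_descriptor_screen <- function(descriptors, effects, alpha = 0.1) {
  stopifnot("compound" %in% names(descriptors), "compound" %in% names(effects))
  if (anyDuplicated(descriptors$compound) || anyDuplicated(effects$compound))
    stop("compound identifiers must be unique", call. = FALSE)
  merged <- merge(descriptors, effects, by = "compound")
  desc_cols <- intersect(c("logd", "logp", "dipole_moment"), names(descriptors))
  eff_cols <- setdiff(names(effects), "compound")
  eff_cols <- eff_cols[vapply(effects[eff_cols], is.numeric, TRUE)]
  no_spearman_effects <- c("dphi_b_max", "dphi_d_max")
  rows <- list()
  for (dcol in desc_cols) {
    for (ecol in eff_cols) {
      x <- merged[[dcol]]; y <- merged[[ecol]]
      cf <- pearson_fisher(x, y, alpha = alpha)
      rho <- if (dcol == "dipole_moment" && ecol %in% no_spearman_effects)
        NA_real_ else spearman_rank(x, y)
      rows[[length(rows) + 1]] <- data.frame(
        descriptor = dcol, effect = ecol, r = cf$r, n = cf$n,
        ci_low = cf$ci_low, ci_high = cf$ci_high,
        significant = cf$significant, spearman_rho = rho,
        computable = is.null(cf$reason), stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("descriptor_screen", "data.frame"))
}

#' @export
print.descriptor_screen <- function(x, ...) {
  cat("Descriptor-effect correlation screen (alpha =",
      format(attr(x, "alpha") %||% 0.1), "):\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
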