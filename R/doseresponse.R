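# The estimand throughout is the dose-response contrast
#   delta(x) = E[Y | X = x] - E[Y | X = ref],
# a linear contrast c' beta of the fitted coefficients, with delta-method
# standard error sqrt(c' V c) from the robust covariance V. Covariates
# never enter: their entries in c are zero because they cancel in the
# difference of two design rows.

# Design row for a single dose over the non-covariate columns, or NULL if
# the dose is not representable under this fit (a category level that was
# empty in the fitted data, or a dose below the minimum observed positive
# dose when zero-dose rows were excluded).
design_row_at <- function(fit, x) {
  spec <- fit$spec
  if (spec$exclude_zero_dose && x < fit$info$min_pos_dose) return(NULL)
  if (spec$exposure_form == "categorical" && x > 0) {
    lev <- as.character(dose_categories(x, spec$breaks))
    if (lev %in% fit$info$levels_dropped) return(NULL)
  }
  row <- c(1, if (spec$include_spike) spike_indicator(x),
           as.numeric(exposure_columns(spec, x, fit$info$levels_kept)))
  c(row, rep(0, fit$n_covariates))
}

#' Contrast weights for the dose-response difference
#'
#' Returns the vector `c` such that `c' beta_hat` estimates
#' `E[Y|X=x] - E[Y|X=reference]`, built as the difference of the design
#' rows at `x` and at the reference dose. Covariate entries are zero.
#'
#' @param fit a `"dr_fit"` from [fit_model()].
#' @param x a single dose.
#' @param reference the reference dose; defaults to the fit's own
#'   reference (0, or the minimum observed positive dose for strategies
#'   that exclude the zero-dose group).
#' @return Named numeric vector of length `length(coef(fit))`, or `NULL`
#'   if `x` is not representable under this fit.
#' @export
dose_contrast <- function(fit, x, reference = NULL) {
  stopifnot(inherits(fit, "dr_fit"))
  if (is.null(reference)) reference <- reference_dose(fit)
  if (fit$spec$exclude_zero_dose && reference < fit$info$min_pos_dose)
    stop("invalid reference: dose ", reference, " is below the minimum ",
         "observed positive dose for a strategy that excludes the ",
         "zero-dose group", call. = FALSE)
  rx <- design_row_at(fit, x)
  rr <- design_row_at(fit, reference)
  if (is.null(rx) || is.null(rr)) return(NULL)
  stats::setNames(rx - rr, names(fit$coefficients))
}

#' Reference dose of a fitted strategy
#'
#' @param fit a `"dr_fit"`.
#' @return 0, or the minimum observed positive dose if the strategy's
#'   reference rule is `"minimum_observed_positive"`.
#' @export
reference_dose <- function(fit) {
  if (fit$spec$reference_rule == "minimum_observed_positive")
    fit$info$min_pos_dose else 0
}

#' Estimated dose-response curve with pointwise confidence bands
#'
#' Evaluates the estimated dose-response contrast relative to the fit's
#' reference dose over a grid, with delta-method standard errors from the
#' robust covariance and normal-quantile pointwise confidence limits.
#' Grid points the fit cannot represent (see [dose_contrast()]) are
#' returned with `NA` estimates rather than aborting.
#'
#' @param fit a `"dr_fit"` from [fit_model()].
#' @param grid numeric vector of nonnegative doses.
#' @param level confidence level (default 0.95).
#' @param reference override the fit's reference dose.
#' @return A data frame of class `"dr_curve"` with columns `dose`,
#'   `estimate`, `se`, `ci_lower`, `ci_upper`, `reference_dose`,
#'   `model_label`.
#' @export
delta_curve <- function(fit, grid, level = 0.95, reference = NULL) {
  stopifnot(inherits(fit, "dr_fit"), level > 0, level < 1)
  grid <- check_doses(grid, "grid dose")
  if (is.null(reference)) reference <- reference_dose(fit)
  beta <- fit$coefficients
  V <- fit$robust_vcov
  est <- se <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    cc <- dose_contrast(fit, grid[i], reference)
    if (is.null(cc)) next
    est[i] <- sum(cc * beta)
    se[i] <- sqrt(max(0, drop(cc %*% V %*% cc)))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(data.frame(dose = grid, estimate = est, se = se,
                       ci_lower = est - z * se, ci_upper = est + z * se,
                       reference_dose = reference,
                       model_label = fit$spec$label),
            class = c("dr_curve", "data.frame"), level = level)
}
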