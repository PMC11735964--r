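#' Declarative specification of one modeling strategy
#'
#' A `dr_model_spec` records everything needed to build the design matrix
#' for one dose-response modeling strategy: the exposure representation,
#' whether a spike-at-zero indicator is included, knot or break locations,
#' whether zero-dose observations are excluded, and which dose serves as
#' the reference for the dose-response contrast.
#'
#' @param strategy_id integer 1-9 identifying the strategy in the catalog.
#' @param label short human-readable description.
#' @param exposure_form one of `"linear"`, `"quadratic"`, `"categorical"`,
#'   `"ncs"`, `"slab_spline"`.
#' @param include_spike add a spike-at-zero indicator column?
#' @param knots [knot_set()] (or numeric vector) for spline forms.
#' @param breaks break values for the categorical form.
#' @param exclude_zero_dose drop zero-dose rows before fitting?
#' @param reference_rule `"zero_dose"` (the default) or
#'   `"minimum_observed_positive"`, which makes the dose-response contrast
#'   relative to the smallest positive dose seen in the fitted data.
#' @return An object of class `"dr_model_spec"`.
#' @export
model_spec <- function(strategy_id, label, exposure_form,
                       include_spike = FALSE, knots = NULL, breaks = NULL,
                       exclude_zero_dose = FALSE,
                       reference_rule = c("zero_dose",
                                          "minimum_observed_positive")) {
  exposure_form <- match.arg(exposure_form,
                             c("linear", "quadratic", "categorical",
                               "ncs", "slab_spline"))
  reference_rule <- match.arg(reference_rule)
  if (exposure_form %in% c("ncs", "slab_spline")) {
    if (is.null(knots)) stop("spline strategies require knots", call. = FALSE)
    knots <- as_knot_set(knots)
  }
  if (exposure_form == "categorical") {
    if (is.null(breaks)) stop("categorical strategy requires breaks",
                              call. = FALSE)
    if (include_spike)
      stop("categorical strategies cannot include a spike: ",
           "dose zero is already its own category", call. = FALSE)
  }
  if (exclude_zero_dose && reference_rule != "minimum_observed_positive")
    stop("excluding zero doses requires reference_rule = ",
         "'minimum_observed_positive'", call. = FALSE)
  structure(list(strategy_id = as.integer(strategy_id), label = label,
                 exposure_form = exposure_form,
                 include_spike = isTRUE(include_spike),
                 knots = knots, breaks = breaks,
                 exclude_zero_dose = isTRUE(exclude_zero_dose),
                 reference_rule = reference_rule),
            class = "dr_model_spec")
}

#' @export
print.dr_model_spec <- function(x, ...) {
  cat(sprintf("strategy %d: %s\n", x$strategy_id, x$label))
  invisible(x)
}

#' The catalog of nine dose-response modeling strategies
#'
#' Returns the nine strategies compared by the simulation engine:
#' \enumerate{
#'   \item simple linear model, no spike;
#'   \item linear model with a spike at zero;
#'   \item quadratic model with a spike at zero (correctly specified for
#'     the bundled generating mechanism);
#'   \item dose categorized as 0, (0, 1/3], (1/3, 2/3] and >2/3;
#'   \item natural cubic spline, knots 1/8, 1/2, 7/8, no spike;
#'   \item natural cubic spline, knots 1/8, 1/2, 7/8, with a spike;
#'   \item natural cubic spline, knots 1/3, 1/2, 2/3, with a spike;
#'   \item slab-and-spline, knots 7/16, 5/8, 13/16: a spike at zero plus
#'     the derivative-constrained spline of [slab_spline_basis()], so the
#'     exposed-group curve is a constant slab over (0, 7/16) joining the
#'     spline at the first knot (one parameter fewer than strategy 6);
#'   \item natural cubic spline fitted to positive doses only (zero-dose
#'     rows excluded), contrasts relative to the minimum observed positive
#'     dose.
#' }
#'
#' @param knot_scale multiply all printed knot and break fractions by this
#'   value (e.g. the dose-scale parameter of a scenario). Default 1 keeps
#'   the literal values above.
#' @return A named list of nine [model_spec()] objects.
#' @export
catalog_models <- function(knot_scale = 1) {
  stopifnot(is.numeric(knot_scale), knot_scale > 0)
  s <- knot_scale
  specs <- list(
    model_spec(1L, "linear, no spike", "linear"),
    model_spec(2L, "linear + spike", "linear", include_spike = TRUE),
    model_spec(3L, "quadratic + spike", "quadratic", include_spike = TRUE),
    model_spec(4L, "categorical", "categorical", breaks = s * c(1/3, 2/3)),
    model_spec(5L, "ncs(1/8,1/2,7/8), no spike", "ncs",
               knots = s * c(1/8, 1/2, 7/8)),
    model_spec(6L, "ncs(1/8,1/2,7/8) + spike", "ncs",
               include_spike = TRUE, knots = s * c(1/8, 1/2, 7/8)),
    model_spec(7L, "ncs(1/3,1/2,2/3) + spike", "ncs",
               include_spike = TRUE, knots = s * c(1/3, 1/2, 2/3)),
    model_spec(8L, "slab-and-spline(7/16,5/8,13/16)", "slab_spline",
               include_spike = TRUE, knots = s * c(7/16, 5/8, 13/16)),
    model_spec(9L, "ncs(1/8,1/2,7/8), zero doses excluded", "ncs",
               knots = s * c(1/8, 1/2, 7/8), exclude_zero_dose = TRUE,
               reference_rule = "minimum_observed_positive")
  )
  names(specs) <- paste0("strategy", vapply(specs, `[[`, 1L, "strategy_id"))
  specs
}

# Exposure columns (everything between the spike column and covariates)
# for one spec at arbitrary doses. `levels_kept` pins the categorical
# dummy columns to the levels that were occupied in the fitted data.
exposure_columns <- function(spec, x, levels_kept = NULL) {
  switch(spec$exposure_form,
    linear = matrix(x, ncol = 1L, dimnames = list(NULL, "dose")),
    quadratic = cbind(dose = x, `dose^2` = x^2),
    categorical = {
      f <- dose_categories(x, spec$breaks)
      all_dummy <- levels(f)[-1L]  # zero-dose level is the reference
      keep <- if (is.null(levels_kept)) all_dummy else levels_kept
      m <- vapply(keep, function(l) as.numeric(f == l), numeric(length(x)))
      matrix(m, nrow = length(x), dimnames = list(NULL, keep))
    },
    ncs = as.matrix(ncs_basis(x, spec$knots,
                              anchor_at_zero = spec$include_spike)),
    slab_spline = as.matrix(slab_spline_basis(x, spec$knots,
                                              anchor_at_zero = TRUE))
  )
}

#' Build the design matrix for a modeling strategy
#'
#' Assembles intercept, optional spike-at-zero column, exposure columns
#' and optional covariates, in that order. Spline bases are anchored at
#' zero whenever a spike is included, so zero-dose rows reduce to the
#' intercept (plus covariates). For strategies that exclude zero-dose
#' observations the full data are passed in and the returned row mask
#' records which rows enter the fit.
#'
#' @param spec a [model_spec()].
#' @param x numeric vector of nonnegative doses (full data).
#' @param covariates optional data frame or matrix of numeric covariates.
#' @return A list with elements `X` (the design matrix, labeled columns),
#'   `keep` (logical row mask), and `info` (categorical levels kept and
#'   dropped, minimum observed positive dose).
#' @export
build_design <- function(spec, x, covariates = NULL) {
  x <- check_doses(x)
  keep <- if (spec$exclude_zero_dose) x > 0 else rep(TRUE, length(x))
  if (spec$exclude_zero_dose && !any(keep))
    stop("insufficient data: no positive doses to fit after excluding ",
         "the zero-dose group", call. = FALSE)
  xk <- x[keep]
  info <- list(min_pos_dose = if (any(xk > 0)) min(xk[xk > 0]) else NA_real_,
               levels_kept = NULL, levels_dropped = character(0))
  if (spec$exposure_form == "categorical") {
    f <- dose_categories(xk, spec$breaks)
    occ <- levels(f)[tabulate(f, nbins = nlevels(f)) > 0L]
    info$levels_kept <- setdiff(occ, levels(f)[1L])
    info$levels_dropped <- setdiff(levels(f)[-1L], info$levels_kept)
  }
  parts <- list(`(Intercept)` = rep(1, length(xk)))
  if (spec$include_spike) parts$spike <- spike_indicator(xk)
  expo <- exposure_columns(spec, xk, info$levels_kept)
  X <- cbind(do.call(cbind, parts), expo)
  colnames(X)[seq_along(parts)] <- names(parts)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != length(x))
      stop("invalid input: covariates must have one row per dose",
           call. = FALSE)
    X <- cbind(X, cv[keep, , drop = FALSE])
  }
  if (nrow(X) > ncol(X)) {  # rank is only diagnosable with n > p
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
      stop("collinear design: column(s) ", paste(bad, collapse = ", "),
           " are linearly dependent on the others", call. = FALSE)
    }
  }
  list(X = X, keep = keep, info = info)
}

#' Ordinary least squares on an explicit design matrix
#'
#' @param design numeric design matrix with labeled columns (include the
#'   intercept column explicitly).
#' @param y numeric outcome vector, one entry per design row.
#' @return A `"dr_ols"` object: coefficients, residuals, fitted values,
#'   the residual standard deviation `sigma_hat`, and the underlying
#'   [stats::lm] fit (used for sandwich covariance computation).
#' @export
fit_ols <- function(design, y) {
  design <- as.matrix(design)
  if (nrow(design) != length(y))
    stop("invalid input: design has ", nrow(design), " rows but y has ",
         length(y), " observations", call. = FALSE)
  if (nrow(design) <= ncol(design))
    stop("insufficient data: ", nrow(design), " observations for ",
         ncol(design), " coefficients", call. = FALSE)
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(design))]]
    stop("collinear design: column(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lmfit <- stats::lm(y ~ 0 + design)
  beta <- stats::coef(lmfit)
  names(beta) <- colnames(design)
  res <- stats::residuals(lmfit)
  structure(list(coefficients = beta,
                 residuals = res,
                 fitted = stats::fitted(lmfit),
                 sigma_hat = sqrt(sum(res^2) / (nrow(design) -
                                                  ncol(design))),
                 n_obs = nrow(design),
                 design_labels = colnames(design),
                 lm = lmfit),
            class = "dr_ols")
}

#' Huber-White and cluster-robust sandwich covariance
#'
#' Heteroskedasticity-consistent covariance of the OLS coefficients,
#' computed with the \pkg{sandwich} package. Without clusters this is the
#' Huber-White estimator (HC1 small-sample scaling by default, plain HC0
#' selectable). With `cluster` the meat sums score contributions within
#' clusters; HC1 then applies the usual G/(G-1) x (n-1)/(n-p) factor,
#' while HC0 is the uncorrected cluster sandwich (which for all-singleton
#' clusters coincides exactly with the observation-level HC0).
#'
#' @param fit a `"dr_ols"` object from [fit_ols()].
#' @param cluster optional vector of cluster identifiers, one per
#'   observation.
#' @param type `"HC1"` (default) or `"HC0"`.
#' @return Symmetric covariance matrix with coefficient labels.
#' @export
robust_covariance <- function(fit, cluster = NULL, type = c("HC1", "HC0")) {
  stopifnot(inherits(fit, "dr_ols"))
  type <- match.arg(type)
  if (is.null(cluster)) {
    V <- sandwich::vcovHC(fit$lm, type = type)
  } else {
    if (length(cluster) != fit$n_obs)
      stop("invalid input: cluster ids (", length(cluster),
           ") do not match the number of observations (", fit$n_obs, ")",
           call. = FALSE)
    V <- sandwich::vcovCL(fit$lm, cluster = cluster, type = type,
                          cadjust = (type == "HC1"))
  }
  dimnames(V) <- list(fit$design_labels, fit$design_labels)
  V
}

#' Fit one modeling strategy to dose-outcome data
#'
#' Convenience wrapper: builds the design with [build_design()], fits by
#' [fit_ols()], and attaches the robust covariance from
#' [robust_covariance()]. The result carries everything needed by
#' [delta_curve()].
#'
#' @inheritParams build_design
#' @param y numeric outcome vector (full data; rows dropped by the spec's
#'   row mask are removed internally).
#' @param cluster optional cluster identifiers (full data).
#' @param hc_type `"HC1"` or `"HC0"` sandwich scaling.
#' @return A `"dr_fit"` object.
#' @export
fit_model <- function(spec, x, y, covariates = NULL, cluster = NULL,
                      hc_type = c("HC1", "HC0")) {
  stopifnot(inherits(spec, "dr_model_spec"))
  hc_type <- match.arg(hc_type)
  if (length(x) != length(y))
    stop("invalid input: dose and outcome lengths differ", call. = FALSE)
  des <- build_design(spec, x, covariates)
  ols <- fit_ols(des$X, y[des$keep])
  cl <- if (!is.null(cluster)) cluster[des$keep]
  V <- robust_covariance(ols, cluster = cl, type = hc_type)
  n_cov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  structure(list(spec = spec, ols = ols,
                 coefficients = ols$coefficients,
                 robust_vcov = V,
                 sigma_hat = ols$sigma_hat,
                 n_obs = ols$n_obs,
                 n_covariates = n_cov,
                 keep = des$keep, info = des$info,
                 cluster_count = if (!is.null(cl)) length(unique(cl))),
            class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("dose-response fit, strategy %d (%s), n = %d\n",
              x$spec$strategy_id, x$spec$label, x$n_obs))
  se <- sqrt(diag(x$robust_vcov))
  print(cbind(estimate = x$coefficients, robust_se = se))
  invisible(x)
}

#' Coefficient table of a fitted strategy
#'
#' @param fit a `"dr_fit"`.
#' @return Data frame with columns `term`, `estimate`, `robust_se`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "dr_fit"))
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             robust_se = sqrt(diag(fit$robust_vcov)),
             row.names = NULL)
}
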