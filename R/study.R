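#' Default dose evaluation grid for a scenario
#'
#' Three fixed low doses (0.01, 0.025, 0.05) that probe behavior near the
#' origin, plus 19 evenly spaced doses from `0.05 * gamma_X` to
#' `0.95 * gamma_X` covering the bulk of the dose support.
#'
#' @param config a [scenario_config()].
#' @return Strictly increasing vector of positive doses.
#' @export
default_grid <- function(config) {
  stopifnot(inherits(config, "dr_scenario"))
  g <- config$gamma_X
  sort(unique(c(0.01, 0.025, 0.05, seq(0.05 * g, 0.95 * g, length.out = 19))))
}

#' One Monte-Carlo replicate: fit every strategy, evaluate the curve
#'
#' Draws one sample from the scenario, fits each strategy, and evaluates
#' the estimated dose-response contrast and its robust standard error on
#' the grid. A strategy that fails to fit (e.g. a collinear design in a
#' degenerate draw) is recorded with `NA` estimates and a reason code
#' rather than aborting. The per-point truth accounts for each strategy's
#' own reference dose (for the zero-exclusion strategy the truth is
#' `delta(x) - delta(x_min)` with that replicate's minimum observed
#' positive dose).
#'
#' @param config a [scenario_config()].
#' @param specs list of [model_spec()] objects.
#' @param grid dose grid; defaults to [default_grid()].
#' @param hc_type sandwich scaling passed to [fit_model()].
#' @return Long data frame: one row per strategy x grid dose with columns
#'   `strategy`, `model_label`, `dose`, `estimate`, `se`, `truth`,
#'   `fail_reason`, plus per-strategy coefficient and sigma estimates in
#'   the `"fits"` attribute.
#' @export
run_replicate <- function(config, specs = catalog_models(),
                          grid = default_grid(config),
                          hc_type = c("HC1", "HC0")) {
  hc_type <- match.arg(hc_type)
  dat <- simulate_sample(config)
  out <- vector("list", length(specs))
  fits <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    spec <- specs[[j]]
    res <- tryCatch({
      fit <- fit_model(spec, dat$dose, dat$outcome, hc_type = hc_type)
      crv <- delta_curve(fit, grid)
      ref <- reference_dose(fit)
      truth <- true_delta(grid, config) - true_delta(ref, config)
      truth[is.na(crv$estimate)] <- NA_real_
      fits[[j]] <- list(coefficients = fit$coefficients,
                        sigma_hat = fit$sigma_hat)
      data.frame(strategy = spec$strategy_id, model_label = spec$label,
                 dose = grid, estimate = crv$estimate, se = crv$se,
                 truth = truth, fail_reason = NA_character_)
    }, error = function(e) {
      data.frame(strategy = spec$strategy_id, model_label = spec$label,
                 dose = grid, estimate = NA_real_, se = NA_real_,
                 truth = NA_real_, fail_reason = conditionMessage(e))
    })
    out[[j]] <- res
  }
  structure(do.call(rbind, out), fits = fits)
}

new_accumulator <- function() {
  list(n = 0, sum = 0, sumsq = 0)
}

# `ok` is a vector over grid points, or a single TRUE for whole-vector
# coefficient updates; contributions outside `ok` count as zero
acc_add <- function(acc, v, ok) {
  okv <- rep_len(ok, length(v))
  v <- ifelse(okv & !is.na(v), v, 0)
  acc$n <- acc$n + ok
  acc$sum <- acc$sum + v
  acc$sumsq <- acc$sumsq + v^2
  acc
}

# n may be a scalar (coefficient accumulators) or a per-grid-point vector
acc_mean <- function(acc) {
  m <- acc$sum / pmax(acc$n, 1)
  m[rep_len(acc$n == 0, length(m))] <- NA_real_
  m
}

acc_sd <- function(acc) {
  v <- (acc$sumsq - acc$sum^2 / pmax(acc$n, 1)) / pmax(acc$n - 1, 1)
  s <- sqrt(pmax(v, 0))
  s[rep_len(acc$n < 2, length(s))] <- NA_real_
  s
}

#' Run a full Monte-Carlo scenario
#'
#' Repeats [run_replicate()] `M` times and aggregates, per strategy and
#' grid dose: the mean estimate, bias, empirical standard error (the SD
#' of the estimates across replicates), average model-based standard
#' error, and the coverage of nominal-level intervals
#' `estimate +/- 1.96 * se` against the true contrast. Replicates where a
#' strategy failed or a grid point was unrepresentable are excluded from
#' that cell's aggregation; the contributing count is reported.
#' Aggregation is streaming (sums and sums of squares), so full-scale
#' runs need no replicate storage.
#'
#' Reproducibility: the master `seed` generates one sub-seed per
#' replicate, and each replicate re-seeds from its own sub-seed, so any
#' replicate can be reproduced independently and results do not depend on
#' execution order.
#'
#' @inheritParams run_replicate
#' @param M number of replicates; defaults to `config$M`.
#' @param seed master seed; `NULL` leaves the RNG state untouched.
#' @param z critical value defining the intervals whose coverage is
#'   tracked (1.96 for nominal 95%).
#' @param verbose print a progress line every 100 replicates?
#' @return A `"dr_metrics"` data frame: one row per strategy x grid dose
#'   with columns `strategy`, `model_label`, `dose`, `truth`,
#'   `mean_estimate`, `bias`, `empirical_se`, `average_se`, `coverage`,
#'   `n_reps`. Attributes: `coef_summary` (per-strategy coefficient
#'   means, SDs and Monte-Carlo standard errors, plus `sigma_hat`),
#'   `n_failures` (failed fits per strategy), `config`.
#' @export
run_scenario <- function(config, specs = catalog_models(),
                         grid = default_grid(config), M = config$M,
                         seed = NULL, hc_type = c("HC1", "HC0"),
                         z = 1.96, verbose = FALSE) {
  stopifnot(inherits(config, "dr_scenario"), M >= 2)
  hc_type <- match.arg(hc_type)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, M)
  ns <- length(specs)
  ng <- length(grid)
  est_acc <- se_acc <- replicate(ns, new_accumulator(), simplify = FALSE)
  for (j in seq_len(ns)) {
    est_acc[[j]] <- list(n = numeric(ng), sum = numeric(ng),
                         sumsq = numeric(ng))
    se_acc[[j]] <- est_acc[[j]]
  }
  cover <- matrix(0, ns, ng)
  truth_sum <- matrix(0, ns, ng)
  coef_acc <- vector("list", ns)
  sigma_acc <- replicate(ns, new_accumulator(), simplify = FALSE)
  n_fail <- integer(ns)
  for (m in seq_len(M)) {
    set.seed(sub_seeds[m])
    rep <- run_replicate(config, specs, grid, hc_type)
    fits <- attr(rep, "fits")
    for (j in seq_len(ns)) {
      rows <- rep[rep$strategy == specs[[j]]$strategy_id, ]
      ok <- !is.na(rows$estimate)
      if (!is.na(rows$fail_reason[1L])) n_fail[j] <- n_fail[j] + 1L
      est_acc[[j]] <- acc_add(est_acc[[j]], rows$estimate, ok)
      se_acc[[j]] <- acc_add(se_acc[[j]], rows$se, ok)
      hit <- ok & !is.na(rows$truth) &
        abs(rows$estimate - rows$truth) <= z * rows$se
      cover[j, ] <- cover[j, ] + ifelse(is.na(hit), FALSE, hit)
      truth_sum[j, ] <- truth_sum[j, ] + ifelse(ok, rows$truth, 0)
      f <- fits[[j]]
      if (!is.null(f)) {
        if (is.null(coef_acc[[j]]))
          coef_acc[[j]] <- list(n = 0,
                                sum = 0 * f$coefficients,
                                sumsq = 0 * f$coefficients)
        # coefficient labels can differ across replicates if a dose
        # category was empty; only pool replicates on the modal design
        if (identical(names(f$coefficients), names(coef_acc[[j]]$sum))) {
          coef_acc[[j]] <- acc_add(coef_acc[[j]], f$coefficients, TRUE)
          sigma_acc[[j]] <- acc_add(sigma_acc[[j]], f$sigma_hat, TRUE)
        }
      }
    }
    if (verbose && m %% 100 == 0)
      message("replicate ", m, "/", M)
  }
  metrics <- do.call(rbind, lapply(seq_len(ns), function(j) {
    n_ok <- est_acc[[j]]$n
    data.frame(strategy = specs[[j]]$strategy_id,
               model_label = specs[[j]]$label,
               dose = grid,
               truth = ifelse(n_ok > 0, truth_sum[j, ] / n_ok, NA_real_),
               mean_estimate = acc_mean(est_acc[[j]]),
               bias = acc_mean(est_acc[[j]]) -
                 ifelse(n_ok > 0, truth_sum[j, ] / n_ok, NA_real_),
               empirical_se = acc_sd(est_acc[[j]]),
               average_se = acc_mean(se_acc[[j]]),
               coverage = ifelse(n_ok > 0, cover[j, ] / n_ok, NA_real_),
               n_reps = n_ok)
  }))
  coef_summary <- do.call(rbind, lapply(seq_len(ns), function(j) {
    ca <- coef_acc[[j]]
    if (is.null(ca)) return(NULL)
    terms <- c(names(ca$sum), "sigma_hat")
    mean_v <- c(acc_mean(ca), acc_mean(sigma_acc[[j]]))
    sd_v <- c(acc_sd(ca), acc_sd(sigma_acc[[j]]))
    nrep <- c(rep(ca$n, length(ca$sum)), sigma_acc[[j]]$n)
    data.frame(strategy = specs[[j]]$strategy_id,
               model_label = specs[[j]]$label, term = terms,
               mean = unname(mean_v), sd = unname(sd_v),
               mcse = unname(sd_v / sqrt(nrep)), n_reps = nrep,
               row.names = NULL)
  }))
  structure(metrics, coef_summary = coef_summary, n_failures = n_fail,
            config = config, class = c("dr_metrics", "data.frame"))
}

#' Coefficient summary of a scenario run
#'
#' @param metrics a `"dr_metrics"` object from [run_scenario()].
#' @return Data frame with per-strategy coefficient means, SDs and
#'   Monte-Carlo standard errors of the mean (term `sigma_hat` summarizes
#'   the residual SD estimate).
#' @export
coef_summary <- function(metrics) {
  stopifnot(inherits(metrics, "dr_metrics"))
  attr(metrics, "coef_summary")
}
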