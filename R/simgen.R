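#' Scenario configuration for the simulation engine
#'
#' Bundles the data-generating mechanism: the dose is 0 with probability
#' `p_zero` and otherwise `gamma_X * Beta(alpha_X, beta_X)`; the outcome
#' follows the quadratic spike model
#' `Y = intercept + beta1 * 1(X > 0) + slope * X + quad * X^2 + eps` with
#' `eps ~ N(0, sigma_Y^2)`.
#'
#' Two bundled dose scenarios are provided: scenario 1
#' (`alpha_X = 1, beta_X = 5, gamma_X = 2`; doses dense near zero) and
#' scenario 2 (`alpha_X = 6, beta_X = 5, gamma_X = 1`; doses sparse near
#' zero). The spike effect is `beta1 = 0.5` when `spike = TRUE` and 0
#' otherwise.
#'
#' @param dose_scenario 1 or 2, selecting the bundled dose distribution;
#'   ignored for any parameter you set explicitly.
#' @param spike does the outcome mechanism include a spike at zero?
#' @param p_zero probability mass at dose 0.
#' @param alpha_X,beta_X Beta shape parameters of the positive dose part.
#' @param gamma_X dose scale: positive doses live on (0, gamma_X).
#' @param beta1 true spike effect (outcome units).
#' @param intercept,slope,quad polynomial outcome coefficients.
#' @param sigma_Y error standard deviation (outcome units).
#' @param N sample size per replicate.
#' @param M number of Monte-Carlo replicates.
#' @return An object of class `"dr_scenario"`.
#' @export
scenario_config <- function(dose_scenario = 1, spike = TRUE,
                            p_zero = 0.25,
                            alpha_X = c(1, 6)[dose_scenario],
                            beta_X = 5,
                            gamma_X = c(2, 1)[dose_scenario],
                            beta1 = if (spike) 0.5 else 0,
                            intercept = 10, slope = -2.4, quad = 4.8,
                            sigma_Y = 1.5, N = 1000, M = 5000) {
  if (!dose_scenario %in% c(1, 2))
    stop("invalid config: dose_scenario must be 1 or 2", call. = FALSE)
  if (p_zero < 0 || p_zero > 1)
    stop("invalid config: p_zero must lie in [0, 1]", call. = FALSE)
  for (nm in c("alpha_X", "beta_X", "gamma_X", "sigma_Y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 ||
        (nm != "sigma_Y" && v == 0))
      stop("invalid config: ", nm, " must be positive", call. = FALSE)
  }
  if (N < 1 || M < 1)
    stop("invalid config: N and M must be at least 1", call. = FALSE)
  structure(list(dose_scenario = as.integer(dose_scenario),
                 p_zero = p_zero, alpha_X = alpha_X, beta_X = beta_X,
                 gamma_X = gamma_X, beta1 = beta1, intercept = intercept,
                 slope = slope, quad = quad, sigma_Y = sigma_Y,
                 N = as.integer(N), M = as.integer(M)),
            class = "dr_scenario")
}

#' @export
print.dr_scenario <- function(x, ...) {
  cat(sprintf(paste0("dose scenario %d: X = 0 w.p. %.3g, else %.3g * ",
                     "Beta(%.3g, %.3g); spike beta1 = %.3g; N = %d, M = %d\n"),
              x$dose_scenario, x$p_zero, x$gamma_X, x$alpha_X, x$beta_X,
              x$beta1, x$N, x$M))
  invisible(x)
}

#' Draw semicontinuous doses
#'
#' Each dose is independently 0 with probability `p_zero`, otherwise
#' `gamma_X` times a `Beta(alpha_X, beta_X)` draw. A Beta draw that
#' underflows to exactly 0 (possible only for `alpha_X < 1`, with
#' probability ~0) is redrawn so that the exposure indicator `1(X > 0)`
#' identifies the mixture arm exactly.
#'
#' @param n number of draws.
#' @param config a [scenario_config()].
#' @return Numeric vector of doses in `[0, gamma_X]`.
#' @export
draw_doses <- function(n, config) {
  stopifnot(inherits(config, "dr_scenario"))
  zero <- stats::runif(n) < config$p_zero
  pos <- stats::rbeta(n, config$alpha_X, config$beta_X)
  while (any(pos == 0)) {
    i <- pos == 0
    pos[i] <- stats::rbeta(sum(i), config$alpha_X, config$beta_X)
  }
  ifelse(zero, 0, config$gamma_X * pos)
}

#' Draw outcomes from the quadratic spike mechanism
#'
#' @param x numeric vector of nonnegative doses.
#' @param config a [scenario_config()].
#' @return Numeric outcome vector of the same length.
#' @export
draw_outcomes <- function(x, config) {
  stopifnot(inherits(config, "dr_scenario"))
  x <- check_doses(x)
  mu <- config$intercept + config$beta1 * (x > 0) +
    config$slope * x + config$quad * x^2
  mu + stats::rnorm(length(x), 0, config$sigma_Y)
}

#' Draw one simulated sample (doses and outcomes)
#'
#' @param config a [scenario_config()].
#' @param n sample size; defaults to `config$N`.
#' @return Data frame with columns `dose` and `outcome`.
#' @export
simulate_sample <- function(config, n = config$N) {
  x <- draw_doses(n, config)
  data.frame(dose = x, outcome = draw_outcomes(x, config))
}

#' True dose-response contrast of the generating mechanism
#'
#' `delta(x) = E[Y|X=x] - E[Y|X=0]`, which is 0 at `x = 0` and
#' `beta1 + slope*x + quad*x^2` for positive doses.
#'
#' @param x nonnegative doses.
#' @param config a [scenario_config()].
#' @return Numeric vector of true contrasts (outcome units).
#' @export
true_delta <- function(x, config) {
  stopifnot(inherits(config, "dr_scenario"))
  x <- check_doses(x)
  ifelse(x == 0, 0, config$beta1 + config$slope * x + config$quad * x^2)
}

#' Synthetic claims-like fixture for the model-fitting front end
#'
#' Generates a synthetic table shaped like an administrative pharmacy
#' claims analysis of opioid dosing: a semicontinuous exposure on a
#' morphine-milligram-equivalent-like scale (a large point mass at zero
#' and a right-skewed positive part in multiples of 7.5 MME), a
#' semicontinuous outcome, a patient cluster id (a configurable fraction
#' of rows reuse an earlier patient's id, emulating repeat deliveries and
#' exercising cluster-robust standard errors), and two numeric covariates
#' (`age`, `parity`). The table is entirely synthetic: distributional
#' shapes are qualitative and no real cohort's moments are targeted.
#'
#' @param n_patients number of rows.
#' @param repeat_fraction fraction of rows whose cluster id repeats an
#'   earlier row's id (0 gives all-unique ids).
#' @param zero_fraction probability of a zero exposure dose.
#' @param path optional CSV output path; the file gets a commented
#'   metadata header (`#` lines) recording the generator settings.
#' @return The data frame, invisibly when `path` is given.
#' @export
generate_applied_fixture <- function(n_patients = 2000,
                                     repeat_fraction = 0.1,
                                     zero_fraction = 0.412,
                                     path = NULL) {
  stopifnot(n_patients >= 1, repeat_fraction >= 0, repeat_fraction < 1,
            zero_fraction >= 0, zero_fraction < 1)
  n <- as.integer(n_patients)
  dose <- ifelse(stats::runif(n) < zero_fraction, 0,
                 7.5 * (1 + stats::rnbinom(n, size = 3, mu = 20)))
  age <- round(stats::rnorm(n, 26, 5.5))
  parity <- stats::rpois(n, 1)
  # outcome: zero-inflated, positive part increasing in initial dose with
  # a spike for any exposure
  mu_out <- 20 + 15 * (dose > 0) + 0.25 * dose + 0.5 * (age - 26)
  any_out <- stats::runif(n) < stats::plogis(-1.2 + 0.004 * dose)
  outcome <- ifelse(any_out,
                    pmax(0, mu_out + stats::rnorm(n, 0, 25)), 0)
  n_rep <- floor(repeat_fraction * n)
  n_base <- n - n_rep
  cluster <- c(seq_len(n_base),
               if (n_rep > 0) sample.int(n_base, n_rep, replace = TRUE))
  df <- data.frame(dose = dose, outcome = round(outcome, 1),
                   cluster = cluster, age = age, parity = parity)
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# synthetic claims-like fixture (no real data)",
                 sprintf("# n_patients=%d repeat_fraction=%g zero_fraction=%g",
                         n, repeat_fraction, zero_fraction)), con)
    utils::write.csv(df, con, row.names = FALSE)
    return(invisible(df))
  }
  df
}
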