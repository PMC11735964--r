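test_that("the catalog enumerates the nine strategies correctly", {
  specs <- catalog_models()
  expect_length(specs, 9L)
  expect_equal(vapply(specs, `[[`, 1L, "strategy_id"), 1:9,
               ignore_attr = TRUE)
  expect_false(specs[[1]]$include_spike)
  expect_true(specs[[2]]$include_spike)
  expect_equal(specs[[3]]$exposure_form, "quadratic")
  expect_equal(specs[[4]]$breaks, c(1/3, 2/3))
  expect_equal(specs[[6]]$knots$knots, c(1/8, 1/2, 7/8))
  expect_equal(specs[[7]]$knots$knots, c(1/3, 1/2, 2/3))
  # slab region runs from 0 up to the lower boundary knot 7/16
  expect_equal(specs[[8]]$exposure_form, "slab_spline")
  expect_equal(specs[[8]]$knots$lower_boundary, 7/16)
  expect_true(specs[[9]]$exclude_zero_dose)
  expect_equal(specs[[9]]$reference_rule, "minimum_observed_positive")
  expect_true(all(!vapply(specs[1:8], `[[`, TRUE, "exclude_zero_dose")))
  # knot rescaling
  s2 <- catalog_models(knot_scale = 2)
  expect_equal(s2[[6]]$knots$knots, c(1/4, 1, 7/4))
  expect_equal(s2[[4]]$breaks, c(2/3, 4/3))
})

test_that("design matrices have the documented column layout", {
  specs <- catalog_models()
  d2 <- build_design(specs[[2]], c(0, 1))
  expect_identical(unname(d2$X), matrix(c(1, 0, 0, 1, 1, 1), 2,
                                        byrow = TRUE))
  expect_identical(colnames(d2$X), c("(Intercept)", "spike", "dose"))
  # categorical at dose zero: only the intercept is active
  d4 <- build_design(specs[[4]], c(0, 0.2, 0.5, 0.9))
  expect_equal(unname(d4$X[1, ]), c(1, 0, 0, 0))
  # zero-exclusion strategy drops exactly the zero-dose rows
  x <- c(0, 0.4, 0, 1.2, 0.7)
  d9 <- build_design(specs[[9]], x)
  expect_identical(d9$keep, x > 0)
  expect_equal(d9$info$min_pos_dose, 0.4)
  # spiked spline designs are anchored: zero-dose rows intercept-only
  d6 <- build_design(specs[[6]], c(0, 0, 0.3))
  expect_equal(unname(d6$X[1:2, -1]), matrix(0, 2, 3))
})

test_that("rank-deficient designs are reported with the offending column", {
  specs <- catalog_models()
  # all-zero doses make the spike column collinear with nothing to fit
  expect_error(build_design(specs[[2]], rep(0, 10)), "collinear")
  X <- cbind(a = rep(1, 10), b = 1:10, c = 2 * (1:10))
  expect_error(fit_ols(X, rnorm(10)), "collinear.*c")
})

test_that("fit_ols solves the normal equations", {
  set.seed(21)
  # exact interpolation of noiseless data
  X <- cbind(`(Intercept)` = 1, x = runif(50), z = rnorm(50))
  beta <- c(2, -1, 0.5)
  f <- fit_ols(X, drop(X %*% beta))
  expect_lt(max(abs(f$coefficients - beta)), 1e-10)
  # matches an explicit inverse on random problems
  for (i in 1:5) {
    X <- cbind(1, matrix(rnorm(40), 20, 2))
    colnames(X) <- c("i", "a", "b")
    y <- rnorm(20)
    bhat <- drop(solve(crossprod(X)) %*% crossprod(X, y))
    f <- fit_ols(X, y)
    expect_lt(max(abs(f$coefficients - bhat)), 1e-8)
    expect_lt(max(abs(crossprod(X, f$residuals))) / 20, 1e-8)
  }
  expect_error(fit_ols(X, rnorm(19)), "rows")
  expect_error(fit_ols(X[1:3, ], rnorm(3)), "insufficient")
})

test_that("spike models separate the zero-dose group exactly", {
  set.seed(31)
  cfg <- scenario_config(1, spike = TRUE)
  d <- simulate_sample(cfg, 400)
  zero_mean <- mean(d$outcome[d$dose == 0])
  for (id in c(2, 3, 6, 7, 8)) {
    spec <- catalog_models()[[id]]
    fit <- fit_model(spec, d$dose, d$outcome)
    # anchored design: zero-dose rows are intercept-only, so the
    # intercept equals the zero-group mean
    expect_lt(abs(fit$coefficients[["(Intercept)"]] - zero_mean), 1e-10)
    # and the positive-dose submodel is unaffected by the zero rows
    pos <- d$dose > 0
    des <- build_design(spec, d$dose)
    sub <- fit_ols(des$X[pos, -2, drop = FALSE], d$outcome[pos])
    expect_lt(max(abs(sub$coefficients[-1] -
                        fit$coefficients[-(1:2)])), 1e-8)
  }
})

test_that("sandwich covariance matches explicit matrix arithmetic", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(25:60, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    colnames(X) <- c("i", "a", "b")
    y <- rnorm(n, sd = exp(X[, 2] / 2))  # heteroskedastic
    f <- fit_ols(X, y)
    V0 <- robust_covariance(f, type = "HC0")
    expect_lt(max(abs(V0 - bf_hc0(X, f$residuals))), 1e-10)
    # HC1 is the HC0 matrix scaled by n/(n-p)
    V1 <- robust_covariance(f, type = "HC1")
    expect_equal(unname(V1), unname(V0) * n / (n - 3), tolerance = 1e-12)
  }
})

test_that("robust covariance is sane and PSD under homoskedasticity", {
  set.seed(51)
  X <- cbind(1, runif(1000))
  colnames(X) <- c("i", "x")
  y <- drop(X %*% c(1, 2)) + rnorm(1000)
  f <- fit_ols(X, y)
  V <- robust_covariance(f)
  expect_true(isSymmetric(V, tol = 1e-12))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-12))
  classical <- f$sigma_hat^2 * solve(crossprod(X))
  expect_lt(max(abs(sqrt(diag(V)) / sqrt(diag(classical)) - 1)), 0.15)
})

test_that("cluster-robust covariance sums scores within clusters", {
  set.seed(61)
  n <- 120
  cl <- sample(1:20, n, replace = TRUE)
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("i", "x")
  y <- rnorm(n) + rnorm(20)[cl]
  f <- fit_ols(X, y)
  V <- robust_covariance(f, cluster = cl, type = "HC0")
  expect_lt(max(abs(V - bf_cluster_hc0(X, f$residuals, cl))), 1e-10)
  # singleton clusters reduce exactly to the observation-level HC0 meat
  V_singleton <- robust_covariance(f, cluster = seq_len(n), type = "HC0")
  expect_lt(max(abs(V_singleton - robust_covariance(f, type = "HC0"))),
            1e-12)
  expect_error(robust_covariance(f, cluster = cl[-1]), "cluster ids")
})

test_that("model specs enforce their structural invariants", {
  expect_error(model_spec(5, "bad", "ncs"), "knots")
  expect_error(model_spec(4, "bad", "categorical", breaks = c(1, 2),
                          include_spike = TRUE), "own category")
  expect_error(model_spec(9, "bad", "ncs", knots = c(1, 2, 3),
                          exclude_zero_dose = TRUE), "minimum_observed")
})
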