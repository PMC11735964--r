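test_that("knot sets are validated", {
  expect_error(knot_set(c(0.5, 0.9)), "at least 3")
  expect_error(knot_set(c(0.5, 0.5, 0.9)), "strictly increasing")
  expect_error(knot_set(c(0.9, 0.5, 0.1)), "strictly increasing")
  expect_error(knot_set(c(-0.1, 0.5, 0.9)), "positive")
  ks <- knot_set(c(1/8, 1/2, 7/8))
  expect_equal(ks$lower_boundary, 1/8)
  expect_equal(ks$upper_boundary, 7/8)
})

test_that("ncs basis has natural-spline structure", {
  ks <- c(1/8, 1/2, 7/8)
  x <- seq(0, 2, length.out = 101)
  b <- ncs_basis(x, ks)
  expect_equal(ncol(b), 2L)  # K - 1 columns
  expect_true(all(is.finite(b)))
  # linear (zero second derivative) beyond both boundary knots
  fun <- function(z) ncs_basis(z, ks)
  for (z in c(1.2, 1.8, 0.02, 0.06)) {
    expect_lt(max(abs(num_deriv2(fun, z))), 1e-6)
  }
})

test_that("anchored basis columns vanish exactly at dose zero", {
  b <- ncs_basis(c(0, 0.3, 0, 1.1), c(1/8, 1/2, 7/8), anchor_at_zero = TRUE)
  expect_identical(unname(as.matrix(b)[c(1, 3), ]),
                   matrix(0, 2, ncol(b)))
  s <- slab_spline_basis(c(0, 0.6), c(7/16, 5/8, 13/16),
                         anchor_at_zero = TRUE)
  expect_identical(unname(as.matrix(s)[1, ]), rep(0, ncol(s)))
})

test_that("ncs basis spans the truncated-power natural spline space", {
  x <- seq(0, 1, length.out = 200)
  knot_sets <- list(c(1/8, 1/2, 7/8), c(1/3, 1/2, 2/3),
                    c(7/16, 5/8, 13/16), c(0.1, 0.3, 0.55, 0.9))
  set.seed(42)
  for (i in 1:6) knot_sets <- c(knot_sets, list(sort(runif(sample(3:6, 1),
                                                           0.05, 0.95))))
  for (ks in knot_sets) {
    b <- as.matrix(ncs_basis(x, ks))
    oracle <- tp_natural_basis(x, ks)
    expect_equal(ncol(b), ncol(oracle))
    # each span contains the other (up to intercept augmentation)
    expect_lt(max_projection_residual(oracle, b), 1e-8)
    expect_lt(max_projection_residual(b, oracle), 1e-8)
  }
})

test_that("spike indicator flags any positive dose", {
  expect_equal(spike_indicator(c(0, 0.2, 0)), c(0, 1, 0))
  expect_equal(spike_indicator(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(spike_indicator(1e-12), 1)
  expect_error(spike_indicator(c(0.1, -0.1)), "negative")
})

test_that("slab basis functions are constant left of the lower knot", {
  ks <- c(7/16, 5/8, 13/16)
  s <- slab_spline_basis(c(0, 0.1, 0.2, 0.43, 7/16), ks)
  for (j in seq_len(ncol(s))) {
    expect_lt(max(abs(s[, j] - s[1, j])), 1e-10)
  }
  # and any fitted function from it is constant there too
  set.seed(7)
  theta <- rnorm(ncol(s))
  vals <- as.matrix(s) %*% theta
  expect_lt(max(abs(vals - vals[1])), 1e-10)
})

test_that("slab basis joins the spline continuously differentiably", {
  ks <- c(7/16, 5/8, 13/16)
  fun <- function(z) slab_spline_basis(z, ks)
  k1 <- 7/16
  h <- 1e-5
  left <- (fun(k1) - fun(k1 - h)) / h
  right <- (fun(k1 + h) - fun(k1)) / h
  expect_lt(max(abs(left - right)), 1e-6)
  expect_lt(max(abs(num_deriv(fun, k1))), 1e-6)
})

test_that("slab basis has natural-spline df minus one", {
  for (ks in list(c(7/16, 5/8, 13/16), c(0.1, 0.3, 0.55, 0.9))) {
    nb <- ncs_basis(seq(0, 1, 0.01), ks)
    sb <- slab_spline_basis(seq(0, 1, 0.01), ks)
    expect_equal(ncol(sb), ncol(nb) - 1L)
    # slab columns lie inside the ncs span
    expect_lt(max_projection_residual(as.matrix(nb), as.matrix(sb)), 1e-8)
  }
})

test_that("slab fit equals constrained least squares on the ncs basis", {
  # oracle: in the truncated-power parametrization {1, x, D_k} the
  # derivative at the lower boundary knot is exactly the coefficient on
  # x, so the zero-slope constraint selects that single coefficient.
  set.seed(11)
  for (ks in list(c(7/16, 5/8, 13/16), c(0.15, 0.4, 0.7, 0.9))) {
    x <- c(runif(40, 0, 1), runif(20, 0, ks[1]))
    y <- sin(3 * x) + rnorm(60, 0, 0.3)
    Xtp <- cbind(1, tp_natural_basis(x, ks))
    C <- matrix(0, 1, ncol(Xtp)); C[1, 2] <- 1  # slope coefficient = 0
    oracle <- constrained_ols(Xtp, y, C)
    Xslab <- cbind(1, as.matrix(slab_spline_basis(x, ks)))
    fit <- lm.fit(Xslab, y)
    expect_lt(abs(sqrt(sum(fit$residuals^2)) - oracle$resid_norm), 1e-8)
  }
})

test_that("anchoring is an affine reparametrization: fits unchanged", {
  set.seed(5)
  x <- c(rep(0, 30), runif(120, 0, 2))
  y <- 10 + 0.5 * (x > 0) - 2.4 * x + 4.8 * x^2 + rnorm(150, 0, 1.5)
  for (builder in list(ncs_basis, slab_spline_basis)) {
    ks <- c(1/8, 1/2, 7/8)
    X1 <- cbind(1, spike_indicator(x), as.matrix(builder(x, ks, TRUE)))
    X2 <- cbind(1, spike_indicator(x), as.matrix(builder(x, ks, FALSE)))
    f1 <- lm.fit(X1, y)
    f2 <- lm.fit(X2, y)
    expect_lt(max(abs(f1$fitted.values - f2$fitted.values)), 1e-10)
  }
})

test_that("dose categories partition the nonnegative axis", {
  f <- dose_categories(c(0, 1/3, 0.9, 0.2, 2/3, 0.5), breaks = c(1/3, 2/3))
  expect_equal(as.integer(f) - 1L, c(0L, 1L, 3L, 1L, 2L, 2L))
  expect_equal(levels(f), c("0", "(0,0.3333333]", "(0.3333333,0.6666667]",
                            ">0.6666667"))
  set.seed(3)
  x <- c(0, runif(500, 0, 3))
  g <- dose_categories(x, breaks = c(0.5, 1, 2))
  expect_false(anyNA(g))
  expect_equal(sum(table(g)), length(x))
  expect_equal(sum(g == "0"), sum(x == 0))
  expect_error(dose_categories(-1, c(1/3, 2/3)), "negative")
  expect_error(dose_categories(1, c(2/3, 1/3)), "increasing")
})

test_that("basis CSV export round-trips at full precision", {
  x <- c(0, exp(1) / 10, pi / 3, 1.1)
  b <- ncs_basis(x, c(1/8, 1/2, 7/8), anchor_at_zero = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_basis_csv(b, x, path)
  back <- read.csv(path, check.names = FALSE)
  expect_identical(back$dose, x)
  vals <- matrix(as.numeric(b), nrow = nrow(b))
  expect_identical(unname(as.matrix(back[, -1])), vals)
})
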