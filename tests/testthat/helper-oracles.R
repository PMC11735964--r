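# Independent oracles used across the suite. These are deliberately
# written from first principles (truncated-power construction, explicit
# matrix arithmetic) and share no code with the package's implementation.

# Natural cubic spline via the truncated-power construction: columns
# {x, D_1(x), ..., D_{K-2}(x)} with
#   d_k(x) = [(x - t_k)_+^3 - (x - t_K)_+^3] / (t_K - t_k)
#   D_k(x) = d_k(x) - d_{K-1}(x)
# Spans the K-1 dimensional (non-intercept) natural spline space: linear
# beyond both boundary knots, C2 everywhere.
tp_natural_basis <- function(x, knots) {
  K <- length(knots)
  tK <- knots[K]
  d <- function(k) {
    (pmax(x - knots[k], 0)^3 - pmax(x - tK, 0)^3) / (tK - knots[k])
  }
  dK1 <- d(K - 1L)
  cols <- lapply(seq_len(K - 2L), function(k) d(k) - dK1)
  cbind(x, do.call(cbind, cols))
}

# Largest residual when projecting each column of B onto span{1, A}.
max_projection_residual <- function(A, B) {
  X <- cbind(1, A)
  resid <- B - X %*% qr.solve(crossprod(X), crossprod(X, B))
  max(abs(resid))
}

# Brute-force HC0 sandwich: (X'X)^-1 X' diag(e^2) X (X'X)^-1.
bf_hc0 <- function(X, e) {
  bread <- solve(crossprod(X))
  meat <- crossprod(X * e, X * e)
  bread %*% meat %*% bread
}

# Brute-force cluster sandwich without small-sample adjustment.
bf_cluster_hc0 <- function(X, e, cl) {
  bread <- solve(crossprod(X))
  scores <- rowsum(X * e, cl)
  bread %*% crossprod(scores) %*% bread
}

# Equality-constrained least squares min ||y - X b|| s.t. Cb = 0, solved
# through the KKT system. Returns coefficients and residual norm.
constrained_ols <- function(X, y, C) {
  p <- ncol(X)
  q <- nrow(C)
  kkt <- rbind(cbind(crossprod(X), t(C)),
               cbind(C, matrix(0, q, q)))
  rhs <- c(crossprod(X, y), rep(0, q))
  sol <- solve(kkt, rhs)
  b <- sol[seq_len(p)]
  list(coefficients = b, resid_norm = sqrt(sum((y - X %*% b)^2)))
}

# Central-difference derivative of each column of a basis constructor.
num_deriv <- function(fun, x, h = 1e-5) {
  (fun(x + h) - fun(x - h)) / (2 * h)
}

# Second derivative by central differences.
num_deriv2 <- function(fun, x, h = 1e-4) {
  (fun(x + h) - 2 * fun(x) + fun(x - h)) / h^2
}
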