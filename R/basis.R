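#' Validated knot set for spline bases
#'
#' Bundles the knot locations used by [ncs_basis()] and
#' [slab_spline_basis()]. The first and last knots act as boundary knots
#' (the natural spline is linear outside them); any knots in between are
#' interior knots.
#'
#' @param knots numeric vector of at least 3 strictly increasing, strictly
#'   positive dose values.
#' @return An object of class `"dr_knots"`: a list with elements `knots`,
#'   `lower_boundary` and `upper_boundary`.
#' @examples
#' knot_set(c(1/8, 1/2, 7/8))
#' @export
knot_set <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L)
    stop("invalid knot specification: at least 3 knots are required, got ",
         length(knots), call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("invalid knot specification: knots must be strictly increasing",
         call. = FALSE)
  if (any(knots <= 0))
    stop("invalid knot specification: knots must be strictly positive doses",
         call. = FALSE)
  structure(list(knots = knots,
                 lower_boundary = knots[1L],
                 upper_boundary = knots[length(knots)]),
            class = "dr_knots")
}

as_knot_set <- function(knots) {
  if (inherits(knots, "dr_knots")) knots else knot_set(knots)
}

#' @export
print.dr_knots <- function(x, ...) {
  cat("knot set:", paste(format(x$knots), collapse = ", "),
      " (boundaries ", format(x$lower_boundary), ", ",
      format(x$upper_boundary), ")\n", sep = "")
  invisible(x)
}

check_doses <- function(x, what = "dose") {
  if (!is.numeric(x)) stop("invalid input: ", what, " must be numeric",
                           call. = FALSE)
  if (anyNA(x)) stop("invalid input: ", what, " contains missing values",
                     call. = FALSE)
  if (any(x < 0)) stop("invalid input: negative ", what,
                       " values are not allowed", call. = FALSE)
  invisible(as.numeric(x))
}

new_basis <- function(values, labels, anchored, knots) {
  dimnames(values) <- list(NULL, labels)
  structure(values, anchored_at_zero = anchored, knots = knots,
            class = c("dr_basis", class(values)))
}

raw_ns <- function(x, ks) {
  k <- ks$knots
  nk <- length(k)
  splines::ns(x, knots = k[-c(1L, nk)], Boundary.knots = c(k[1L], k[nk]))
}

#' Natural cubic spline basis for a dose variable
#'
#' Evaluates a natural cubic spline basis (piecewise cubic, linear beyond
#' the boundary knots, continuous second derivatives) at the supplied
#' doses. With K knots the basis has K-1 non-intercept columns. When
#' `anchor_at_zero = TRUE` each column has its value at dose 0 subtracted,
#' so that all columns vanish at zero; this is an affine reparametrization
#' that leaves the fitted curve unchanged but makes a spike-at-zero
#' coefficient directly interpretable as the limiting effect of an
#' infinitesimally small dose.
#'
#' @param x numeric vector of nonnegative doses.
#' @param knots a [knot_set()] or numeric vector of at least 3 knots.
#' @param anchor_at_zero subtract the basis row at dose 0 from every row?
#' @return A `"dr_basis"` matrix with column labels and knot metadata
#'   attached.
#' @seealso [slab_spline_basis()] for the constrained variant.
#' @export
ncs_basis <- function(x, knots, anchor_at_zero = FALSE) {
  ks <- as_knot_set(knots)
  x <- check_doses(x)
  vals <- unclass(raw_ns(x, ks))
  attributes(vals)[c("degree", "knots", "Boundary.knots", "intercept")] <- NULL
  dim(vals) <- c(length(x), length(ks$knots) - 1L)
  if (anchor_at_zero) {
    at0 <- as.numeric(raw_ns(0, ks))
    vals <- sweep(vals, 2L, at0, "-")
  }
  new_basis(vals, paste0("ns", seq_len(ncol(vals))), anchor_at_zero, ks)
}

# Row vector of per-column derivatives of the natural spline basis at the
# lower boundary knot. The natural spline is exactly linear at and below
# that knot, so a two-point slope on the left tail is exact.
ns_lower_derivative <- function(ks) {
  a <- ks$lower_boundary
  b1 <- as.numeric(raw_ns(a, ks))
  b0 <- as.numeric(raw_ns(a - 1, ks))
  b1 - b0
}

# Orthonormal basis of the null space of a single row vector, computed via
# a full QR of its transpose. Deterministic given the knots.
null_space <- function(d) {
  q <- qr.Q(qr(matrix(d, ncol = 1L)), complete = TRUE)
  q[, -1L, drop = FALSE]
}

#' Slab-and-spline basis: a natural spline constant below its first knot
#'
#' Constructs a basis spanning exactly the subspace of the natural cubic
#' spline span whose members have zero first derivative at (and hence left
#' of) the lower boundary knot. Fitted functions are therefore constant (a
#' "slab") on `[0, lower_boundary)` and join the spline at the first knot
#' with a continuous first derivative. The basis has one column fewer than
#' [ncs_basis()] with the same knots, so the slab costs one degree of
#' freedom less than a spike term plus an unconstrained spline.
#'
#' The construction multiplies the unconstrained natural spline basis by an
#' orthonormal null-space transformation of the row vector of column
#' derivatives at the lower boundary knot.
#'
#' @inheritParams ncs_basis
#' @return A `"dr_basis"` matrix with `length(knots) - 2` columns.
#' @export
slab_spline_basis <- function(x, knots, anchor_at_zero = FALSE) {
  ks <- as_knot_set(knots)
  x <- check_doses(x)
  nmat <- null_space(ns_lower_derivative(ks))
  vals <- unclass(raw_ns(x, ks)) %*% nmat
  if (anchor_at_zero) {
    at0 <- as.numeric(raw_ns(0, ks) %*% nmat)
    vals <- sweep(vals, 2L, at0, "-")
  }
  new_basis(vals, paste0("slab", seq_len(ncol(vals))), anchor_at_zero, ks)
}

#' Spike-at-zero indicator
#'
#' Binary indicator of any exposure: 1 for a strictly positive dose, 0 for
#' a dose of exactly zero. Added to a dose-response model it frees the
#' exposed group's intercept, so the model no longer forces the curve (and
#' its confidence band) through the origin.
#'
#' @param x numeric vector of nonnegative doses.
#' @return Numeric 0/1 vector of the same length.
#' @export
spike_indicator <- function(x) {
  x <- check_doses(x)
  as.numeric(x > 0)
}

#' Categorize a semicontinuous dose
#'
#' Dose 0 forms its own category; positive doses are binned into
#' left-open, right-closed intervals defined by `breaks`, with a final
#' open-ended category above the top break.
#'
#' @param x numeric vector of nonnegative doses.
#' @param breaks strictly increasing, strictly positive break values.
#' @return A factor whose first level `"0"` is the zero-dose group,
#'   followed by `"(0,b1]"`, `"(b1,b2]"`, ..., `">bk"`. Integer category
#'   indices (0 for the zero-dose group) are `as.integer(result) - 1`.
#' @examples
#' dose_categories(c(0, 1/3, 0.9), breaks = c(1/3, 2/3))
#' @export
dose_categories <- function(x, breaks) {
  x <- check_doses(x)
  breaks <- as.numeric(breaks)
  if (any(breaks <= 0) || any(diff(breaks) <= 0))
    stop("invalid input: breaks must be strictly increasing and positive",
         call. = FALSE)
  fb <- format(breaks, trim = TRUE)
  labs <- c("0",
            paste0("(", c("0", fb[-length(fb)]), ",", fb, "]"),
            paste0(">", fb[length(fb)]))
  idx <- findInterval(x, c(0, breaks), left.open = TRUE)
  idx[x == 0] <- 0L
  factor(labs[idx + 1L], levels = labs)
}

#' Write an evaluated basis to CSV
#'
#' One row per input dose, a `dose` column first, then one column per
#' basis term, written at full double precision so the file round-trips
#' exactly.
#'
#' @param basis a `"dr_basis"` matrix.
#' @param x the doses at which it was evaluated.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_basis_csv <- function(basis, x, path) {
  df <- data.frame(dose = x, as.matrix(basis), check.names = FALSE)
  write_csv_full(df, path)
}
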