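#' Design bases for growth-curve models
#'
#' All four trajectory models in this package are built from a small set of
#' time bases: centred polynomials up to degree 3, cubic (optionally linear)
#' truncated-power splines on the raw age scale, natural cubic splines, and a
#' continuous-time AR(1) correlation kernel for irregularly spaced visits.
#' A [basis_spec()] names a basis declaratively so model specifications can be
#' serialized and compared; [build_basis()] realizes it as a design matrix.
#'
#' @name growth-bases
NULL

#' Declarative basis specification
#'
#' @param kind One of `"polynomial"`, `"truncated_power"` or
#'   `"natural_cubic_spline"`.
#' @param degree Polynomial degree (0--3) for `"polynomial"`, or the piecewise
#'   degree (1 or 3) for `"truncated_power"`.
#' @param knots Interior knots in years for spline kinds.
#' @param df Degrees of freedom for `"natural_cubic_spline"` (3--8).
#' @param center Centring constant in years, applied to polynomial terms
#'   (default 8, the sample mean age of the emulated cohort). Truncated-power
#'   spline knots are interpreted on the raw age scale.
#' @param transform Time transform applied before basis construction:
#'   `"identity"` or `"ln"`.
#' @param scale_quadratic If `TRUE`, quadratic polynomial columns are scaled by
#'   0.5 (the `1 + age + 0.5*age^2` random-effect parameterization; changes
#'   only the parameterization of the random-effect covariance, not the fit).
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(kind = c("polynomial", "truncated_power",
                                "natural_cubic_spline"),
                       degree = 3L, knots = numeric(), df = NULL,
                       center = 8, transform = c("identity", "ln"),
                       scale_quadratic = FALSE) {
  kind <- match.arg(kind)
  transform <- match.arg(transform)
  if (kind == "polynomial") {
    if (!degree %in% 0:3) {
      stop("polynomial degree must be in 0..3 (cubic is the maximum used)")
    }
  }
  if (kind == "truncated_power") {
    if (!degree %in% c(1L, 3L)) {
      stop("truncated-power basis supports degree 1 or 3")
    }
    if (length(knots) && is.unsorted(knots, strictly = TRUE)) {
      stop("knots must be strictly increasing")
    }
  }
  if (kind == "natural_cubic_spline") {
    if (is.null(df)) stop("natural_cubic_spline requires df")
    if (df < 3 || df > 8) stop("natural-spline df must lie in [3, 8]")
  }
  structure(
    list(kind = kind, degree = as.integer(degree), knots = as.numeric(knots),
         df = if (!is.null(df)) as.integer(df) else NULL,
         center = center, transform = transform,
         scale_quadratic = isTRUE(scale_quadratic)),
    class = "basis_spec"
  )
}

#' @export
print.basis_spec <- function(x, ...) {
  extra <- switch(x$kind,
    polynomial = sprintf("degree %d, center %g", x$degree, x$center),
    truncated_power = sprintf("degree %d, knots {%s}", x$degree,
                              paste(x$knots, collapse = ", ")),
    natural_cubic_spline = sprintf("df %d", x$df))
  cat(sprintf("<basis_spec: %s (%s), time %s>\n", x$kind, extra, x$transform))
  invisible(x)
}

#' Centred polynomial design matrix
#'
#' Columns `1, a, a^2, ..., a^degree` with `a = age - center`.
#'
#' @param ages Numeric vector of ages in years.
#' @param degree Polynomial degree, 0--3.
#' @param center Centring constant in years.
#' @param scale_quadratic Scale the quadratic column by 0.5 (see
#'   [basis_spec()]).
#' @return Matrix with `degree + 1` columns; first column all ones.
#' @export
polynomial_basis <- function(ages, degree = 3L, center = 8,
                             scale_quadratic = FALSE) {
  if (!degree %in% 0:3) stop("degree must be in 0..3")
  a <- ages - center
  X <- outer(a, 0:degree, `^`)
  nm <- c("(Intercept)", "age", "age2", "age3")[seq_len(degree + 1)]
  if (scale_quadratic && degree >= 2) {
    X[, 3] <- 0.5 * X[, 3]
    nm[3] <- "0.5*age2"
  }
  colnames(X) <- nm
  X
}

#' Truncated-power spline design matrix
#'
#' For degree 3 (the default used by the semi-parametric model) the columns are
#' `1, t, t^2, t^3, (t - k1)^3_+, ..., (t - kK)^3_+`; the truncated terms are
#' zero at and below their knot, making the curve and its first two derivatives
#' continuous at every knot. Knots are on the raw (uncentred) age scale. A
#' degree-1 variant (`1, t, (t - k)_+`) is available.
#'
#' @param ages Ages in years.
#' @param knots Strictly increasing interior knots in years.
#' @param degree 1 or 3.
#' @return Matrix with `degree + 1 + length(knots)` columns.
#' @export
truncated_power_basis <- function(ages, knots, degree = 3L) {
  if (!degree %in% c(1L, 3L)) stop("degree must be 1 or 3")
  if (length(knots) && is.unsorted(knots, strictly = TRUE)) {
    stop("knots must be strictly increasing")
  }
  X <- outer(ages, 0:degree, `^`)
  nm <- c("(Intercept)", "age", "age2", "age3")[seq_len(degree + 1)]
  for (k in knots) {
    X <- cbind(X, pmax(ages - k, 0)^degree)
    nm <- c(nm, sprintf("(age-%g)+%d", k, degree))
  }
  colnames(X) <- nm
  X
}

#' Natural cubic spline design matrix
#'
#' Wraps [splines::ns()] with interior knots at equally spaced quantiles of the
#' observed values and boundary knots at configurable quantiles; beyond the
#' boundary knots the fitted function is linear (second derivative zero). The
#' returned matrix carries the knots as attributes so the identical basis can
#' be evaluated at new points with [evaluate_ns()].
#'
#' @param x Numeric vector (typically age or ln age).
#' @param df Degrees of freedom, 3--8 (columns, intercept excluded).
#' @param boundary_quantiles Quantiles of `x` used for the boundary knots.
#' @return Matrix with `df` columns and attributes `knots`,
#'   `Boundary.knots`.
#' @export
natural_spline_basis <- function(x, df, boundary_quantiles = c(0, 1)) {
  if (df < 3 || df > 8) stop("df must lie in [3, 8]")
  if (length(unique(x)) < df + 2) stop("too few distinct values for df")
  bk <- stats::quantile(x, boundary_quantiles, names = FALSE)
  probs <- seq(0, 1, length.out = df + 1)[-c(1, df + 1)]
  kn <- stats::quantile(x[x >= bk[1] & x <= bk[2]], probs, names = FALSE)
  B <- splines::ns(x, knots = kn, Boundary.knots = bk)
  B <- unclass(B)[, , drop = FALSE]
  colnames(B) <- paste0("ns", seq_len(ncol(B)))
  attr(B, "knots") <- kn
  attr(B, "Boundary.knots") <- bk
  B
}

#' Evaluate a stored natural-spline basis at new points
#'
#' @param basis A matrix from [natural_spline_basis()].
#' @param x New points.
#' @return Matrix with the same columns as `basis`.
#' @export
evaluate_ns <- function(basis, x) {
  B <- splines::ns(x, knots = attr(basis, "knots"),
                   Boundary.knots = attr(basis, "Boundary.knots"))
  B <- unclass(B)[, , drop = FALSE]
  colnames(B) <- paste0("ns", seq_len(ncol(B)))
  B
}

#' Continuous-time AR(1) correlation matrix
#'
#' `C[s, t] = phi^|age_s - age_t|` for measurement gap in years; appropriate
#' for irregularly spaced longitudinal visits. `phi = 0` gives the identity.
#'
#' @param ages Visit ages in years.
#' @param phi Correlation at a one-year gap, in `[0, 1)`.
#' @return Symmetric positive-definite correlation matrix with unit diagonal.
#' @export
car1_correlation <- function(ages, phi) {
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  if (phi == 0) return(diag(length(ages)))
  phi^abs(outer(ages, ages, `-`))
}

#' Realize a basis specification as a design matrix
#'
#' @param spec A [basis_spec()].
#' @param ages Ages in years (transformed internally if the spec says so).
#' @return Design matrix.
#' @export
build_basis <- function(spec, ages) {
  stopifnot(inherits(spec, "basis_spec"))
  t <- if (spec$transform == "ln") log(ages) else ages
  switch(spec$kind,
    polynomial = polynomial_basis(t, spec$degree, spec$center,
                                  spec$scale_quadratic),
    truncated_power = truncated_power_basis(t, spec$knots, spec$degree),
    natural_cubic_spline = cbind(`(Intercept)` = 1,
                                 natural_spline_basis(t, spec$df))
  )
}

#' Number of columns a basis specification produces
#' @param spec A [basis_spec()].
#' @return Integer column count.
#' @export
basis_ncol <- function(spec) {
  switch(spec$kind,
    polynomial = spec$degree + 1L,
    truncated_power = spec$degree + 1L + length(spec$knots),
    natural_cubic_spline = spec$df + 1L)
}
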