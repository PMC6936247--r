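# Core ellipsoid geometry: construction from trivariate samples, semi-axes,
# standard ellipsoid volume (SEV), the three-dimensional small-sample
# correction, chi-square coverage rescaling, and point containment.

#' Coverage fraction of the 1-sigma standard ellipsoid
#'
#' Under a trivariate normal, the squared Mahalanobis radius is chi-square
#' with 3 degrees of freedom, so the 1-sigma ("standard") ellipsoid captures
#' `pchisq(1, 3)`, roughly 19.9% of the data -- the familiar "about 20%"
#' of the standard ellipse carried over to three dimensions.
#'
#' @return A single numeric fraction (about 0.1987).
#' @export
sigma1_coverage <- function() pchisq(1, df = 3)

#' Construct an ellipsoid
#'
#' An `ellipsoid` is a center (per-mil values on the \eqn{\delta^{13}}C,
#' \eqn{\delta^{15}}N, \eqn{\delta^{34}}S axes), a symmetric positive-definite
#' 3x3 shape matrix (a covariance at the 1-sigma scale, or a rescaled multiple
#' of one), the coverage fraction its boundary corresponds to under the
#' generating trivariate normal, and the sample size it was built from
#' (0 for synthetic ellipsoids).
#'
#' @param center Numeric 3-vector.
#' @param shape Symmetric positive-definite 3x3 matrix.
#' @param coverage Fraction in (0, 1) of the generating normal captured at
#'   this scale; defaults to the 1-sigma value [sigma1_coverage()].
#' @param n Sample size used to estimate the ellipsoid (0 if synthetic).
#' @return An object of class `"ellipsoid"`.
#' @examples
#' e <- ellipsoid(c(-16, 12.5, 19), diag(c(0.5, 0.2, 0.3)))
#' sev(e)
#' @export
ellipsoid <- function(center, shape, coverage = sigma1_coverage(), n = 0L) {
  center <- as.numeric(center)
  shape <- as.matrix(shape)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("center must be a finite 3-vector")
  if (!all(dim(shape) == c(3L, 3L)) || !all(is.finite(shape)))
    stop("shape must be a finite 3x3 matrix")
  if (max(abs(shape - t(shape))) > 1e-8 * max(1, max(abs(shape))))
    stop("shape must be symmetric")
  shape <- (shape + t(shape)) / 2
  ev <- eigen(shape, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[3] <= 1e-12 * ev[1])
    stop("degenerate covariance: shape matrix is not positive definite")
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage <= 0 || coverage >= 1)
    stop("invalid coverage: must lie strictly in (0, 1)")
  structure(
    list(center = center, shape = shape, coverage = coverage,
         n = as.integer(n)),
    class = "ellipsoid"
  )
}

#' @export
print.ellipsoid <- function(x, ...) {
  ax <- semi_axes(x)
  cat("Trivariate niche ellipsoid\n")
  cat("  center   :", paste(sprintf("%.3f", x$center), collapse = ", "), "\n")
  cat("  semi-axes:", paste(sprintf("%.3f", ax), collapse = ", "), "\n")
  cat(sprintf("  volume   : %.4f  (coverage %.1f%%, n = %d)\n",
              sev(x), 100 * x$coverage, x$n))
  invisible(x)
}

#' Fit the standard ellipsoid to a trivariate sample
#'
#' Center is the vector of column means; the shape matrix is the unbiased
#' (n-1 denominator) sample covariance, so the result is the 1-sigma standard
#' ellipsoid of the sample. The (n-1)/(n-3) correction of [sev_c()] must not
#' be applied on top of a shape that already uses another convention.
#'
#' @param data Numeric n x 3 matrix, columns ordered
#'   (\eqn{\delta^{13}}C, \eqn{\delta^{15}}N, \eqn{\delta^{34}}S).
#' @return An [ellipsoid()] with `coverage = sigma1_coverage()` and `n` set.
#' @export
ellipsoid_from_sample <- function(data) {
  data <- as.matrix(data)
  if (ncol(data) != 3L)
    stop("data must have exactly 3 columns")
  if (anyNA(data) || !all(is.finite(data)))
    stop("data must not contain missing or non-finite values")
  if (nrow(data) < 4L)
    stop("insufficient sample: at least 4 rows are required")
  s <- cov(data)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[3] <= 1e-12 * ev[1])
    stop("degenerate covariance: sample is (near-)collinear")
  ellipsoid(colMeans(data), s, coverage = sigma1_coverage(), n = nrow(data))
}

#' Semi-axis lengths of an ellipsoid
#'
#' Square roots of the shape-matrix eigenvalues, sorted so that
#' `a >= b >= c` (one semi-major and two semi-minor axes).
#'
#' @param e An [ellipsoid()].
#' @return Named numeric vector `c(a = , b = , c = )` in per mil.
#' @export
semi_axes <- function(e) {
  stopifnot(inherits(e, "ellipsoid"))
  ev <- eigen(e$shape, symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] <= 0) stop("degenerate covariance")
  ax <- sqrt(ev)
  names(ax) <- c("a", "b", "c")
  ax
}

#' Standard ellipsoid volume (SEV)
#'
#' Volume `(4/3) * pi * a * b * c` of the ellipsoid at its current scale,
#' equivalently `(4/3) * pi * sqrt(det(shape))`. For an ellipsoid fitted by
#' [ellipsoid_from_sample()] (1-sigma scale) this is the SEV statistic.
#'
#' @param e An [ellipsoid()].
#' @return Volume in per mil cubed.
#' @export
sev <- function(e) {
  stopifnot(inherits(e, "ellipsoid"))
  d <- det(e$shape)
  if (d <= 0) stop("degenerate covariance")
  (4 / 3) * pi * sqrt(d)
}

#' Small-sample corrected ellipsoid volume (SEV_C)
#'
#' SEV underestimates population volume at small n; in three dimensions the
#' degrees-of-freedom correction factor is `(n - 1) / (n - 3)` (the 3-D
#' analogue of the standard-ellipse area correction SEAc).
#'
#' @param e An [ellipsoid()].
#' @param n Sample size; defaults to the size stored in `e`.
#' @return Corrected volume in per mil cubed; always strictly larger than
#'   [sev()], with ratio tending to 1 as n grows.
#' @export
sev_c <- function(e, n = e$n) {
  stopifnot(inherits(e, "ellipsoid"))
  n <- as.integer(n)
  if (is.na(n) || n <= 3L)
    stop("correction undefined: (n - 1)/(n - 3) requires n >= 4")
  sev(e) * (n - 1) / (n - 3)
}

#' Rescale an ellipsoid to capture a chosen fraction of the data
#'
#' Under the trivariate-normal assumption the squared Mahalanobis radius is
#' chi-square with 3 df, so the ellipsoid whose boundary sits at squared
#' radius `q = qchisq(p, 3)` captures fraction `p` of the generating
#' distribution. The shape matrix is multiplied by the ratio of the target
#' and current chi-square quantiles, so rescaling is consistent from any
#' starting coverage (fitting "to 75% of the data" uses `p = 0.75`).
#'
#' @param e An [ellipsoid()].
#' @param p Target coverage fraction in (0, 1).
#' @return An [ellipsoid()] at coverage `p`.
#' @export
scale_to_coverage <- function(e, p) {
  stopifnot(inherits(e, "ellipsoid"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("invalid coverage: p must lie strictly in (0, 1)")
  scale <- qchisq(p, df = 3) / qchisq(e$coverage, df = 3)
  ellipsoid(e$center, e$shape * scale, coverage = p, n = e$n)
}

#' Test whether points lie inside an ellipsoid
#'
#' A point is inside when its squared Mahalanobis distance with respect to
#' the shape matrix at the ellipsoid's current scale is at most 1.
#'
#' @param e An [ellipsoid()].
#' @param x Numeric 3-vector or n x 3 matrix of points.
#' @param tol Boundary tolerance added to the unit radius (points on the
#'   surface count as inside).
#' @return Logical scalar or vector.
#' @export
contains <- function(e, x, tol = 0) {
  stopifnot(inherits(e, "ellipsoid"))
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
  if (ncol(x) != 3L) stop("x must be a 3-vector or an n x 3 matrix")
  mahalanobis_sq(e, x) <= 1 + tol
}

# squared Mahalanobis distance of rows of x to the ellipsoid center
mahalanobis_sq <- function(e, x) {
  ctr <- sweep(x, 2L, e$center)
  a <- solve(e$shape)
  rowSums((ctr %*% a) * ctr)
}
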