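# Quadrilateral surface meshes on ellipsoids and mesh-based overlap volumes.
#
# An ellipsoid is discretized as the affine image of a latitude-longitude
# quadrilateral sphere mesh; subdividing each quad into four (with new
# vertices reprojected onto the surface) tightens the approximation. The
# intersection of two ellipsoids is convex, so the convex hull of (i) each
# mesh's vertices inside the other ellipsoid and (ii) mesh-edge crossings of
# the other surface is an inner approximation of the overlap volume that
# converges from below as subdivision increases.

#' Build a quadrilateral surface mesh on an ellipsoid
#'
#' The base mesh (level 0) is a `base_n` x `base_n` latitude-longitude quad
#' grid on the unit sphere; each subdivision level splits every quadrilateral
#' into four through reprojected edge midpoints and face centers. Vertices are
#' mapped onto the ellipsoid through its Cholesky factor and center, so every
#' vertex satisfies squared-Mahalanobis radius 1 at the ellipsoid's scale.
#' Construction is deterministic for fixed inputs.
#'
#' @param e An [ellipsoid()].
#' @param subdivision Non-negative integer subdivision level.
#' @param base_n Latitude/longitude resolution of the level-0 grid.
#' @return Object of class `"surface_mesh"`: `vertices` (n x 3), `faces`
#'   (m x 4 vertex indices), `subdivision`, `base_n`, `source` ellipsoid.
#' @export
build_mesh <- function(e, subdivision = 4L, base_n = 16L) {
  stopifnot(inherits(e, "ellipsoid"))
  subdivision <- as.integer(subdivision)
  base_n <- as.integer(base_n)
  if (is.na(subdivision) || subdivision < 0L)
    stop("subdivision must be a non-negative integer")
  if (base_n < 3L) stop("base_n must be at least 3")

  m <- unit_sphere_grid(base_n)
  k <- subdivision
  while (k > 0L) {
    m <- subdivide_quads(m$vertices, m$faces)
    k <- k - 1L
  }
  # affine map onto the ellipsoid: x = center + L v with shape = L L'
  l <- t(chol(e$shape))
  v <- m$vertices %*% t(l)
  v <- sweep(v, 2L, e$center, "+")
  structure(
    list(vertices = v, faces = m$faces, subdivision = subdivision,
         base_n = base_n, source = e),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "Ellipsoid surface mesh: %d vertices, %d quad faces (level %d, base %dx%d)\n",
    nrow(x$vertices), nrow(x$faces), x$subdivision, x$base_n, x$base_n))
  invisible(x)
}

# lat-long quad grid on the unit sphere; pole quads are degenerate (two
# coincident corners), which the hull and edge routines tolerate
unit_sphere_grid <- function(base_n) {
  theta <- pi * seq_len(base_n - 1L) / base_n       # colatitude of inner rows
  phi <- 2 * pi * (seq_len(base_n) - 1L) / base_n
  rows <- lapply(theta, function(t)
    cbind(sin(t) * cos(phi), sin(t) * sin(phi), cos(t)))
  v <- rbind(c(0, 0, 1), do.call(rbind, rows), c(0, 0, -1))
  npole <- 1L
  spole <- nrow(v)
  idx <- function(i, j) {
    # i in 0..base_n (latitude row), j in 0..base_n-1 wrapped
    j <- j %% base_n
    ifelse(i == 0L, npole,
           ifelse(i == base_n, spole, 1L + (i - 1L) * base_n + j + 1L))
  }
  gi <- rep(0:(base_n - 1L), each = base_n)
  gj <- rep(0:(base_n - 1L), times = base_n)
  faces <- cbind(idx(gi, gj), idx(gi + 1L, gj),
                 idx(gi + 1L, gj + 1L), idx(gi, gj + 1L))
  storage.mode(faces) <- "integer"
  list(vertices = v, faces = faces)
}

# one quadrisection step in unit-sphere space, reprojecting new vertices
subdivide_quads <- function(v, f) {
  nv <- nrow(v)
  m <- nrow(f)
  corners <- cbind(f[, 1L], f[, 2L], f[, 3L], f[, 4L], f[, 1L])
  ea <- c(corners[, 1L], corners[, 2L], corners[, 3L], corners[, 4L])
  eb <- c(corners[, 2L], corners[, 3L], corners[, 4L], corners[, 5L])
  lo <- pmin(ea, eb)
  hi <- pmax(ea, eb)
  key <- as.numeric(lo) * (nv + 1) + as.numeric(hi)
  uk <- !duplicated(key)
  mid_id <- match(key, key[uk])          # 1..n_unique, per (face, edge) slot
  mids <- (v[lo[uk], , drop = FALSE] + v[hi[uk], , drop = FALSE]) / 2
  mids <- mids / pmax(sqrt(rowSums(mids^2)), .Machine$double.eps)
  ctrs <- (v[f[, 1L], ] + v[f[, 2L], ] + v[f[, 3L], ] + v[f[, 4L], ]) / 4
  ctrs <- ctrs / pmax(sqrt(rowSums(ctrs^2)), .Machine$double.eps)

  mid_global <- nv + mid_id              # length 4m: e12, e23, e34, e41 blocks
  m12 <- mid_global[seq_len(m)]
  m23 <- mid_global[m + seq_len(m)]
  m34 <- mid_global[2L * m + seq_len(m)]
  m41 <- mid_global[3L * m + seq_len(m)]
  cc <- nv + sum(uk) + seq_len(m)
  new_f <- rbind(
    cbind(f[, 1L], m12, cc, m41),
    cbind(m12, f[, 2L], m23, cc),
    cbind(cc, m23, f[, 3L], m34),
    cbind(m41, cc, m34, f[, 4L])
  )
  storage.mode(new_f) <- "integer"
  list(vertices = rbind(v, mids, ctrs), faces = new_f)
}

#' Convex hull volume of a 3-D point set
#'
#' Quickhull-based volume of the convex hull; degenerate inputs (fewer than
#' four points, or all points within tolerance of a plane) return 0.
#'
#' @param points Numeric n x 3 matrix.
#' @return Hull volume (non-negative scalar).
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (nrow(points) < 4L) return(0)
  storage.mode(points) <- "double"
  .qhull_volume(points)
}

# unique undirected edges of a quad mesh, dropping degenerate (pole) edges
mesh_edges <- function(mesh) {
  f <- mesh$faces
  ea <- c(f[, 1L], f[, 2L], f[, 3L], f[, 4L])
  eb <- c(f[, 2L], f[, 3L], f[, 4L], f[, 1L])
  lo <- pmin(ea, eb)
  hi <- pmax(ea, eb)
  keep <- lo != hi
  lo <- lo[keep]
  hi <- hi[keep]
  key <- as.numeric(lo) * (nrow(mesh$vertices) + 1) + as.numeric(hi)
  uk <- !duplicated(key)
  cbind(lo[uk], hi[uk])
}

# points where mesh edges cross the surface of ellipsoid e (quadratic in the
# edge parameter), restricted to the edge segment
edge_surface_points <- function(mesh, e) {
  ed <- mesh_edges(mesh)
  p <- mesh$vertices[ed[, 1L], , drop = FALSE]
  q <- mesh$vertices[ed[, 2L], , drop = FALSE]
  d <- q - p
  a_inv <- solve(e$shape)
  pc <- sweep(p, 2L, e$center)
  aa <- rowSums((d %*% a_inv) * d)
  bb <- 2 * rowSums((d %*% a_inv) * pc)
  cc <- rowSums((pc %*% a_inv) * pc) - 1
  disc <- bb^2 - 4 * aa * cc
  ok <- which(aa > 0 & disc >= 0)
  if (!length(ok)) return(matrix(numeric(0), ncol = 3L))
  sq <- sqrt(disc[ok])
  t1 <- (-bb[ok] - sq) / (2 * aa[ok])
  t2 <- (-bb[ok] + sq) / (2 * aa[ok])
  tol <- 1e-9
  pts <- rbind(
    p[ok, , drop = FALSE] + t1 * d[ok, , drop = FALSE],
    p[ok, , drop = FALSE] + t2 * d[ok, , drop = FALSE]
  )
  keep <- c(t1 >= -tol & t1 <= 1 + tol, t2 >= -tol & t2 <= 1 + tol)
  pts[keep, , drop = FALSE]
}

#' Mesh-based overlap of two ellipsoids
#'
#' Both ellipsoids are meshed at the same subdivision level; the overlap
#' region is approximated by the convex hull of the vertices of each mesh
#' lying inside the other ellipsoid together with the crossing points of each
#' mesh's edges with the other surface. Directed percentages divide the hull
#' volume by each mesh's own hull volume at the same subdivision, so
#' discretization bias cancels and self-overlap is exactly 100%.
#'
#' @param ea,eb [ellipsoid()] objects at the same coverage scale.
#' @param subdivision Subdivision level passed to [build_mesh()].
#' @param base_n Base mesh resolution passed to [build_mesh()].
#' @return Object of class `"overlap_estimate"` with fields
#'   `percent_of_first`, `percent_of_second`, `absolute_volume`,
#'   `hull_volume_first`, `hull_volume_second`, `subdivision`, `base_n`.
#' @export
overlap <- function(ea, eb, subdivision = 4L, base_n = 16L) {
  stopifnot(inherits(ea, "ellipsoid"), inherits(eb, "ellipsoid"))
  if (abs(ea$coverage - eb$coverage) > 1e-9)
    stop("scale mismatch: ellipsoids must be at the same coverage")
  ma <- build_mesh(ea, subdivision, base_n)
  mb <- build_mesh(eb, subdivision, base_n)
  tol <- 1e-9
  va_in <- ma$vertices[contains(eb, ma$vertices, tol = tol), , drop = FALSE]
  vb_in <- mb$vertices[contains(ea, mb$vertices, tol = tol), , drop = FALSE]
  pts <- rbind(va_in, vb_in,
               edge_surface_points(ma, eb),
               edge_surface_points(mb, ea))
  vol <- if (nrow(pts) >= 4L) convex_hull_volume(pts) else 0
  ha <- convex_hull_volume(ma$vertices)
  hb <- convex_hull_volume(mb$vertices)
  structure(
    list(
      percent_of_first = min(100, 100 * vol / ha),
      percent_of_second = min(100, 100 * vol / hb),
      absolute_volume = vol,
      hull_volume_first = ha,
      hull_volume_second = hb,
      subdivision = as.integer(subdivision),
      base_n = as.integer(base_n)
    ),
    class = "overlap_estimate"
  )
}

#' @export
print.overlap_estimate <- function(x, ...) {
  cat("Ellipsoid overlap (mesh convex-hull estimate)\n")
  cat(sprintf("  shared volume : %.4f\n", x$absolute_volume))
  cat(sprintf("  %% of first    : %.2f\n", x$percent_of_first))
  cat(sprintf("  %% of second   : %.2f\n", x$percent_of_second))
  cat(sprintf("  subdivision   : %d (base %dx%d)\n",
              x$subdivision, x$base_n, x$base_n))
  invisible(x)
}

#' Monte Carlo oracle for ellipsoid intersection volume
#'
#' Rejection sampling in the axis-aligned bounding box of the first
#' ellipsoid, counting points inside both. Used as an independent check of
#' the mesh-based estimate.
#'
#' @param ea,eb [ellipsoid()] objects.
#' @param n_points Number of uniform samples (at least 1e4).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `volume` and binomial `se`.
#' @export
mc_overlap_oracle <- function(ea, eb, n_points = 1e6, seed = NULL) {
  stopifnot(inherits(ea, "ellipsoid"), inherits(eb, "ellipsoid"))
  n_points <- as.integer(n_points)
  if (n_points < 1e4) stop("n_points must be at least 10^4")
  if (!is.null(seed)) set.seed(seed)
  half <- sqrt(diag(ea$shape))
  x <- cbind(runif(n_points, -half[1], half[1]),
             runif(n_points, -half[2], half[2]),
             runif(n_points, -half[3], half[3]))
  x <- sweep(x, 2L, ea$center, "+")
  inside <- contains(ea, x) & contains(eb, x)
  phat <- mean(inside)
  box <- prod(2 * half)
  list(volume = box * phat,
       se = box * sqrt(phat * (1 - phat) / n_points))
}
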