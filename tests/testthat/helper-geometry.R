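# Shared fixtures: random rotations, SPD matrices and ellipsoids, built in
# code under the caller's seed.

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_spd <- function(eig_range = c(0.3, 2)) {
  r <- random_rotation()
  r %*% diag(runif(3, eig_range[1], eig_range[2])) %*% t(r)
}

random_ellipsoid <- function(center_sd = 0.5, eig_range = c(0.3, 2)) {
  ellipsoid(rnorm(3, 0, center_sd), random_spd(eig_range))
}

unit_sphere <- function(center = c(0, 0, 0)) ellipsoid(center, diag(3))

# closed-form volume of the lens shared by two unit spheres a distance d apart
lens_volume <- function(d, r = 1) pi * (4 * r + d) * (2 * r - d)^2 / 12
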