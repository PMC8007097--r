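# Small vector / quaternion helpers shared across modules. Internal.

.deg2rad <- pi / 180

.unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Three unit directions at the tetrahedral angle (109.47 deg) from -d1 and
# from each other; phi0 (degrees) rotates the triad about d1. Used to build
# idealized sp3 geometries: if an atom has a bond along d1, the remaining
# three substituents point along tetra_dirs(d1).
.tetra_dirs <- function(d1, phi0 = 0) {
  d1 <- .unitv(d1)
  a <- if (abs(d1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unitv(a - sum(a * d1) * d1)
  v <- .cross(d1, u)
  phis <- (phi0 + c(0, 120, 240)) * .deg2rad
  t(vapply(phis, function(p) {
    -d1 / 3 + (2 * sqrt(2) / 3) * (cos(p) * u + sin(p) * v)
  }, numeric(3)))
}

# Quaternions as length-4 numeric (w, x, y, z), unit norm.

.quat_identity <- c(1, 0, 0, 0)

.quat_mul <- function(q, p) {
  c(q[1] * p[1] - q[2] * p[2] - q[3] * p[3] - q[4] * p[4],
    q[1] * p[2] + q[2] * p[1] + q[3] * p[4] - q[4] * p[3],
    q[1] * p[3] - q[2] * p[4] + q[3] * p[1] + q[4] * p[2],
    q[1] * p[4] + q[2] * p[3] - q[3] * p[2] + q[4] * p[1])
}

.quat_from_axis_angle <- function(axis, angle) {
  axis <- .unitv(axis)
  c(cos(angle / 2), sin(angle / 2) * axis)
}

.quat_random <- function() {
  # Marsaglia: uniform on S^3 via normalized Gaussians.
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

.quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Rotate an n x 3 coordinate block by quaternion q.
.rotate_coords <- function(xyz, q) {
  xyz %*% t(.quat_to_matrix(q))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
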