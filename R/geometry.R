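# Rigid-body geometry: quaternions, rotations, minimum image, dihedrals,
# best-fit plane normals. Internal helpers shared by colvars and sampling.

R_GAS <- 8.3145e-3  # kJ mol^-1 K^-1

.kt <- function(temperature) R_GAS * temperature

#' Normalize a quaternion to unit length
#' @param q numeric length-4 (w, x, y, z)
#' @return unit quaternion
#' @keywords internal
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < 1e-12) stop("cannot normalize a near-zero quaternion")
  q / n
}

#' Rotation matrix of a unit quaternion
#'
#' Column-vector convention: \code{v_world = R \%*\% v_body}.
#' @param q unit quaternion (w, x, y, z)
#' @return 3x3 rotation matrix
#' @keywords internal
quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)),
    nrow = 3, byrow = TRUE)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Uniform random unit quaternion (uses the current RNG stream)
#' @keywords internal
random_quat <- function() quat_normalize(stats::rnorm(4))

# quaternion for rotation by `angle` about unit `axis`
axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis * axis))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# random small-rotation quaternion: uniform axis, uniform angle in [-max, max]
random_rotation_quat <- function(max_angle) {
  ax <- stats::rnorm(3)
  axis_angle_quat(ax, stats::runif(1, -max_angle, max_angle))
}

#' Minimum-image displacement in a cubic periodic box
#' @param d displacement (vector or array), nm
#' @param box box edge length, nm
#' @keywords internal
min_image <- function(d, box) d - box * round(d / box)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle over four points
#'
#' Standard atan2 formulation; result in (-pi, pi].
#' @param p1,p2,p3,p4 3-vectors
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1 * n1) < 1e-20 || sum(n2 * n2) < 1e-20)
    stop("dihedral undefined: collinear points")
  b2n <- b2 / sqrt(sum(b2 * b2))
  m1 <- cross3(n1, b2n)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

#' Best-fit plane normal of a point set
#'
#' Unit normal = right singular vector of the centred coordinates with the
#' smallest singular value.
#' @param coords n x 3 matrix, n >= 3
#' @keywords internal
plane_normal <- function(coords) {
  if (nrow(coords) < 3) stop("plane normal needs at least 3 points")
  cen <- sweep(coords, 2, colMeans(coords))
  sv <- svd(cen)
  # degenerate (collinear) points: second singular value ~ 0
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("plane normal undefined: collinear ring atoms")
  sv$v[, 3]
}

# world-frame coordinates of a template given pose (n x 3)
template_world <- function(coords, pos, quat) {
  R <- quat_to_mat(quat)
  sweep(coords %*% t(R), 2, pos, "+")
}

# run `expr` under a fixed seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
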