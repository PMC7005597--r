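# Unit-quaternion algebra used for rigid-body orientations.
# Convention: q = (w, x, y, z), scalar first; rotations act on column
# 3-vectors as R(q) v. All exported poses keep ||q|| = 1 within 1e-9.

#' Normalize a quaternion to unit length
#'
#' @param q Numeric vector of length 4, (w, x, y, z).
#' @return Unit quaternion as a numeric vector of length 4.
#' @export
quatNormalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < .Machine$double.eps) stop("cannot normalize a zero quaternion")
  q / n
}

#' Hamilton product of two quaternions
#'
#' `quatMultiply(a, b)` is the rotation "first b, then a":
#' R(a*b) = R(a) R(b).
#'
#' @param a,b Quaternions (w, x, y, z).
#' @return Product quaternion.
#' @export
quatMultiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion conjugate (inverse for unit quaternions)
#' @param q Quaternion.
#' @return Conjugate quaternion.
#' @export
quatConjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Rotation matrix equivalent of a unit quaternion
#' @param q Unit quaternion.
#' @return 3x3 rotation matrix \code{R} with \code{R \%*\% v} rotating v.
#' @export
quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion for a rotation about an axis
#' @param axis 3-vector (normalized internally).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion.
#' @export
quatFromAxisAngle <- function(axis, angle) {
  n <- sqrt(sum(axis * axis))
  if (n < .Machine$double.eps) stop("zero-length rotation axis")
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Geodesic angle between two orientations
#'
#' The rotation angle (radians, in [0, pi]) taking orientation `a` to `b`,
#' identifying q with -q.
#'
#' @param a,b Unit quaternions.
#' @return Angle in radians.
#' @export
quatAngle <- function(a, b) {
  d <- min(1, abs(sum(a * b)))
  2 * acos(d)
}

#' Spherical linear interpolation between orientations
#'
#' @param a,b Unit quaternions.
#' @param t Interpolation fraction in [0, 1]; 0 gives `a`, 1 gives `b`.
#' @return Unit quaternion on the shortest great-circle arc.
#' @export
quatSlerp <- function(a, b, t) {
  d <- sum(a * b)
  if (d < 0) { b <- -b; d <- -d }  # shortest arc
  if (d > 1 - 1e-12) {
    return(quatNormalize(a + t * (b - a)))
  }
  theta <- acos(min(1, d))
  quatNormalize((sin((1 - t) * theta) * a + sin(t * theta) * b) / sin(theta))
}

#' Uniform random orientation
#'
#' Samples a quaternion uniformly on the 3-sphere (Haar measure on SO(3))
#' by normalizing four standard normals; uses the current RNG stream.
#'
#' @param n Number of quaternions.
#' @return If n = 1 a length-4 vector, else an n x 4 matrix.
#' @export
randomQuaternion <- function(n = 1) {
  m <- matrix(stats::rnorm(4 * n), ncol = 4)
  m <- m / sqrt(rowSums(m^2))
  if (n == 1) m[1, ] else m
}

#' Minimal rotation aligning one direction with another
#'
#' Returns a unit quaternion q with R(q) v parallel to u (both inputs are
#' normalized internally). The antiparallel case uses any axis orthogonal
#' to v.
#'
#' @param v Source direction (3-vector).
#' @param u Target direction (3-vector).
#' @return Unit quaternion.
#' @export
quatAlignVectors <- function(v, u) {
  nv <- sqrt(sum(v * v)); nu <- sqrt(sum(u * u))
  if (nv < .Machine$double.eps || nu < .Machine$double.eps)
    stop("cannot align a zero-length vector")
  v <- v / nv; u <- u / nu
  d <- sum(v * u)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # 180 degrees about any axis orthogonal to v
    ax <- c(-v[2], v[1], 0)
    if (sum(ax * ax) < 1e-12) ax <- c(0, -v[3], v[2])
    return(quatFromAxisAngle(ax, pi))
  }
  ax <- c(v[2] * u[3] - v[3] * u[2],
          v[3] * u[1] - v[1] * u[3],
          v[1] * u[2] - v[2] * u[1])
  quatFromAxisAngle(ax, acos(max(-1, min(1, d))))
}
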