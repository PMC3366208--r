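## Small 3-vector and rotation helpers used throughout the model and engine.
## Positions are plain numeric length-3 vectors (nm) or n x 3 matrices.

#' Euclidean norm of a 3-vector
#' @param v numeric length-3 vector.
#' @return scalar norm.
#' @keywords internal
vnorm <- function(v) sqrt(sum(v * v))

#' Normalise a 3-vector to unit length
#' @param v numeric length-3 vector; must be non-zero.
#' @return unit vector.
#' @keywords internal
vhat <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis (Rodrigues form)
#'
#' @param axis numeric length-3 axis (need not be unit length).
#' @param angle rotation angle in radians (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- vhat(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * (u %o% u)
}

#' Rotate points about a pivot
#'
#' @param X n x 3 matrix (or length-3 vector) of positions.
#' @param axis rotation axis.
#' @param angle angle in radians.
#' @param pivot centre of rotation (default origin).
#' @return rotated positions, same shape as `X`.
#' @export
rotate_about <- function(X, axis, angle, pivot = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle)
  one_vec <- is.null(dim(X))
  if (one_vec) X <- matrix(X, 1, 3)
  out <- sweep(sweep(X, 2, pivot) %*% t(R), 2, pivot, `+`)
  if (one_vec) out[1, ] else out
}

#' Uniform random unit vectors
#'
#' Draws directions uniformly on the unit sphere (normalised Gaussian
#' triples), consuming the global RNG stream.
#'
#' @param n number of vectors.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  lens <- sqrt(rowSums(m * m))
  lens[lens < 1e-12] <- 1
  m / lens
}

#' Signed angle between two vectors in the plane orthogonal to a reference
#'
#' Both vectors are projected onto the plane orthogonal to `normal`; the
#' returned angle rotates the projection of `a` onto the projection of `b`,
#' right-handed about `normal`, in (-pi, pi].
#'
#' @param a,b numeric length-3 vectors.
#' @param normal plane normal defining the sign convention.
#' @return angle in radians.
#' @keywords internal
signed_angle_about <- function(a, b, normal) {
  n <- vhat(normal)
  ap <- a - sum(a * n) * n
  bp <- b - sum(b * n) * n
  if (vnorm(ap) < 1e-12 || vnorm(bp) < 1e-12) return(0)
  atan2(sum(n * pracma_cross(ap, bp)), sum(ap * bp))
}

## cross product (avoids pulling in pracma for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two vectors
#' @param a,b numeric length-3 vectors.
#' @return angle in radians in [0, pi].
#' @keywords internal
angle_between <- function(a, b) {
  ca <- sum(vhat(a) * vhat(b))
  acos(max(-1, min(1, ca)))
}
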