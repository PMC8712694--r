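# Small geometric primitives shared across the analyses. All coordinates are
# in Angstrom; all angles in degrees unless a function name says otherwise.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle` degrees
#' about the (not necessarily unit) 3-vector `axis`.
#'
#' @param axis numeric length-3 axis vector.
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg2rad(angle)
  ca <- cos(a); sa <- sin(a)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ca + sa * K + (1 - ca) * tcrossprod(u)
}

# Rotate the rows of an n x 3 matrix about `axis` through `origin`.
rotate_about <- function(xyz, axis, angle, origin = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle)
  sweep(sweep(xyz, 2L, origin) %*% t(R), 2L, origin, `+`)
}

#' Dihedral angle of four points
#'
#' Standard signed torsion angle p1-p2-p3-p4 in (-180, 180], computed with the
#' atan2 formulation (numerically stable near 0 and 180 degrees).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return dihedral angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang + 360 else ang
}

# cross product without pulling in an extra dependency
pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Quasi-uniform points on the unit sphere (Fibonacci lattice), used by the
# Shrake-Rupley quadrature. Returns an n x 3 matrix.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Centre of mass of selected rows (plain mean; all pseudo-atoms weigh equally).
centroid <- function(xyz, idx = NULL) {
  if (!is.null(idx)) xyz <- xyz[idx, , drop = FALSE]
  colMeans(xyz)
}

# Wrap an angle (degrees) into (-180, 180].
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  ifelse(w <= -180, w + 360, w)
}
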