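#' Rotation matrix from intrinsic Z-Y-Z Euler angles
#'
#' Builds the 3x3 rotation taking template-frame vectors into the tomogram
#' frame. The convention is intrinsic Z-Y-Z: first a spin `psi` about the
#' template z axis, then a tilt `theta` about the new y axis, then an
#' azimuthal rotation `phi` about the final z axis, i.e.
#' `R = Rz(phi) %*% Ry(theta) %*% Rz(psi)`.
#'
#' @param phi,theta,psi angles in degrees.
#' @return a 3x3 rotation matrix.
#' @export
#' @examples
#' euler_to_matrix(0, 90, 0) %*% c(0, 0, 1)  # z axis tilted onto x
euler_to_matrix <- function(phi, theta, psi) {
  rz <- function(a) {
    ca <- cos(a * pi / 180); sa <- sin(a * pi / 180)
    matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    ca <- cos(a * pi / 180); sa <- sin(a * pi / 180)
    matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
  }
  rz(phi) %*% ry(theta) %*% rz(psi)
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]. At the gimbal singularity (`theta` = 0 or
#' 180 degrees) `phi` is set to 0 and `psi` carries the full in-plane
#' rotation, which makes the decomposition deterministic.
#'
#' @param R a 3x3 rotation matrix.
#' @return named numeric vector `c(phi, theta, psi)` in degrees, with
#'   `theta` in `[0, 180]` and `phi`, `psi` in `[-180, 180)`.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct) * 180 / pi
  if (abs(ct) > 1 - 1e-12) {
    phi <- 0
    # R reduces to Rz(phi + sign * psi)
    psi <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    if (ct < 0) psi <- -psi
  } else {
    phi <- atan2(R[2, 3], R[1, 3]) * 180 / pi
    psi <- atan2(R[3, 2], -R[3, 1]) * 180 / pi
  }
  c(phi = wrap_angle(phi), theta = theta, psi = wrap_angle(psi))
}

#' Normalize Euler angles to canonical ranges
#'
#' Canonical ranges are `theta` in `[0, 180]`, `phi` and `psi` in
#' `[-180, 180)`. The operation is idempotent and preserves the rotation.
#'
#' @param phi,theta,psi angles in degrees (vectorized).
#' @return a three-column matrix with columns `phi`, `theta`, `psi`.
#' @export
normalize_euler <- function(phi, theta, psi) {
  n <- max(length(phi), length(theta), length(psi))
  phi <- rep_len(phi, n); theta <- rep_len(theta, n); psi <- rep_len(psi, n)
  out <- t(vapply(seq_len(n), function(i) {
    matrix_to_euler(euler_to_matrix(phi[i], theta[i], psi[i]))
  }, numeric(3)))
  colnames(out) <- c("phi", "theta", "psi")
  out
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == 180] <- -180
  a
}

#' Rotation aligning the +z axis onto a direction
#'
#' Returns Euler angles whose rotation takes the template +z axis onto the
#' given direction with zero in-plane spin (`psi = 0`), the convention used
#' to initialize particle orientations from membrane normals.
#'
#' @param v a 3-vector (need not be unit length).
#' @return named numeric vector `c(phi, theta, psi)` in degrees.
#' @export
z_axis_to_direction <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) abort("direction vector has zero length")
  v <- v / nv
  theta <- acos(max(-1, min(1, v[3]))) * 180 / pi
  phi <- if (abs(v[3]) > 1 - 1e-12) 0 else atan2(v[2], v[1]) * 180 / pi
  c(phi = wrap_angle(phi), theta = theta, psi = 0)
}

#' Angle between two rotations
#'
#' The geodesic angle (degrees) of the relative rotation `Ra' Rb`.
#' @param Ra,Rb 3x3 rotation matrices.
#' @return angle in degrees in `[0, 180]`.
#' @export
rotation_angle_between <- function(Ra, Rb) {
  R <- t(Ra) %*% Rb
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Axis and angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return list with unit `axis` and `angle` (degrees, in `[0, 180]`).
#' @export
rotation_axis_angle <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-9) return(list(axis = c(0, 0, 1), angle = 0))
  if (abs(ang - pi) < 1e-6) {
    # near 180 deg: axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    i <- which.max(ax)
    ax <- B[, i] / ax[i]
    ax <- ax / sqrt(sum(ax^2))
    return(list(axis = ax, angle = ang * 180 / pi))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  list(axis = ax, angle = ang * 180 / pi)
}

#' Rotation matrix from axis and angle
#' @param axis 3-vector (normalized internally).
#' @param angle degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_to_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
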