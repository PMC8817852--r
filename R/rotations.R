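# Rotation parameterisations: 3x3 matrices, axis-angle (Rodrigues) vectors,
# and the pitch/yaw/roll Euler convention used for head pose.
#
# Euler convention: R = Rz(roll) %*% Ry(yaw) %*% Rx(pitch), angles in degrees.
# Pitch rotates about the x axis (nodding), yaw about y (turning left/right),
# roll about z (swaying). In this composition order the middle (yaw) angle is
# confined to [-90, 90]; at |yaw| = 90 the decomposition is degenerate and
# roll is set to 0.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

check_rotation <- function(R, tol = 1e-6) {
  R <- as.matrix(R)
  if (!identical(dim(R), c(3L, 3L)) || !all(is.finite(R)))
    stop("R must be a finite 3 x 3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("R is not a rotation matrix (orthonormal with determinant +1)")
  R
}

#' Convert a rotation matrix to a Rodrigues (axis-angle) vector
#'
#' The returned vector points along the rotation axis and has length equal to
#' the rotation angle in radians. [rodrigues_to_rotation()] inverts the
#' conversion; the round trip is the identity to numerical tolerance.
#'
#' @param R a 3 x 3 rotation matrix.
#' @return A length-3 numeric rotation vector.
#' @export
rotation_to_rodrigues <- function(R) {
  R <- check_rotation(R)
  cos_theta <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(cos_theta)
  if (theta < 1e-10) return(c(0, 0, 0))
  if (pi - theta < 1e-6) {
    # near a half turn the skew part vanishes; recover the axis from R + I
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    # fix relative signs from the largest component
    k <- which.max(axis)
    sgn <- sign(B[k, ])
    sgn[sgn == 0] <- 1
    axis <- axis * sgn * sign(axis[k])
    axis <- axis / sqrt(sum(axis^2))
    return(axis * theta)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  axis * theta
}

#' Convert a Rodrigues (axis-angle) vector to a rotation matrix
#'
#' @param vec a length-3 numeric rotation vector (axis times angle in
#'   radians).
#' @return A 3 x 3 rotation matrix.
#' @export
rodrigues_to_rotation <- function(vec) {
  vec <- as.numeric(vec)
  stopifnot(length(vec) == 3L, all(is.finite(vec)))
  theta <- sqrt(sum(vec^2))
  if (theta < 1e-12) return(diag(3))
  k <- vec / theta
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Compose a rotation matrix from pitch/yaw/roll Euler angles
#'
#' Builds `R = Rz(roll) Ry(yaw) Rx(pitch)` with angles in degrees.
#'
#' @param pitch,yaw,roll angles in degrees about the x, y and z axes.
#' @return A 3 x 3 rotation matrix.
#' @export
euler_to_rotation <- function(pitch, yaw, roll) {
  p <- deg2rad(pitch); y <- deg2rad(yaw); r <- deg2rad(roll)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(p), -sin(p),
                 0, sin(p), cos(p)), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(y), 0, sin(y),
                 0, 1, 0,
                 -sin(y), 0, cos(y)), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(r), -sin(r), 0,
                 sin(r), cos(r), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Extract pitch/yaw/roll Euler angles from a rotation matrix
#'
#' Decomposes `R = Rz(roll) Ry(yaw) Rx(pitch)`; angles are reported in
#' degrees, pitch and roll in (-180, 180] and yaw in [-90, 90]. In the
#' degenerate configuration |yaw| = 90 the roll is set to 0 and the remaining
#' rotation is assigned to pitch.
#'
#' @param R a 3 x 3 rotation matrix.
#' @return A named numeric vector `c(pitch=, yaw=, roll=)` in degrees.
#' @export
rotation_to_euler <- function(R) {
  R <- check_rotation(R)
  sy <- sqrt(R[1, 1]^2 + R[2, 1]^2)
  if (sy > 1e-8) {
    pitch <- atan2(R[3, 2], R[3, 3])
    yaw   <- atan2(-R[3, 1], sy)
    roll  <- atan2(R[2, 1], R[1, 1])
  } else {
    pitch <- atan2(-R[2, 3], R[2, 2])
    yaw   <- atan2(-R[3, 1], sy)
    roll  <- 0
  }
  c(pitch = rad2deg(pitch), yaw = rad2deg(yaw), roll = rad2deg(roll))
}
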