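#' Rotation conventions
#'
#' Rotations are represented as unit quaternions `c(w, x, y, z)`, as 3x3
#' matrices acting on column vectors, or as intrinsic ZYZ Euler angles
#' (`rot`, `tilt`, `psi`) in degrees. The Euler convention is
#' `R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)`: a particle image is the
#' projection of the rotated density along +z. This convention is normative
#' for all metadata written by the package.
#'
#' @name rotations
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Convert ZYZ Euler angles (degrees) to a rotation matrix
#'
#' @param rot,tilt,psi Euler angles in degrees, intrinsic ZYZ.
#' @return A 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  rot_z(deg2rad(rot)) %*% rot_y(deg2rad(tilt)) %*% rot_z(deg2rad(psi))
}

#' Recover ZYZ Euler angles (degrees) from a rotation matrix
#'
#' At the gimbal singularities (`tilt` = 0 or 180 degrees) the convention
#' `psi = 0` is used and the full in-plane angle is carried by `rot`.
#'
#' @param R A 3x3 rotation matrix.
#' @return Named numeric vector `c(rot, tilt, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct)
  if (abs(sin(tilt)) < 1e-10) {
    # Rz(rot +/- psi) only is determined; put it all in rot.
    if (ct > 0) {
      rot <- atan2(R[2, 1], R[1, 1])
    } else {
      rot <- atan2(-R[2, 1], -R[1, 1])
    }
    psi <- 0
  } else {
    rot <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  }
  c(rot = rad2deg(rot), tilt = rad2deg(tilt), psi = rad2deg(psi))
}

#' Quaternion to rotation matrix
#'
#' @param q Unit quaternion `c(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Rotation matrix to quaternion
#'
#' Returns the representative with non-negative scalar part.
#'
#' @param R 3x3 rotation matrix.
#' @return Unit quaternion `c(w, x, y, z)`.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' @export
euler_to_quat <- function(rot, tilt, psi) {
  matrix_to_quat(euler_to_matrix(rot, tilt, psi))
}

#' @export
quat_to_euler <- function(q) {
  matrix_to_euler(quat_to_matrix(q))
}

#' Geodesic distance between two rotations
#'
#' @param q1,q2 Unit quaternions.
#' @return Rotation angle in radians, in `[0, pi]`.
#' @export
rotation_distance <- function(q1, q2) {
  d <- abs(sum(q1 * q2))
  2 * acos(max(-1, min(1, d)))
}

halton <- function(n, base) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    f <- 1; r <- 0; k <- i
    while (k > 0) {
      f <- f / base
      r <- r + f * (k %% base)
      k <- k %/% base
    }
    out[i] <- r
  }
  out
}

#' Quasi-uniform rotations on SO(3)
#'
#' Deterministic low-discrepancy cover of the rotation group: a Halton
#' sequence (bases 2, 3, 5, Cranley-Patterson rotated by a seed-derived
#' offset) mapped through the subgroup-algorithm parameterization of
#' uniform random rotations. Used to give simulated particle stacks evenly
#' distributed orientations.
#'
#' @param n Number of rotations.
#' @param seed Integer seed controlling the sequence offset.
#' @return An `n` x 4 matrix of unit quaternions (rows `c(w, x, y, z)`).
#' @export
quasi_uniform_rotations <- function(n, seed = 1) {
  set.seed(seed)
  off <- runif(3)
  u1 <- (halton(n, 2) + off[1]) %% 1
  u2 <- (halton(n, 3) + off[2]) %% 1
  u3 <- (halton(n, 5) + off[3]) %% 1
  q <- cbind(
    sqrt(u1) * cos(2 * pi * u3),
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3)
  )
  sgn <- ifelse(q[, 1] < 0, -1, 1)
  q * sgn
}
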