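# Rotation utilities shared across the tensor, Monte-Carlo, refinement and
# ensemble modules.  All angles at the user surface are in degrees; rotation
# matrices are proper (det = +1) and act on column vectors, v' = R %*% v.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Builds the proper rotation matrix for a right-handed rotation by
#' `angle` degrees about `axis` (Rodrigues' formula). The axis need not be
#' normalised.
#'
#' @param axis numeric length-3 axis (any non-zero length).
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  rdc_assert(is.numeric(axis) && length(axis) == 3 && all(is.finite(axis)),
             "axis must be a finite numeric vector of length 3")
  n <- sqrt(sum(axis^2))
  rdc_assert(n > 0, "rotation axis must be non-zero")
  u <- axis / n
  th <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' z-y-z Euler angles to rotation matrix
#'
#' Convention: `R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`, angles in degrees.
#'
#' @param alpha,beta,gamma Euler angles in degrees (z-y-z convention).
#' @return a 3x3 rotation matrix.
#' @export
euler_zyz_to_matrix <- function(alpha, beta, gamma) {
  rz <- function(a) {
    a <- deg2rad(a)
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- deg2rad(a)
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Rotation matrix to z-y-z Euler angles
#'
#' Inverse of [euler_zyz_to_matrix()]. Returns `c(alpha, beta, gamma)` in
#' degrees with `beta` in `[0, 180]` and `alpha`, `gamma` in `[0, 360)`.
#' At the gimbal singularities (`beta` = 0 or 180) `gamma` is set to 0 and
#' the full in-plane rotation is carried by `alpha`.
#'
#' @param R a 3x3 rotation matrix.
#' @return numeric length-3 vector of degrees, named alpha/beta/gamma.
#' @export
matrix_to_euler_zyz <- function(R) {
  rdc_assert(is.matrix(R) && all(dim(R) == 3), "R must be a 3x3 matrix")
  cb <- min(1, max(-1, R[3, 3]))
  beta <- acos(cb)
  if (sin(beta) > 1e-10) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    # beta ~ 0 or pi: alpha and gamma degenerate; put everything in alpha
    alpha <- atan2(R[2, 1], R[1, 1])
    if (cb < 0) alpha <- -alpha
    gamma <- 0
  }
  out <- rad2deg(c(alpha, beta, gamma))
  out[c(1, 3)] <- out[c(1, 3)] %% 360
  names(out) <- c("alpha", "beta", "gamma")
  out
}

#' Angle of a rotation matrix
#'
#' The rotation angle (degrees, in `[0, 180]`) of a proper rotation matrix,
#' from its trace.
#'
#' @param R a 3x3 rotation matrix.
#' @return angle in degrees.
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  rad2deg(acos(min(1, max(-1, ct))))
}

# Axis + angle (degrees) of a rotation matrix; axis is unit length, and for
# the identity (angle 0) an arbitrary z axis is returned.
rotation_axis_angle <- function(R) {
  ang <- rotation_angle(R)
  if (ang < 1e-9) return(list(axis = c(0, 0, 1), angle = 0))
  if (ang > 180 - 1e-7) {
    # axis from the symmetric part: R = 2 u u^T - I
    M <- (R + diag(3)) / 2
    i <- which.max(diag(M))
    u <- M[, i] / sqrt(M[i, i])
    return(list(axis = u / sqrt(sum(u^2)), angle = ang))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(list(axis = c(0, 0, 1), angle = ang))
  list(axis = v / nv, angle = ang)
}

#' Uniform random rotation matrices
#'
#' Samples rotations uniformly on the rotation group via normalised
#' Gaussian quaternions. Uses the current RNG state.
#'
#' @param n number of rotations.
#' @return a 3 x 3 x n array of rotation matrices.
#' @export
random_rotations <- function(n) {
  rdc_assert(n >= 1, "n must be >= 1")
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  out <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n)) out[, , i] <- quat_to_matrix(q[i, ])
  out
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# Rotate unit vector v about a uniformly random axis perpendicular to it by
# |N(0, sd_deg)| degrees (cone-style structural-noise move). Uses the
# current RNG state.
perturb_vector_cone <- function(v, sd_deg) {
  if (sd_deg == 0) return(v)
  r <- stats::rnorm(3)
  perp <- r - sum(r * v) * v
  nn <- sqrt(sum(perp^2))
  while (nn < 1e-12) {  # pathological draw parallel to v
    r <- stats::rnorm(3)
    perp <- r - sum(r * v) * v
    nn <- sqrt(sum(perp^2))
  }
  ang <- abs(stats::rnorm(1, 0, sd_deg))
  as.vector(rotation_about_axis(perp, ang) %*% v)
}
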