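# Tensor comparison: irreducible 5-vector form, the 5D inter-tensor
# angle, and Sanson-Flamsteed projection of principal axes.
#
# The 5-vector scaling is chosen so that its Euclidean inner product
# equals the Frobenius inner product of the Saupe matrices; the 5D angle
# is then identical to the matrix-level definition
# cos(theta) = <S1, S2>_F / (|S1|_F |S2|_F) with no convention ambiguity.

#' Irreducible 5-vector of an alignment tensor
#'
#' Norm-preserving linear map of the five independent Saupe components:
#' `(sqrt(3/2) Szz, (Sxx - Syy)/sqrt(2), sqrt(2) Sxy, sqrt(2) Sxz,
#' sqrt(2) Syz)`. The Euclidean norm equals the Frobenius norm of the
#' Saupe matrix and is invariant under rotation of the tensor.
#'
#' @param tensor an `alignment_tensor`.
#' @return numeric length-5 vector of class `irreducible5`.
#' @export
to_5vector <- function(tensor) {
  stopifnot(inherits(tensor, "alignment_tensor"))
  S <- tensor$saupe
  v <- c(sqrt(3 / 2) * S[3, 3],
         (S[1, 1] - S[2, 2]) / sqrt(2),
         sqrt(2) * S[1, 2],
         sqrt(2) * S[1, 3],
         sqrt(2) * S[2, 3])
  structure(v, class = "irreducible5",
            names = c("zz", "xx-yy", "xy", "xz", "yz"))
}

#' Rebuild an alignment tensor from its irreducible 5-vector
#'
#' Exact inverse of [to_5vector()].
#'
#' @param v length-5 numeric vector in [to_5vector()] component order.
#' @param scale dipolar constant (Hz) of the rebuilt tensor.
#' @return an `alignment_tensor`.
#' @export
from_5vector <- function(v, scale = DMAX_NH_DEFAULT) {
  rdc_assert(length(v) == 5, "v must have 5 components")
  v <- as.numeric(v)
  Szz <- v[1] / sqrt(3 / 2)
  d <- v[2] * sqrt(2)             # Sxx - Syy
  Sxx <- (-Szz + d) / 2
  Syy <- (-Szz - d) / 2
  S <- matrix(c(Sxx, v[3] / sqrt(2), v[4] / sqrt(2),
                v[3] / sqrt(2), Syy, v[5] / sqrt(2),
                v[4] / sqrt(2), v[5] / sqrt(2), Szz), 3, 3)
  alignment_tensor(S, scale = scale)
}

#' 5D angle between two alignment tensors
#'
#' Arc-cosine of the normalised inner product of the irreducible
#' 5-vectors, in degrees in `[0, 180]`. Equals the Frobenius-inner-product
#' angle between the Saupe matrices, and so compares both the orientation
#' and the shape (rhombicity) of the two alignments, independent of their
#' magnitudes.
#'
#' @param t1,t2 `alignment_tensor`s (both non-zero).
#' @return angle in degrees.
#' @export
five_d_angle <- function(t1, t2) {
  v1 <- as.numeric(to_5vector(t1))
  v2 <- as.numeric(to_5vector(t2))
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  rdc_assert(n1 > 0 && n2 > 0, "5D angle undefined for a zero tensor", "zero_tensor")
  rad2deg(acos(min(1, max(-1, sum(v1 * v2) / (n1 * n2)))))
}

#' Sanson-Flamsteed projection of the principal axes
#'
#' Maps each principal axis of the tensor to longitude/latitude on the
#' unit sphere and then to the equal-area sinusoidal projection
#' `x = lambda cos(phi), y = phi`. Axes are unsigned; each is replaced by
#' the antipodal representative with non-negative z (ties: non-negative
#' y, then x). For an axially symmetric tensor the x/y axes are not
#' unique and the `degenerate` flag is set.
#'
#' @param tensor an `alignment_tensor`.
#' @return data.frame with rows xx/yy/zz and columns `lambda`, `phi`,
#'   `x`, `y` (degrees); attribute `degenerate`.
#' @export
project_axes <- function(tensor) {
  p <- tensor_parameters(tensor)
  ax <- p$axes
  out <- do.call(rbind, lapply(1:3, function(i) project_axis(ax[, i])))
  rownames(out) <- c("xx", "yy", "zz")
  attr(out, "degenerate") <- p$degenerate
  out
}

# One unsigned axis -> (lambda, phi, x, y) in degrees.
project_axis <- function(u) {
  u <- u / sqrt(sum(u^2))
  if (u[3] < 0 ||
      (u[3] == 0 && (u[2] < 0 || (u[2] == 0 && u[1] < 0)))) u <- -u
  phi <- rad2deg(asin(min(1, max(-1, u[3]))))
  lambda <- if (abs(u[1]) < 1e-300 && abs(u[2]) < 1e-300) 0 else rad2deg(atan2(u[2], u[1]))
  if (lambda <= -180) lambda <- lambda + 360
  data.frame(lambda = lambda, phi = phi,
             x = lambda * cos(deg2rad(phi)), y = phi)
}

#' Per-axis angular differences between two tensors
#'
#' The angle (degrees, in `[0, 90]` because axes are unsigned) between
#' corresponding principal axes of two tensors.
#'
#' @param t1,t2 `alignment_tensor`s.
#' @return named numeric vector with elements `xx`, `yy`, `zz`.
#' @export
axis_angles <- function(t1, t2) {
  a1 <- tensor_parameters(t1)$axes
  a2 <- tensor_parameters(t2)$axes
  ang <- vapply(1:3, function(i) {
    ct <- abs(sum(a1[, i] * a2[, i]))
    rad2deg(acos(min(1, ct)))
  }, numeric(1))
  stats::setNames(ang, c("xx", "yy", "zz"))
}
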