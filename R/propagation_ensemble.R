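# Inter-domain alignment propagation: the tensor-magnitude order
# parameter, ensemble-averaged (propagated) alignment tensors, and
# generators for linker-rotation ensembles.
#
# The order parameter S^2 is the ratio of the alignment-tensor magnitude
# of an indirectly aligned domain to that of the directly aligned domain:
# 1 for rigid inter-domain coupling, 0 for a fully flexible linker.

#' Inter-domain order parameter from tensor magnitudes
#'
#' `S2 = mag_indirect / mag_direct`, with first-order (delta-method)
#' uncertainty
#' `sigma_S2 = S2 * sqrt((sd_indirect/mag_indirect)^2 +
#' (sd_direct/mag_direct)^2)`.
#'
#' @param mag_direct,sd_direct magnitude (> 0) and s.d. of the directly
#'   aligned domain's tensor (unitless, e.g. GDO).
#' @param mag_indirect,sd_indirect magnitude and s.d. of the indirectly
#'   aligned domain's tensor.
#' @return an `order_parameter` list: `S2`, `sigma_S2`, and the input
#'   magnitudes/s.d.s.
#' @export
order_parameter <- function(mag_direct, sd_direct, mag_indirect, sd_indirect) {
  rdc_assert(mag_direct > 0, "direct magnitude must be positive", "nonpositive_denominator")
  rdc_assert(sd_direct >= 0 && sd_indirect >= 0, "s.d.s must be >= 0")
  S2 <- mag_indirect / mag_direct
  sigma <- if (mag_indirect == 0) S2 * 0 else
    S2 * sqrt((sd_indirect / mag_indirect)^2 + (sd_direct / mag_direct)^2)
  structure(list(S2 = S2, sigma_S2 = sigma,
                 mag_direct = mag_direct, sd_direct = sd_direct,
                 mag_indirect = mag_indirect, sd_indirect = sd_indirect),
            class = "order_parameter")
}

#' @export
print.order_parameter <- function(x, ...) {
  cat(sprintf("order parameter S2 = %.2f +/- %.2f (indirect %.3g / direct %.3g)\n",
              x$S2, x$sigma_S2, x$mag_indirect, x$mag_direct))
  invisible(x)
}

#' Construct a two-domain conformer ensemble
#'
#' @param rotations 3 x 3 x n array of proper rotations of the mobile
#'   domain's frame relative to the reference frame.
#' @param weights conformer weights (>= 0; normalised to sum to 1;
#'   default uniform).
#' @param model,kappa,seed generator metadata.
#' @return a `two_domain_ensemble`.
#' @export
two_domain_ensemble <- function(rotations, weights = NULL, model = "custom",
                                kappa = NA_real_, seed = NA_integer_) {
  rdc_assert(is.array(rotations) && length(dim(rotations)) == 3 &&
             all(dim(rotations)[1:2] == 3) && dim(rotations)[3] >= 1,
             "rotations must be a 3 x 3 x n array")
  n <- dim(rotations)[3]
  for (i in seq_len(min(n, 25))) {  # spot-check orthogonality
    R <- rotations[, , i]
    rdc_assert(max(abs(t(R) %*% R - diag(3))) < 1e-6 && det(R) > 0,
               "rotations must be proper (orthogonal, det +1)")
  }
  if (is.null(weights)) weights <- rep(1 / n, n)
  rdc_assert(length(weights) == n && all(weights >= 0) && sum(weights) > 0,
             "weights must be non-negative and sum > 0")
  structure(list(rotations = rotations, weights = weights / sum(weights),
                 model = model, kappa = kappa, seed = seed),
            class = "two_domain_ensemble")
}

#' @export
print.two_domain_ensemble <- function(x, ...) {
  cat(sprintf("two_domain_ensemble: %d conformers, model '%s'%s\n",
              dim(x$rotations)[3], x$model,
              if (is.na(x$kappa)) "" else sprintf(" (kappa = %.3g)", x$kappa)))
  invisible(x)
}

#' Sample a linker-rotation ensemble
#'
#' `model = "random"` draws rotations uniformly on the rotation group
#' (fully flexible linker; `kappa` ignored). `model = "concentrated"`
#' draws rotation axes uniformly on the sphere and rotation angles
#' `omega` on `[0, pi]` with density proportional to
#' `exp(kappa * cos(omega))` — a single-parameter family interpolating
#' from (angle-)uniform at `kappa = 0` to the rigid limit as
#' `kappa -> Inf`, used as a tunable surrogate for a partially coupled
#' linker.
#'
#' @param model "random" or "concentrated".
#' @param kappa concentration parameter (>= 0), "concentrated" only.
#' @param n number of conformers (>= 1).
#' @param seed integer RNG seed; sampling is deterministic given the seed.
#' @return a [two_domain_ensemble()] with uniform weights.
#' @export
make_linker_ensemble <- function(model = c("random", "concentrated"),
                                 kappa = 0, n = 1000, seed = 1L) {
  model <- match.arg(model)
  rdc_assert(n >= 1, "n must be >= 1")
  rdc_assert(kappa >= 0, "kappa must be >= 0")
  set.seed(as.integer(seed))
  if (model == "random") {
    rots <- random_rotations(n)
  } else {
    omega <- sample_exp_cos_angle(n, kappa)
    ax <- matrix(stats::rnorm(3 * n), ncol = 3)
    ax <- ax / sqrt(rowSums(ax^2))
    rots <- array(0, dim = c(3, 3, n))
    for (i in seq_len(n)) rots[, , i] <- rotation_about_axis(ax[i, ], rad2deg(omega[i]))
  }
  two_domain_ensemble(rots, model = model,
                      kappa = if (model == "random") NA_real_ else kappa,
                      seed = as.integer(seed))
}

# Draw angles on [0, pi] with density ~ exp(kappa * cos(omega)) by
# numerical inversion of the CDF on a dense grid (grid narrowed to the
# region carrying mass for large kappa).
sample_exp_cos_angle <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, pi))
  upper <- if (kappa > 16) min(pi, 12 / sqrt(kappa)) else pi
  grid <- seq(0, upper, length.out = 4096)
  logf <- kappa * (cos(grid) - 1)
  f <- exp(logf)
  cdf <- cumsum((f[-1] + f[-length(f)]) / 2 * diff(grid))
  cdf <- c(0, cdf) / cdf[length(cdf)]
  u <- stats::runif(n)
  stats::approx(cdf, grid, xout = u, ties = "ordered")$y
}

#' Ensemble-propagated alignment tensor
#'
#' The effective tensor experienced by the mobile domain: the weighted
#' average of the direct tensor conjugated into each conformer's frame,
#' `S_eff = sum_c w_c t(R_c) S R_c` (traceless symmetric by
#' construction).
#'
#' @param direct the directly induced `alignment_tensor`.
#' @param ensemble a [two_domain_ensemble()].
#' @return an `alignment_tensor` in the mobile-domain frame.
#' @export
propagate_alignment <- function(direct, ensemble) {
  stopifnot(inherits(direct, "alignment_tensor"),
            inherits(ensemble, "two_domain_ensemble"))
  S <- direct$saupe
  acc <- matrix(0, 3, 3)
  w <- ensemble$weights
  for (i in seq_along(w)) {
    R <- ensemble$rotations[, , i]
    acc <- acc + w[i] * (t(R) %*% S %*% R)
  }
  acc <- (acc + t(acc)) / 2
  acc <- acc - diag(3) * sum(diag(acc)) / 3
  alignment_tensor(acc, scale = direct$scale)
}

#' Predicted inter-domain order parameter of an ensemble
#'
#' `GDO(propagated) / GDO(direct)` for a given direct tensor and linker
#' ensemble: 1 for a rigid linker, approaching 0 for a fully flexible
#' one.
#'
#' @param direct the directly induced `alignment_tensor` (non-zero).
#' @param ensemble a [two_domain_ensemble()].
#' @return unitless predicted S^2.
#' @export
predicted_s2 <- function(direct, ensemble) {
  rdc_assert(gdo(direct) > 0, "direct tensor must be non-zero", "zero_tensor")
  gdo(propagate_alignment(direct, ensemble)) / gdo(direct)
}

#' Compose two linker ensembles
#'
#' Pairwise composition of conformer rotations (`R2 %*% R1`), modelling
#' propagation through two sequential linkers; both ensembles must have
#' the same number of conformers (weights multiply and are renormalised).
#'
#' @param e1,e2 [two_domain_ensemble()]s of equal size.
#' @return a [two_domain_ensemble()].
#' @export
compose_ensembles <- function(e1, e2) {
  n1 <- dim(e1$rotations)[3]
  n2 <- dim(e2$rotations)[3]
  rdc_assert(n1 == n2, "ensembles must have the same number of conformers")
  rots <- array(0, dim = c(3, 3, n1))
  for (i in seq_len(n1)) rots[, , i] <- e2$rotations[, , i] %*% e1$rotations[, , i]
  two_domain_ensemble(rots, weights = e1$weights * e2$weights,
                      model = paste(e1$model, e2$model, sep = "+"))
}
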