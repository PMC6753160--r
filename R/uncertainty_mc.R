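# Monte-Carlo propagation of experimental RDC noise and structural noise
# into empirical distributions of alignment-tensor parameters.
#
# Each iteration draws independent Gaussian noise on every included
# coupling (s.d. = its own sigma_D) and reorients every bond vector about
# a uniformly random perpendicular axis by |N(0, structural_noise_angle)|
# degrees, refits the tensor, and records the fitted parameters.

#' Monte-Carlo specification
#'
#' @param n_iterations number of perturb-and-refit cycles (>= 1).
#' @param structural_noise_angle s.d. (degrees) of the random bond-vector
#'   reorientation modelling residual structural noise; 0 disables the
#'   channel. Default 5.
#' @param rdc_noise_scale multiplier on the per-record sigma_D used as the
#'   coupling noise s.d. (default 1; 0 disables the channel).
#' @param seed integer RNG seed.
#' @return an `mc_spec` list.
#' @export
mc_spec <- function(n_iterations = 1000, structural_noise_angle = 5,
                    rdc_noise_scale = 1, seed = 1L) {
  rdc_assert(n_iterations >= 1, "n_iterations must be >= 1")
  rdc_assert(structural_noise_angle >= 0 && rdc_noise_scale >= 0,
             "noise levels must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 structural_noise_angle = structural_noise_angle,
                 rdc_noise_scale = rdc_noise_scale,
                 seed = as.integer(seed)),
            class = "mc_spec")
}

# Deterministic per-iteration seed below 2^31.
iteration_seed <- function(seed, iteration) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(iteration)) %% 2147483629)
}

#' Perturb a dataset and bond vectors for one Monte-Carlo iteration
#'
#' Adds Gaussian noise of s.d. `rdc_noise_scale * sigma_D` to each
#' included coupling and rotates each bond vector about a uniformly
#' random perpendicular axis by an angle drawn from
#' |N(0, structural_noise_angle)|. Deterministic given (spec$seed,
#' iteration).
#'
#' @param dataset an [rdc_dataset()].
#' @param vectors a `bond_vectors` object.
#' @param spec an [mc_spec()].
#' @param iteration iteration index (used to derive the stream seed).
#' @return list with elements `dataset` and `vectors`.
#' @export
perturb_dataset <- function(dataset, vectors, spec, iteration = 1L) {
  stopifnot(inherits(spec, "mc_spec"))
  set.seed(iteration_seed(spec$seed, iteration))
  ds <- as.data.frame(dataset)
  if (spec$rdc_noise_scale > 0) {
    live <- !ds$excluded
    ds$D[live] <- ds$D[live] +
      stats::rnorm(sum(live), 0, spec$rdc_noise_scale * ds$sigma_D[live])
  }
  V <- unclass(vectors)
  if (spec$structural_noise_angle > 0) {
    for (i in seq_len(nrow(V)))
      V[i, ] <- perturb_vector_cone(V[i, ], spec$structural_noise_angle)
  }
  list(dataset = rdc_dataset(ds),
       vectors = bond_vectors(V, chain = attr(vectors, "chain"),
                              missing = attr(vectors, "missing"),
                              source = attr(vectors, "source")))
}

#' Monte-Carlo uncertainty of a fitted alignment tensor
#'
#' Runs `n_iterations` perturb-and-refit cycles and collects empirical
#' distributions of the fitted Saupe components, Da, rhombicity, GDO,
#' Euler angles and (optionally) the 5D angle to a reference tensor.
#' Euler angles are degeneracy-resolved per iteration by choosing the
#' equivalent frame closest to the unperturbed point estimate, then
#' summarised circularly.
#'
#' @param dataset an [rdc_dataset()].
#' @param vectors a `bond_vectors` object.
#' @param spec an [mc_spec()].
#' @param reference optional `alignment_tensor`; when given, the 5D angle
#'   of each iterate to it is recorded.
#' @param scale,weighted passed to [svd_fit()].
#' @return an `mc_result`: list with `samples` (data.frame, one row per
#'   successful iteration), `summary` (per-parameter mean, sd and central
#'   68/95% intervals; circular versions for angles), `point` (the
#'   unperturbed fit), `n_failed`, and the echoed `spec`.
#' @export
mc_tensor_uncertainty <- function(dataset, vectors, spec, reference = NULL,
                                  scale = DMAX_NH_DEFAULT, weighted = FALSE) {
  stopifnot(inherits(spec, "mc_spec"))
  point <- svd_fit(dataset, vectors, scale = scale, weighted = weighted)
  ref_euler <- point$parameters$euler

  cols <- c("Sxx", "Syy", "Szz", "Sxy", "Sxz", "Syz", "Da", "rhombicity",
            "magnitude", "alpha", "beta", "gamma", "angle5d")
  samples <- matrix(NA_real_, spec$n_iterations, length(cols),
                    dimnames = list(NULL, cols))
  failed <- 0L
  for (it in seq_len(spec$n_iterations)) {
    pert <- perturb_dataset(dataset, vectors, spec, it)
    fit <- tryCatch(svd_fit(pert$dataset, pert$vectors, scale = scale,
                            weighted = weighted),
                    rdcalign_error = function(e) NULL)
    if (is.null(fit)) {
      failed <- failed + 1L
      next
    }
    S <- fit$tensor$saupe
    eul <- closest_equivalent_euler(fit$tensor, ref_euler)
    samples[it, ] <- c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3],
                       fit$parameters$Da, fit$parameters$rhombicity,
                       fit$parameters$magnitude, eul,
                       if (is.null(reference)) NA_real_
                       else five_d_angle(fit$tensor, reference))
  }
  if (failed > 0.1 * spec$n_iterations)
    rdc_abort(sprintf("%d of %d Monte-Carlo fits failed (> 10%%)",
                      failed, spec$n_iterations), "mc_failures")
  samples <- as.data.frame(samples[stats::complete.cases(samples[, "Da"]), ,
                                   drop = FALSE])
  if (is.null(reference)) samples$angle5d <- NULL

  circular <- c("alpha", "beta", "gamma")
  summ <- do.call(rbind, lapply(names(samples), function(p) {
    x <- samples[[p]]
    if (p %in% circular) {
      data.frame(parameter = p, mean = circ_mean(x), sd = circ_sd(x),
                 lo68 = NA_real_, hi68 = NA_real_,
                 lo95 = NA_real_, hi95 = NA_real_)
    } else {
      q <- stats::quantile(x, c(0.16, 0.84, 0.025, 0.975), names = FALSE)
      data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
                 lo68 = q[1], hi68 = q[2], lo95 = q[3], hi95 = q[4])
    }
  }))
  structure(list(samples = samples, summary = summ, point = point,
                 n_failed = failed, spec = spec),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("mc_result: %d iterations (%d failed), seed %d\n",
              x$spec$n_iterations, x$n_failed, x$spec$seed))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

# Of the four equivalent principal frames of `tensor`, the Euler triple
# closest (as a rotation) to `ref_euler`.
closest_equivalent_euler <- function(tensor, ref_euler) {
  cands <- equivalent_frames(tensor)
  Rref <- euler_zyz_to_matrix(ref_euler[1], ref_euler[2], ref_euler[3])
  d <- apply(cands, 1, function(e) {
    Rc <- euler_zyz_to_matrix(e[1], e[2], e[3])
    rotation_angle(t(Rref) %*% Rc)
  })
  cands[which.min(d), ]
}

# Circular mean / s.d. (degrees) via the mean resultant vector.
circ_mean <- function(x) {
  m <- atan2(mean(sin(deg2rad(x))), mean(cos(deg2rad(x))))
  rad2deg(m) %% 360
}

circ_sd <- function(x) {
  Rbar <- sqrt(mean(cos(deg2rad(x)))^2 + mean(sin(deg2rad(x)))^2)
  Rbar <- min(1, Rbar)
  if (Rbar <= 0) return(Inf)
  rad2deg(sqrt(-2 * log(Rbar)))
}
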