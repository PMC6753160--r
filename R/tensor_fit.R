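# Saupe alignment-tensor representation, back-calculation of RDCs,
# SVD least-squares fitting, and agreement scores.
#
# An alignment tensor is stored as the unitless traceless symmetric 3x3
# Saupe order matrix S plus a dipolar interaction constant `scale` (Hz),
# so that the coupling of a unit bond vector b is D = scale * t(b) S b.
# The default scale corresponds to an N-H dipolar constant of 21.7 kHz
# (r_NH = 1.04 A); all dimensionless results (Q, rhombicity, angles,
# order parameters) are invariant to this constant.

DMAX_NH_DEFAULT <- 21700  # Hz

#' Construct an alignment tensor
#'
#' @param saupe symmetric traceless 3x3 matrix (unitless order matrix).
#'   Small numerical asymmetry/trace (< 1e-8 relative) is projected out;
#'   larger violations are an error.
#' @param scale dipolar interaction constant in Hz; `D = scale * t(b) S b`.
#' @return an object of class `alignment_tensor`.
#' @export
alignment_tensor <- function(saupe, scale = DMAX_NH_DEFAULT) {
  rdc_assert(is.matrix(saupe) && all(dim(saupe) == 3) && all(is.finite(saupe)),
             "saupe must be a finite 3x3 matrix")
  nrm <- max(abs(saupe), 1e-300)
  rdc_assert(max(abs(saupe - t(saupe))) <= 1e-8 * nrm,
             "saupe matrix must be symmetric")
  rdc_assert(abs(sum(diag(saupe))) <= 1e-8 * nrm * 3,
             "saupe matrix must be traceless")
  S <- (saupe + t(saupe)) / 2
  S <- S - diag(3) * sum(diag(S)) / 3
  dimnames(S) <- list(c("x", "y", "z"), c("x", "y", "z"))
  structure(list(saupe = S, scale = scale), class = "alignment_tensor")
}

#' Build an alignment tensor from axial/rhombic parameters and orientation
#'
#' The principal-frame Saupe matrix is `diag(Axx, Ayy, Azz)` with
#' `Azz = 2 Da / scale`, `Axx - Ayy = 3 R Azz / 2` (so rhombicity
#' `R = (2/3)(Axx - Ayy)/Azz` under the |Azz| >= |Ayy| >= |Axx| ordering),
#' and it is carried into the reference (PDB) frame by the z-y-z Euler
#' rotation `euler`.
#'
#' @param Da axial component in Hz (`Da = scale * Azz / 2`).
#' @param rhombicity rhombicity R in `[0, 2/3]`.
#' @param euler z-y-z Euler angles (degrees) rotating reference-frame
#'   coordinates into the principal axis frame. Default `c(0,0,0)`.
#' @param scale dipolar constant in Hz.
#' @return an `alignment_tensor`.
#' @export
tensor_from_parameters <- function(Da, rhombicity = 0, euler = c(0, 0, 0),
                                   scale = DMAX_NH_DEFAULT) {
  rdc_assert(rhombicity >= 0 && rhombicity <= 2 / 3,
             "rhombicity must lie in [0, 2/3]")
  Azz <- 2 * Da / scale
  d <- 1.5 * rhombicity * Azz           # Axx - Ayy = (3/2) R Azz
  Axx <- (-Azz + d) / 2
  Ayy <- (-Azz - d) / 2
  Spaf <- diag(c(Axx, Ayy, Azz))
  Rm <- euler_zyz_to_matrix(euler[1], euler[2], euler[3])  # ref -> PAF
  alignment_tensor(t(Rm) %*% Spaf %*% Rm, scale = scale)
}

#' @export
print.alignment_tensor <- function(x, ...) {
  p <- tensor_parameters(x)
  cat(sprintf("alignment_tensor: Da = %.3g Hz, R = %.3f, GDO = %.3g (scale %.4g Hz)\n",
              p$Da, p$rhombicity, p$magnitude, x$scale))
  invisible(x)
}

#' Generalized degree of order
#'
#' Rotation-invariant scalar magnitude of an alignment tensor,
#' `GDO = sqrt(2/3 * sum(S^2))` over all nine Saupe matrix elements.
#'
#' @param tensor an `alignment_tensor`.
#' @return unitless magnitude (>= 0).
#' @export
gdo <- function(tensor) {
  stopifnot(inherits(tensor, "alignment_tensor"))
  sqrt(2 / 3 * sum(tensor$saupe^2))
}

#' Back-calculate RDCs from a tensor and bond vectors
#'
#' `D_i = scale * t(b_i) S b_i` for every bond vector; equivalently
#' `Da * (3 cos^2 theta - 1 + 1.5 R sin^2 theta cos 2 phi)` in the
#' principal frame.
#'
#' @param tensor an `alignment_tensor`.
#' @param vectors a `bond_vectors` object (or plain n x 3 matrix with
#'   residue rownames).
#' @return named numeric vector of couplings (Hz), names = residue numbers.
#' @export
back_calculate <- function(tensor, vectors) {
  stopifnot(inherits(tensor, "alignment_tensor"))
  B <- unclass(vectors)
  D <- tensor$scale * rowSums((B %*% tensor$saupe) * B)
  names(D) <- rownames(vectors)
  D
}

# Design matrix for the 5-parameter linear problem
# D/scale = s1 (x^2 - z^2) + s2 (y^2 - z^2) + s3 2xy + s4 2xz + s5 2yz
# with s = (Sxx, Syy, Sxy, Sxz, Syz) and Szz = -Sxx - Syy.
rdc_design_matrix <- function(B) {
  cbind(B[, 1]^2 - B[, 3]^2,
        B[, 2]^2 - B[, 3]^2,
        2 * B[, 1] * B[, 2],
        2 * B[, 1] * B[, 3],
        2 * B[, 2] * B[, 3])
}

saupe_from_components <- function(s) {
  matrix(c(s[1], s[3], s[4],
           s[3], s[2], s[5],
           s[4], s[5], -s[1] - s[2]), 3, 3)
}

saupe_components <- function(S) {
  c(Sxx = S[1, 1], Syy = S[2, 2], Sxy = S[1, 2], Sxz = S[1, 3], Syz = S[2, 3])
}

#' Fit an alignment tensor to measured RDCs by SVD
#'
#' Solves the linear least-squares problem relating the five independent
#' Saupe-matrix components to the measured couplings via singular-value
#' decomposition of the direction-cosine design matrix, then derives the
#' principal-frame parameters, back-calculated couplings, Q factor and
#' rmsd. Only records not flagged as excluded and with a matching bond
#' vector enter the fit.
#'
#' @param dataset an [rdc_dataset()].
#' @param vectors a `bond_vectors` object.
#' @param scale dipolar constant in Hz used to convert couplings to
#'   order-matrix units.
#' @param weighted if TRUE, rows are weighted by `1/sigma_D` (weighted
#'   least squares); default FALSE (PALES-style unweighted fit).
#' @param q_convention passed to [q_factor()].
#' @param max_condition condition-number threshold above which the bond
#'   geometry is declared degenerate.
#' @return an object of class `rdc_fit` with elements `tensor`,
#'   `parameters`, `back_calculated` (all vector residues), `observed`,
#'   `Q`, `rmsd` (Hz), `n_used`, `condition_number`, `residues_used`.
#' @export
svd_fit <- function(dataset, vectors, scale = DMAX_NH_DEFAULT,
                    weighted = FALSE, q_convention = c("rms_obs", "da_r"),
                    max_condition = 1e8) {
  q_convention <- match.arg(q_convention)
  ds <- as.data.frame(dataset)
  ds <- ds[!ds$excluded, , drop = FALSE]
  res_v <- residues_of(vectors)
  ds <- ds[ds$resno %in% res_v, , drop = FALSE]
  if (nrow(ds) < 5)
    rdc_abort(sprintf("need >= 5 usable RDCs with bond vectors, have %d", nrow(ds)),
              "too_few_rdcs")
  B <- unclass(vectors)[match(ds$resno, res_v), , drop = FALSE]
  A <- rdc_design_matrix(B)
  b <- ds$D / scale
  if (weighted) {
    w <- 1 / pmax(ds$sigma_D, 1e-12)
    A <- A * w
    b <- b * w
  }
  sv <- svd(A)
  cond <- sv$d[1] / sv$d[5]
  if (!is.finite(cond) || cond > max_condition)
    rdc_abort(paste0("degenerate bond-vector geometry: design matrix is rank-",
                     "deficient (condition number ", format(cond, digits = 3),
                     "); couplings do not determine all five tensor components"),
              "rank_deficient")
  s <- sv$v %*% ((t(sv$u) %*% b) / sv$d)
  tensor <- alignment_tensor(saupe_from_components(as.numeric(s)), scale = scale)
  calc_all <- back_calculate(tensor, vectors)
  obs <- stats::setNames(ds$D, ds$resno)
  calc_used <- calc_all[as.character(ds$resno)]
  params <- tensor_parameters(tensor)
  Q <- q_factor(obs, calc_used, convention = q_convention,
                Da = params$Da, rhombicity = params$rhombicity)
  structure(list(tensor = tensor, parameters = params,
                 back_calculated = calc_all, observed = obs,
                 Q = Q, rmsd = sqrt(mean((calc_used - obs)^2)),
                 n_used = nrow(ds), condition_number = cond,
                 residues_used = ds$resno),
            class = "rdc_fit")
}

#' @export
print.rdc_fit <- function(x, ...) {
  cat(sprintf("rdc_fit: n = %d, Q = %.4f, rmsd = %.3f Hz, Da = %.3f Hz, R = %.3f\n",
              x$n_used, x$Q, x$rmsd, x$parameters$Da, x$parameters$rhombicity))
  cat(sprintf("  euler (zyz): %.1f %.1f %.1f deg; GDO = %.3g; cond = %.3g\n",
              x$parameters$euler[1], x$parameters$euler[2], x$parameters$euler[3],
              x$parameters$magnitude, x$condition_number))
  invisible(x)
}

#' RDC Q factor
#'
#' `Q = rms(D_calc - D_obs) / rms(D_obs)` over the shared residues
#' (convention "rms_obs"); alternatively the denominator
#' `sqrt(2 Da^2 (4 + 3 R^2) / 5)` ("da_r").
#'
#' @param observed,calculated named numeric vectors of couplings (Hz),
#'   names = residue numbers.
#' @param convention denominator convention, see above.
#' @param Da,rhombicity required for the "da_r" convention.
#' @return unitless Q.
#' @export
q_factor <- function(observed, calculated, convention = c("rms_obs", "da_r"),
                     Da = NULL, rhombicity = NULL) {
  convention <- match.arg(convention)
  shared <- intersect(names(observed), names(calculated))
  rdc_assert(length(shared) > 0, "no shared residues between observed and calculated",
             "empty_intersection")
  o <- observed[shared]
  c_ <- calculated[shared]
  num <- sqrt(mean((c_ - o)^2))
  if (convention == "rms_obs") {
    den <- sqrt(mean(o^2))
    rdc_assert(den > 0, "rms of observed couplings is zero", "zero_observed")
  } else {
    rdc_assert(!is.null(Da) && !is.null(rhombicity),
               "Da and rhombicity required for the da_r convention")
    den <- sqrt(2 * Da^2 * (4 + 3 * rhombicity^2) / 5)
    rdc_assert(den > 0, "Da must be non-zero for the da_r convention", "zero_observed")
  }
  num / den
}

#' Principal-frame parameters of an alignment tensor
#'
#' Eigendecomposition with the standard ordering |Azz| >= |Ayy| >= |Axx|,
#' giving the axial component `Da = scale * Azz / 2`, the rhombicity
#' `R = (2/3)(Axx - Ayy)/Azz` in `[0, 2/3]`, the z-y-z Euler angles of the
#' rotation from the reference (PDB) frame into the principal axis frame
#' (canonical representative with beta in `[0, 90]`), and the generalized
#' degree of order.
#'
#' @param tensor an `alignment_tensor`.
#' @return a list of class `tensor_parameters`: `Da` (Hz), `rhombicity`,
#'   `euler` (degrees), `magnitude` (GDO), `eigenvalues` (Axx, Ayy, Azz),
#'   `axes` (3x3, columns = principal x/y/z in the reference frame),
#'   `degenerate` (TRUE for an axially symmetric or zero tensor, whose
#'   x/y axes are not unique).
#' @export
tensor_parameters <- function(tensor) {
  stopifnot(inherits(tensor, "alignment_tensor"))
  S <- tensor$saupe
  mag <- gdo(tensor)
  if (mag == 0)
    return(structure(list(Da = 0, rhombicity = 0, euler = c(alpha = NA_real_,
                          beta = NA_real_, gamma = NA_real_), magnitude = 0,
                          eigenvalues = c(Axx = 0, Ayy = 0, Azz = 0),
                          axes = diag(3), degenerate = TRUE),
                     class = "tensor_parameters"))
  e <- eigen(S, symmetric = TRUE)
  o <- order(abs(e$values))          # |Axx| <= |Ayy| <= |Azz|
  vals <- e$values[o]
  V <- e$vectors[, o, drop = FALSE]  # columns: x, y, z principal axes
  if (det(V) < 0) V[, 1] <- -V[, 1]
  Axx <- vals[1]; Ayy <- vals[2]; Azz <- vals[3]
  Da <- tensor$scale * Azz / 2
  R <- (2 / 3) * (Axx - Ayy) / Azz
  degenerate <- abs(Axx - Ayy) <= 1e-9 * max(abs(vals))

  euler <- canonical_euler(V)
  structure(list(Da = Da, rhombicity = R, euler = euler, magnitude = mag,
                 eigenvalues = c(Axx = Axx, Ayy = Ayy, Azz = Azz),
                 axes = V, degenerate = degenerate),
            class = "tensor_parameters")
}

# Canonical Euler representative over the 4-fold tensor-frame degeneracy:
# beta in [0, 90]; ties broken by smallest alpha, then gamma.
canonical_euler <- function(V) {
  cands <- equivalent_frame_eulers(V)
  ok <- cands[cands[, "beta"] <= 90 + 1e-9, , drop = FALSE]
  if (nrow(ok) == 0) ok <- cands
  ok <- ok[order(round(ok[, "beta"], 9), round(ok[, "alpha"], 9),
                 round(ok[, "gamma"], 9)), , drop = FALSE]
  ok[1, ]
}

# All four proper sign choices of the principal axes (the pi rotations of
# the D2 symmetry group of a symmetric tensor), as zyz Euler triples.
equivalent_frame_eulers <- function(V) {
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  out <- t(vapply(flips, function(f) {
    Vk <- V %*% diag(f)
    matrix_to_euler_zyz(t(Vk))   # rows of t(V) map reference -> PAF
  }, numeric(3)))
  colnames(out) <- c("alpha", "beta", "gamma")
  out
}

#' Enumerate the equivalent principal-frame orientations of a tensor
#'
#' A symmetric tensor's principal frame is defined only up to the four
#' proper sign combinations of its axes; this returns all four z-y-z Euler
#' triples (degrees).
#'
#' @param tensor an `alignment_tensor`.
#' @return a 4 x 3 matrix with columns alpha, beta, gamma.
#' @export
equivalent_frames <- function(tensor) {
  p <- tensor_parameters(tensor)
  equivalent_frame_eulers(p$axes)
}

#' Rotate an alignment tensor
#'
#' Conjugates the Saupe matrix: the returned tensor is the original one
#' carried through the frame rotation `R` (`S' = R S t(R)`).
#'
#' @param tensor an `alignment_tensor`.
#' @param R a 3x3 rotation matrix.
#' @return an `alignment_tensor`.
#' @export
rotate_tensor <- function(tensor, R) {
  stopifnot(inherits(tensor, "alignment_tensor"))
  alignment_tensor(R %*% tensor$saupe %*% t(R), scale = tensor$scale)
}

#' Analytic (delta-method) uncertainties of fitted Saupe components
#'
#' First-order propagation of the per-record RDC uncertainties through the
#' unweighted linear least-squares fit: `cov(s) = P Sigma t(P)` with
#' `P = (AtA)^-1 t(A)` the pseudoinverse of the design matrix and
#' `Sigma = diag(sigma_D^2 / scale^2)`.
#'
#' @inheritParams svd_fit
#' @return named numeric vector of standard deviations of the five fitted
#'   components (Sxx, Syy, Sxy, Sxz, Syz), unitless.
#' @export
analytic_saupe_sd <- function(dataset, vectors, scale = DMAX_NH_DEFAULT) {
  ds <- as.data.frame(dataset)
  ds <- ds[!ds$excluded, , drop = FALSE]
  res_v <- residues_of(vectors)
  ds <- ds[ds$resno %in% res_v, , drop = FALSE]
  rdc_assert(nrow(ds) >= 5, "need >= 5 usable records", "too_few_rdcs")
  B <- unclass(vectors)[match(ds$resno, res_v), , drop = FALSE]
  A <- rdc_design_matrix(B)
  P <- solve(crossprod(A), t(A))
  covm <- P %*% diag((ds$sigma_D / scale)^2, nrow(ds)) %*% t(P)
  stats::setNames(sqrt(diag(covm)), c("Sxx", "Syy", "Sxy", "Sxz", "Syz"))
}
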