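# Rigid-body refinement of secondary-structure-element orientations
# against measured RDCs.
#
# The refined degrees of freedom are one proper rotation per element
# (about its C-alpha centroid) plus a global rotation of the alignment
# tensor frame; the tensor's axial magnitude and rhombicity are held
# fixed. The target is a soft square-well restraint energy whose well
# half-widths are the per-record experimental uncertainties, minimised by
# Metropolis simulated annealing with geometric cooling followed by a
# greedy quench with shrinking move sizes. Translations are excluded
# (RDCs are orientation-only observables), loops and linkers are left at
# their template coordinates, and no covalent bookkeeping is done at
# element junctions: junction distortion is reported as a diagnostic, not
# repaired.
#
# Gauge convention: RDCs are invariant under a common rotation of all
# elements and the tensor frame, so per-element rotations are only
# defined relative to a reference. The reported solution is re-expressed
# in the gauge in which the element carrying the most restraints (ties:
# first in the definition) has zero net rotation; its reorientation
# relative to the alignment frame is carried by the tensor orientation.

#' Refinement configuration
#'
#' @param Da,rhombicity fixed axial component (Hz) and rhombicity for
#'   back-calculation; if NULL, taken from an SVD fit to the template.
#' @param t0 initial annealing temperature (energy units); NULL means
#'   calibrate automatically so the initial acceptance is about 50%.
#' @param cooling geometric cooling factor in (0, 1) (default 0.95).
#' @param steps_per_temp Monte-Carlo moves per temperature (default 200).
#' @param n_temperatures number of temperature steps (default 50).
#' @param max_sse_rotation largest single-move element rotation, degrees
#'   (default 2).
#' @param max_tensor_rotation largest single-move tensor-frame rotation,
#'   degrees (default 2).
#' @param k restraint force constant in Hz^-2 (default 1).
#' @param float_tensor allow the tensor frame to rotate (default TRUE).
#' @param quench_steps greedy downhill moves (with geometrically
#'   shrinking move size) run after the annealing schedule (default
#'   3000; 0 disables).
#' @param seed integer RNG seed.
#' @return a `refine_config` list.
#' @export
refine_config <- function(Da = NULL, rhombicity = NULL, t0 = NULL,
                          cooling = 0.95, steps_per_temp = 200,
                          n_temperatures = 50, max_sse_rotation = 2,
                          max_tensor_rotation = 2, k = 1,
                          float_tensor = TRUE, quench_steps = 3000, seed = 1L) {
  rdc_assert(cooling > 0 && cooling < 1, "cooling factor must be in (0, 1)")
  rdc_assert(max_sse_rotation > 0 && max_tensor_rotation > 0,
             "move sizes must be positive")
  rdc_assert(steps_per_temp >= 1 && n_temperatures >= 1, "schedule must be non-empty")
  structure(list(Da = Da, rhombicity = rhombicity, t0 = t0, cooling = cooling,
                 steps_per_temp = as.integer(steps_per_temp),
                 n_temperatures = as.integer(n_temperatures),
                 max_sse_rotation = max_sse_rotation,
                 max_tensor_rotation = max_tensor_rotation,
                 k = k, float_tensor = isTRUE(float_tensor),
                 quench_steps = as.integer(quench_steps),
                 seed = as.integer(seed)),
            class = "refine_config")
}

#' Soft square-well RDC restraint energy
#'
#' `E = k * sum_i max(0, |D_calc_i - D_obs_i| - width_i)^2` over included
#' records: zero inside the well (residual within the experimental
#' uncertainty), quadratic outside, with a continuous first derivative at
#' the well edge.
#'
#' @param observed an [rdc_dataset()] (or data.frame with `resno`, `D`,
#'   `excluded`).
#' @param calculated named numeric vector of back-calculated couplings.
#' @param widths named numeric vector of well half-widths (Hz, >= 0),
#'   residue -> width.
#' @param k force constant in Hz^-2.
#' @return unitless energy.
#' @export
restraint_energy <- function(observed, calculated, widths, k = 1) {
  ds <- as.data.frame(observed)
  ds <- ds[!ds$excluded, , drop = FALSE]
  key <- as.character(ds$resno)
  rdc_assert(all(key %in% names(calculated)),
             "calculated couplings missing for some restrained residues")
  w <- widths[key]
  rdc_assert(all(!is.na(w)) && all(w >= 0), "well widths must be >= 0 for all residues")
  excess <- pmax(0, abs(calculated[key] - ds$D) - w)
  k * sum(excess^2)
}

#' Refine element orientations against RDCs by simulated annealing
#'
#' See the module header for the model. Every restrained (included)
#' record must lie inside a secondary-structure element and have a bond
#' vector; each element must contribute at least 3 vectors. The run is
#' deterministic for a given seed.
#'
#' @param template an [rdc_structure()] (the template coordinates).
#' @param sses an [sse_definition()].
#' @param dataset an [rdc_dataset()] of restraints.
#' @param config a [refine_config()].
#' @param chain chain to refine (default: first chain).
#' @param scale dipolar constant (Hz).
#' @return a `refine_result`: list with `structure` (refined), `rotations`
#'   (per element: axis, angle in degrees), `tensor` (final
#'   `alignment_tensor`), `tensor_euler`, `energy_trace` (best-so-far
#'   energy per temperature), `energy_initial`, `energy_final`,
#'   `q_before`, `q_after`, `ca_rmsd_all`, `ca_rmsd_sse` (Angstrom),
#'   `junction_max_shift` (Angstrom, largest displacement of an element
#'   boundary atom — the chain-closure diagnostic), and `config`.
#' @export
refine_orientations <- function(template, sses, dataset, config = refine_config(),
                                chain = NULL, scale = DMAX_NH_DEFAULT) {
  stopifnot(inherits(template, "rdc_structure"), inherits(sses, "sse_definition"))
  vec_all <- extract_nh_vectors(template, chain)
  ds <- as.data.frame(dataset)
  ds <- ds[!ds$excluded, , drop = FALSE]
  if (nrow(ds) == 0) {
    # under-restraint safety: nothing to refine, template returned as-is
    rotations <- lapply(seq_len(nrow(sses)), function(i)
      list(label = sses$label[i], axis = c(0, 0, 1), angle = 0, matrix = diag(3)))
    names(rotations) <- sses$label
    return(structure(list(structure = template, rotations = rotations,
                          tensor = NULL, tensor_euler = rep(NA_real_, 3),
                          energy_trace = numeric(0), energy_initial = 0,
                          energy_final = 0, q_before = NA_real_,
                          q_after = NA_real_, ca_rmsd_all = 0, ca_rmsd_sse = 0,
                          junction_max_shift = 0, config = config),
                     class = "refine_result"))
  }

  in_sse <- ds$resno %in% sse_residues(sses)
  if (!all(in_sse))
    rdc_abort(paste("restrained residues outside any element:",
                    paste(ds$resno[!in_sse], collapse = ", ")),
              "restraint_outside_element")
  has_vec <- ds$resno %in% residues_of(vec_all)
  rdc_assert(all(has_vec), "restrained residues missing bond vectors")

  # per-element bookkeeping
  n_el <- nrow(sses)
  el_res <- lapply(seq_len(n_el), function(i) sses$start[i]:sses$end[i])
  res_used <- ds$resno
  el_rows <- lapply(el_res, function(rr) which(res_used %in% rr))
  for (i in seq_len(n_el))
    if (length(el_rows[[i]]) < 3)
      rdc_abort(sprintf("element %s has %d restrained vectors (< 3)",
                        sses$label[i], length(el_rows[[i]])), "degenerate_element")

  V0 <- unclass(vec_all)[match(res_used, residues_of(vec_all)), , drop = FALSE]
  obs <- ds$D
  widths <- pmax(ds$sigma_D, 0)
  k <- config$k

  # initial tensor from the template fit; Da, R fixed thereafter
  fit0 <- svd_fit(dataset, vec_all, scale = scale)
  Da <- if (is.null(config$Da)) fit0$parameters$Da else config$Da
  Rh <- if (is.null(config$rhombicity)) fit0$parameters$rhombicity else config$rhombicity
  eul0 <- fit0$parameters$euler
  S0 <- tensor_from_parameters(Da, Rh, eul0, scale = scale)$saupe

  # returns c(soft-well energy, plain sum of squared residuals); the
  # second is used only to break ties on the flat well bottom
  energy_of2 <- function(rot_list, Rt) {
    S <- Rt %*% S0 %*% t(Rt)
    E <- 0
    ssq <- 0
    for (i in seq_len(n_el)) {
      rows <- el_rows[[i]]
      B <- V0[rows, , drop = FALSE] %*% t(rot_list[[i]])
      resid <- scale * rowSums((B %*% S) * B) - obs[rows]
      E <- E + sum(pmax(0, abs(resid) - widths[rows])^2)
      ssq <- ssq + sum(resid^2)
    }
    c(k * E, ssq)
  }
  energy_of <- function(rot_list, Rt) energy_of2(rot_list, Rt)[1]

  set.seed(config$seed)
  rot <- replicate(n_el, diag(3), simplify = FALSE)
  Rt <- diag(3)
  e_cur <- energy_of(rot, Rt)
  e_init <- e_cur
  best <- list(rot = rot, Rt = Rt, e = e_cur)

  n_dof <- n_el + as.integer(config$float_tensor)
  t0 <- config$t0
  if (is.null(t0)) {
    # calibrate so that a median uphill move is accepted with p ~ 0.5
    dE <- replicate(60, {
      i <- sample.int(n_dof, 1)
      if (i <= n_el) {
        r2 <- rot
        r2[[i]] <- rotation_about_axis(stats::rnorm(3),
                     stats::runif(1, -config$max_sse_rotation,
                                  config$max_sse_rotation)) %*% r2[[i]]
        energy_of(r2, Rt) - e_cur
      } else {
        R2 <- rotation_about_axis(stats::rnorm(3),
                stats::runif(1, -config$max_tensor_rotation,
                             config$max_tensor_rotation)) %*% Rt
        energy_of(rot, R2) - e_cur
      }
    })
    up <- dE[dE > 0]
    t0 <- if (length(up) == 0) 1e-6 else stats::median(up) / log(2)
    t0 <- max(t0, 1e-9)
  }

  temp <- t0
  trace <- numeric(config$n_temperatures)
  for (tstep in seq_len(config$n_temperatures)) {
    for (m in seq_len(config$steps_per_temp)) {
      i <- sample.int(n_dof, 1)
      if (i <= n_el) {
        prop_rot <- rot
        prop_rot[[i]] <- rotation_about_axis(stats::rnorm(3),
                           stats::runif(1, -config$max_sse_rotation,
                                        config$max_sse_rotation)) %*% prop_rot[[i]]
        prop_Rt <- Rt
      } else {
        prop_rot <- rot
        prop_Rt <- rotation_about_axis(stats::rnorm(3),
                     stats::runif(1, -config$max_tensor_rotation,
                                  config$max_tensor_rotation)) %*% Rt
      }
      e_new <- energy_of(prop_rot, prop_Rt)
      if (e_new <= e_cur || stats::runif(1) < exp(-(e_new - e_cur) / temp)) {
        rot <- prop_rot
        Rt <- prop_Rt
        e_cur <- e_new
        if (e_cur < best$e) best <- list(rot = rot, Rt = Rt, e = e_cur)
      }
    }
    trace[tstep] <- best$e
    temp <- temp * config$cooling
  }

  # greedy quench from the best state with shrinking move sizes
  rot <- best$rot
  Rt <- best$Rt
  e_cur <- best$e
  if (config$quench_steps > 0) {
    cur2 <- energy_of2(rot, Rt)
    shrink <- (0.01)^(1 / config$quench_steps)
    sc <- 1
    for (m in seq_len(config$quench_steps)) {
      sc <- sc * shrink
      i <- sample.int(n_dof, 1)
      if (i <= n_el) {
        prop_rot <- rot
        prop_rot[[i]] <- rotation_about_axis(stats::rnorm(3),
                           stats::runif(1, -1, 1) * sc * config$max_sse_rotation) %*%
                         prop_rot[[i]]
        prop_Rt <- Rt
      } else {
        prop_rot <- rot
        prop_Rt <- rotation_about_axis(stats::rnorm(3),
                     stats::runif(1, -1, 1) * sc * config$max_tensor_rotation) %*% Rt
      }
      new2 <- energy_of2(prop_rot, prop_Rt)
      if (new2[1] < cur2[1] || (new2[1] <= cur2[1] && new2[2] < cur2[2])) {
        rot <- prop_rot
        Rt <- prop_Rt
        cur2 <- new2
      }
    }
    best <- list(rot = rot, Rt = Rt, e = cur2[1])
  }
  rot <- best$rot
  Rt <- best$Rt

  # gauge anchoring: remove the net rotation of the reference element
  # (most restraints; ties -> first) from every element and fold it into
  # the tensor frame, which leaves all couplings unchanged
  if (config$float_tensor) {
    ref_el <- which.max(lengths(el_rows))
    g <- rot[[ref_el]]
    rot <- lapply(rot, function(Re) t(g) %*% Re)
    Rt <- t(g) %*% Rt
    best <- list(rot = rot, Rt = Rt, e = energy_of(rot, Rt))
  }

  # apply rotations about element C-alpha centroids
  refined <- template
  a <- refined$atoms
  ch <- if (is.null(chain)) a$chain[1] else chain
  for (i in seq_len(n_el)) {
    sel <- a$chain == ch & a$resno %in% el_res[[i]]
    ca <- a[sel & a$atom == "CA", c("x", "y", "z"), drop = FALSE]
    centroid <- colMeans(as.matrix(ca))
    xyz <- t(as.matrix(a[sel, c("x", "y", "z")]))
    xyz <- rot[[i]] %*% (xyz - centroid) + centroid
    a$x[sel] <- xyz[1, ]; a$y[sel] <- xyz[2, ]; a$z[sel] <- xyz[3, ]
  }
  refined$atoms <- a

  final_tensor <- alignment_tensor(Rt %*% S0 %*% t(Rt), scale = scale)
  vec_ref <- extract_nh_vectors(refined, ch)
  obs_named <- stats::setNames(ds$D, ds$resno)
  q_before <- q_factor(obs_named, back_calculate(fit0$tensor, vec_all))
  q_after <- q_factor(obs_named, back_calculate(final_tensor, vec_ref))

  rotations <- lapply(seq_len(n_el), function(i) {
    aa <- rotation_axis_angle(rot[[i]])
    list(label = sses$label[i], axis = aa$axis, angle = aa$angle,
         matrix = rot[[i]])
  })
  names(rotations) <- sses$label

  sse_set <- intersect(sse_residues(sses), template$atoms$resno[template$atoms$chain == ch])
  boundary <- unique(c(sses$start, sses$end))
  bnd_sel <- a$chain == ch & a$resno %in% boundary & a$atom %in% c("N", "C")
  tmp_a <- template$atoms
  shift <- sqrt((a$x[bnd_sel] - tmp_a$x[bnd_sel])^2 +
                (a$y[bnd_sel] - tmp_a$y[bnd_sel])^2 +
                (a$z[bnd_sel] - tmp_a$z[bnd_sel])^2)

  structure(list(structure = refined, rotations = rotations,
                 tensor = final_tensor,
                 tensor_euler = tensor_parameters(final_tensor)$euler,
                 energy_trace = trace, energy_initial = e_init,
                 energy_final = best$e,
                 q_before = q_before, q_after = q_after,
                 ca_rmsd_all = ca_rmsd(template, refined),
                 ca_rmsd_sse = ca_rmsd(template, refined, selection = sse_set),
                 junction_max_shift = if (length(shift)) max(shift) else 0,
                 config = config),
            class = "refine_result")
}

#' @export
print.refine_result <- function(x, ...) {
  cat(sprintf("refine_result: E %.3g -> %.3g, Q %.3f -> %.3f, Ca rmsd %.3f A (all) %.3f A (SSE)\n",
              x$energy_initial, x$energy_final, x$q_before, x$q_after,
              x$ca_rmsd_all, x$ca_rmsd_sse))
  for (r in x$rotations)
    cat(sprintf("  %s: %.2f deg about (%.3f %.3f %.3f)\n", r$label, r$angle,
                r$axis[1], r$axis[2], r$axis[3]))
  invisible(x)
}

#' C-alpha RMSD between two structures
#'
#' Root-mean-square deviation over C-alpha coordinates of the shared
#' residues. By default no superposition is performed (both structures
#' are assumed to share the template frame); with `superpose = TRUE` the
#' second structure is least-squares fitted onto the first before the
#' deviation is computed.
#'
#' @param a,b [rdc_structure()]s.
#' @param selection optional residue numbers to restrict to.
#' @param superpose least-squares superpose first (default FALSE).
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(a, b, selection = NULL, superpose = FALSE) {
  get_ca <- function(s) {
    ca <- s$atoms[s$atoms$atom == "CA", , drop = FALSE]
    if (!is.null(selection)) ca <- ca[ca$resno %in% selection, , drop = FALSE]
    ca[order(ca$chain, ca$resno), , drop = FALSE]
  }
  ca1 <- get_ca(a)
  ca2 <- get_ca(b)
  shared <- intersect(paste(ca1$chain, ca1$resno), paste(ca2$chain, ca2$resno))
  rdc_assert(length(shared) > 0, "no shared C-alpha atoms", "missing_ca")
  if (!is.null(selection))
    rdc_assert(all(selection %in% ca1$resno) && all(selection %in% ca2$resno),
               "C-alpha missing for some selected residues", "missing_ca")
  m1 <- as.matrix(ca1[match(shared, paste(ca1$chain, ca1$resno)), c("x", "y", "z")])
  m2 <- as.matrix(ca2[match(shared, paste(ca2$chain, ca2$resno)), c("x", "y", "z")])
  if (superpose) {
    c1 <- colMeans(m1); c2 <- colMeans(m2)
    H <- t(sweep(m2, 2, c2)) %*% sweep(m1, 2, c1)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    m2 <- t(R %*% t(sweep(m2, 2, c2))) + matrix(c1, nrow(m2), 3, byrow = TRUE)
  }
  sqrt(mean(rowSums((m1 - m2)^2)))
}
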