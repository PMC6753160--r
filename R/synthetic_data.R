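# Synthetic-data generator: toy structures with known N-H geometry,
# simulated RDC datasets, and simulated peak-list pairs, all with known
# ground truth so that every downstream operation can be tested by
# parameter recovery.
#
# The generator emulates the data regime of weak phage alignment of a
# protein domain: couplings up to a few tens of Hz, RMS coupling
# uncertainties near 1.8 Hz, and 15N TROSY linewidths of 11 +/- 2 Hz.

#' Specification for a synthetic fixture
#'
#' @param kind structure kind: "ideal_helix", "two_helix" or "strand".
#' @param n_residues residues per element (>= 5 so a tensor fit on one
#'   element is solvable).
#' @param tensor ground-truth `alignment_tensor` (default: Da = 10 Hz,
#'   R = 0.3, rotated by zyz Euler angles 20/30/40 degrees).
#' @param noise RDC noise s.d. in Hz (default 1.8, a realistic RMS
#'   coupling uncertainty for ribosome-scale data).
#' @param j_nh one-bond N-H scalar coupling in Hz (default -93).
#' @param sn signal-to-noise model: a single value or per-residue vector
#'   (default 30).
#' @param lw_mean,lw_sd 15N linewidth model in Hz (default 11 +/- 2,
#'   truncated positive).
#' @param peak_noise s.d. of peak-position noise in Hz (default 0).
#' @param seed RNG seed for all stochastic draws.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(kind = c("ideal_helix", "two_helix", "strand"),
                         n_residues = 12,
                         tensor = tensor_from_parameters(10, 0.3, c(20, 30, 40)),
                         noise = 1.8, j_nh = -93, sn = 30,
                         lw_mean = 11, lw_sd = 2, peak_noise = 0, seed = 1L) {
  kind <- match.arg(kind)
  rdc_assert(n_residues >= 5, "need >= 5 residues per element")
  rdc_assert(noise >= 0 && lw_mean > 0 && lw_sd >= 0 && all(sn > 0),
             "noise/linewidth/SN parameters out of range")
  structure(list(kind = kind, n_residues = n_residues, tensor = tensor,
                 noise = noise, j_nh = j_nh, sn = sn, lw_mean = lw_mean,
                 lw_sd = lw_sd, peak_noise = peak_noise, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Place atom D bonded to C given positions of A, B, C, the C-D bond
# length, the B-C-D angle and the A-B-C-D dihedral (degrees). Standard
# internal-coordinate (NeRF) construction.
place_atom <- function(A, B, C, bond, angle, dihedral) {
  th <- deg2rad(angle)
  ph <- deg2rad(dihedral)
  d <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  M <- cbind(bc, m, n)
  as.vector(M %*% d + C)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Backbone geometry constants (Engh-Huber-like ideal values, Angstrom/deg)
.bb <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_n_h = 1.02,
            b_c_o = 1.231,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
            a_c_n_h = 119.5, a_ca_c_o = 120.5)

# Build one chain segment with fixed (phi, psi); residues numbered
# first_resno..(first_resno + n - 1). Atoms: N, H (from residue 2 of the
# segment), CA, C, O. Returns an atom data.frame.
build_segment <- function(n, phi, psi, first_resno = 1L, chain = "A") {
  g <- .bb
  atoms <- list()
  add <- function(resno, name, xyz) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      chain = chain, resno = resno, resname = "ALA", atom = name,
      x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, stringsAsFactors = FALSE)
  }
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  thc <- deg2rad(180 - g$a_n_ca_c)
  C <- CA + g$b_ca_c * c(cos(thc), sin(thc), 0)
  add(first_resno, "N", N); add(first_resno, "CA", CA); add(first_resno, "C", C)
  add(first_resno, "O", place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o, psi + 180))
  prevN <- N; prevCA <- CA; prevC <- C
  for (i in seq_len(n - 1)) {
    resno <- first_resno + i
    Nn <- place_atom(prevN, prevCA, prevC, g$b_c_n, g$a_ca_c_n, psi)
    CAn <- place_atom(prevCA, prevC, Nn, g$b_n_ca, g$a_c_n_ca, 180)  # omega
    H <- place_atom(prevCA, prevC, Nn, g$b_n_h, g$a_c_n_h, 0)        # trans to CA(i)
    Cn <- place_atom(prevC, Nn, CAn, g$b_ca_c, g$a_n_ca_c, phi)
    O <- place_atom(Nn, CAn, Cn, g$b_c_o, g$a_ca_c_o, psi + 180)
    add(resno, "N", Nn); add(resno, "H", H); add(resno, "CA", CAn)
    add(resno, "C", Cn); add(resno, "O", O)
    prevN <- Nn; prevCA <- CAn; prevC <- Cn
  }
  do.call(rbind, atoms)
}

#' Build a synthetic structure with known geometry
#'
#' Constructs an ideal alpha-helix (backbone dihedrals phi = -57,
#' psi = -47 degrees, standard bond geometry, amide protons placed in the
#' peptide plane trans to the following C-alpha), an ideal strand
#' (phi = -135, psi = 135), or a two-helix fixture (two ideal helices
#' separated by a 3-residue numbering gap, the second rotated and
#' translated away from the first). The N-terminal residue of each
#' segment carries no amide proton. Deterministic: the same spec always
#' yields the same coordinates.
#'
#' For "two_helix" the matching secondary-structure definition is
#' attached as attribute `"sse"` (and for single elements as a one-row
#' definition).
#'
#' @param spec a [fixture_spec()].
#' @return an [rdc_structure()] with attribute `sse`.
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_residues
  if (spec$kind == "ideal_helix") {
    atoms <- build_segment(n, -57, -47)
    sse <- sse_definition("H1", "helix", 1L, n)
  } else if (spec$kind == "strand") {
    atoms <- build_segment(n, -135, 135)
    sse <- sse_definition("S1", "strand", 1L, n)
  } else {
    a1 <- build_segment(n, -57, -47, first_resno = 1L)
    a2 <- build_segment(n, -57, -47, first_resno = n + 4L)
    R <- rotation_about_axis(c(1, 1, 0), 75)
    xyz <- t(R %*% t(as.matrix(a2[, c("x", "y", "z")])))
    a2$x <- xyz[, 1] + 15
    a2$y <- xyz[, 2] + 10
    a2$z <- xyz[, 3]
    atoms <- rbind(a1, a2)
    sse <- sse_definition(c("H1", "H2"), c("helix", "helix"),
                          c(1L, n + 4L), c(n, 2L * n + 3L))
  }
  out <- rdc_structure(atoms)
  attr(out, "sse") <- sse
  out
}

#' Simulate an RDC dataset from a structure and a known tensor
#'
#' Back-calculates couplings for every extractable N-H vector and adds
#' independent Gaussian noise. `sigma_D` is set to the noise s.d. (floor
#' 0.1 Hz for noiseless data, so downstream weighting stays defined).
#'
#' @param structure an [rdc_structure()].
#' @param tensor generating `alignment_tensor`.
#' @param noise Gaussian noise s.d. in Hz.
#' @param seed RNG seed (deterministic output for a given seed).
#' @param chain chain to use.
#' @return an [rdc_dataset()].
#' @export
simulate_rdcs <- function(structure, tensor, noise = 0, seed = 1L, chain = NULL) {
  vec <- extract_nh_vectors(structure, chain)
  D0 <- back_calculate(tensor, vec)
  set.seed(as.integer(seed))
  D <- D0 + stats::rnorm(length(D0), 0, noise)
  rdc_dataset(data.frame(resno = residues_of(vec), D = as.numeric(D),
                         sigma_D = max(noise, 0.1),
                         stringsAsFactors = FALSE))
}

#' Simulate isotropic/anisotropic peak-list pairs
#'
#' Generates the four peak lists from which the measurement module
#' recovers couplings. Multiplet centres are placed deterministically per
#' residue; under the simulated convention the TROSY component is
#' displaced by `+(J+D)/2` from the decoupled (HSQC) position, with D = 0
#' in the isotropic condition and the back-calculated coupling in the
#' anisotropic one. For "ipap" the two components sit at
#' `centre -/+ (J+D)/2` (upfield/downfield labels follow the sign of the
#' displacement so that the round trip returns D with its sign). SN is
#' taken from the spec; LW is drawn from N(lw_mean, lw_sd) truncated
#' positive; optional Gaussian position noise of s.d. `peak_noise` is
#' added to every peak.
#'
#' @param structure an [rdc_structure()].
#' @param tensor generating `alignment_tensor`.
#' @param spec a [fixture_spec()] (uses `j_nh`, `sn`, `lw_mean`, `lw_sd`,
#'   `peak_noise`, `seed`).
#' @param method "hsqc_trosy" or "ipap".
#' @param chain chain to use.
#' @return named list of four peak data.frames: for "hsqc_trosy"
#'   `hsqc_iso`, `trosy_iso`, `hsqc_aniso`, `trosy_aniso`; for "ipap"
#'   `up_iso`, `down_iso`, `up_aniso`, `down_aniso`. The generating
#'   couplings are attached as attribute `truth`.
#' @export
simulate_peak_lists <- function(structure, tensor, spec,
                                method = c("hsqc_trosy", "ipap"), chain = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  method <- match.arg(method)
  vec <- extract_nh_vectors(structure, chain)
  D <- back_calculate(tensor, vec)
  res <- residues_of(vec)
  nres <- length(res)
  J <- spec$j_nh
  set.seed(spec$seed)
  centre <- 6000 + 25 * seq_len(nres)   # arbitrary resolved 15N positions (Hz)
  sn <- rep(spec$sn, length.out = nres)
  draw_lw <- function() {
    lw <- stats::rnorm(nres, spec$lw_mean, spec$lw_sd)
    pmax(lw, 0.5)
  }
  jitter <- function(x) x + stats::rnorm(length(x), 0, spec$peak_noise)
  mk <- function(nu) data.frame(resno = res, nu15N = jitter(nu), SN = sn,
                                LW = draw_lw(), overlapped = FALSE,
                                stringsAsFactors = FALSE)
  out <- if (method == "hsqc_trosy") {
    list(hsqc_iso = mk(centre),
         trosy_iso = mk(centre + J / 2),
         hsqc_aniso = mk(centre),
         trosy_aniso = mk(centre + (J + D) / 2))
  } else {
    list(up_iso = mk(centre - J / 2),
         down_iso = mk(centre + J / 2),
         up_aniso = mk(centre - (J + D) / 2),
         down_aniso = mk(centre + (J + D) / 2))
  }
  attr(out, "truth") <- stats::setNames(as.numeric(D), res)
  out
}

#' Write a complete simulated fixture to disk
#'
#' Emits the PDB file, SSE config, RDC table and the four peak lists for a
#' fixture, providing file-level inputs for the whole pipeline.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @param method peak-list method, see [simulate_peak_lists()].
#' @return named list of written paths, invisibly.
#' @export
write_fixture <- function(spec, dir, method = "hsqc_trosy") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- make_structure(spec)
  paths <- list(pdb = file.path(dir, "structure.pdb"),
                sse = file.path(dir, "sse.cfg"),
                rdc = file.path(dir, "rdcs.tsv"))
  write_structure(st, paths$pdb)
  write_sse(attr(st, "sse"), paths$sse)
  ds <- simulate_rdcs(st, spec$tensor, noise = spec$noise, seed = spec$seed)
  write_rdc_table(ds, paths$rdc, comment = "simulated dataset")
  pl <- simulate_peak_lists(st, spec$tensor, spec, method = method)
  for (nm in names(pl)) {
    p <- file.path(dir, paste0("peaks_", nm, ".txt"))
    write_peak_list(pl[[nm]], p, comment = paste("simulated", nm))
    paths[[nm]] <- p
  }
  invisible(paths)
}
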