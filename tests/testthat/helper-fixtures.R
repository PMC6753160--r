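# Shared fixtures built in code: a reference tensor in the realistic
# weak-alignment regime and helpers to build perturbed two-helix systems.

ref_tensor <- function(Da = 10, R = 0.3, euler = c(20, 30, 40)) {
  tensor_from_parameters(Da, R, euler)
}

# Two-helix fixture with the second element rigidly rotated by `angle`
# degrees about `axis` through its own C-alpha centroid.
rotated_two_helix <- function(angle = 10, axis = c(0, 0, 1), n_residues = 12) {
  spec <- fixture_spec("two_helix", n_residues = n_residues)
  st <- make_structure(spec)
  sse <- attr(st, "sse")
  a <- st$atoms
  sel <- a$resno >= sse$start[2] & a$resno <= sse$end[2]
  cen <- colMeans(as.matrix(a[sel & a$atom == "CA", c("x", "y", "z")]))
  R <- rotation_about_axis(axis, angle)
  xyz <- t(R %*% (t(as.matrix(a[sel, c("x", "y", "z")])) - cen) + cen)
  a$x[sel] <- xyz[, 1]; a$y[sel] <- xyz[, 2]; a$z[sel] <- xyz[, 3]
  rot <- rdc_structure(a)
  attr(rot, "sse") <- sse
  list(template = st, rotated = rot, sse = sse)
}

# Random unit vectors with residue rownames (generic bond geometry).
random_vectors <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m <- m / sqrt(rowSums(m^2))
  rownames(m) <- seq_len(n)
  bond_vectors(m)
}

# Minimal PDB writer for hand-built records (fixture files in tests).
write_mini_pdb <- function(path, lines) writeLines(lines, path)

residues_of_test <- function(v) as.integer(rownames(v))

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", insert = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resname, chain, resno, insert, x, y, z, occ, 0)
}
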