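# Coordinate input/output and amide bond-vector extraction.
#
# A `rdc_structure` is a light container around an atom table (one row per
# atom) for a single selected model; PDB parsing and writing are delegated
# to bio3d. Coordinates are in Angstrom, residue numbering is taken
# verbatim from the file (author numbering).

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer),
#'   `resname`, `atom` (atom name, e.g. "N", "H", "CA"), `x`, `y`, `z`
#'   (Angstrom) and optionally `occ` (occupancy, default 1).
#' @param model model number the atoms came from (default 1).
#' @return an object of class `rdc_structure`.
#' @export
rdc_structure <- function(atoms, model = 1L) {
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  rdc_assert(is.data.frame(atoms) && all(need %in% names(atoms)),
             paste("atoms must have columns", paste(need, collapse = ", ")))
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms$resno <- as.integer(atoms$resno)
  rdc_assert(all(is.finite(atoms$x)) && all(is.finite(atoms$y)) &&
             all(is.finite(atoms$z)), "coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  rdc_assert(!anyDuplicated(key),
             "duplicate (chain, residue, atom) entries in atom table")
  structure(list(atoms = atoms[order(atoms$chain, atoms$resno), , drop = FALSE],
                 model = as.integer(model)),
            class = "rdc_structure")
}

#' @export
print.rdc_structure <- function(x, ...) {
  cat(sprintf("rdc_structure: %d atoms, %d residues, chains %s (model %d)\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ","), x$model))
  invisible(x)
}

#' Load a structure from a PDB file
#'
#' Reads ATOM records of one model of a PDB file. Alternate locations are
#' resolved by keeping the highest-occupancy conformer (ties broken in
#' favour of altloc "A"); files containing insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @param model model number to select (1-based; default 1).
#' @param keep_hetatm also keep HETATM records (default FALSE).
#' @return an [rdc_structure()].
#' @export
load_structure <- function(path, model = 1L, keep_hetatm = FALSE) {
  if (!file.exists(path)) rdc_abort(paste("PDB file not found:", path), "missing_file")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) rdc_abort(paste("malformed PDB file:", conditionMessage(e)),
                                  "malformed_pdb"))
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) rdc_abort("no ATOM records in file", "malformed_pdb")
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    rdc_abort("insertion codes are not supported", "insertion_codes")

  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  model <- as.integer(model)
  if (model < 1L || model > n_models)
    rdc_abort(sprintf("model %d not present (file has %d model(s))", model, n_models),
              "absent_model")
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  idx <- which(pdb$atom$type == "ATOM" | keep_hetatm)
  co <- matrix(xyz, ncol = 3, byrow = TRUE)[idx, , drop = FALSE]

  atoms <- data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
                      atom = at$elety, x = co[, 1], y = co[, 2], z = co[, 3],
                      occ = ifelse(is.na(at$o), 1, at$o),
                      alt = ifelse(is.na(at$alt), "", at$alt),
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "

  # altloc resolution: highest occupancy, tie -> 'A' (blank altloc sorts first)
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occ, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$atom)), , drop = FALSE]
  }
  atoms$alt <- NULL
  rdc_structure(atoms, model = model)
}

#' Write a structure to a PDB file
#'
#' Emits standard ATOM records via bio3d. Coordinates are written with the
#' PDB's 3-decimal precision.
#'
#' @param structure an [rdc_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "rdc_structure"))
  a <- structure$atoms
  suppressWarnings(bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resname, chain = a$chain,
    elety = a$atom, o = a$occ, b = rep(0, nrow(a))))
  invisible(path)
}

#' Extract amide N-H bond vectors
#'
#' Computes the unit internuclear vector (H - N)/|H - N| for every residue
#' of the requested chain that has both a backbone nitrogen and an amide
#' proton (atom name "H" or "HN"). Prolines are never included. Residues
#' missing either atom are omitted and listed in the `missing` attribute.
#'
#' @param structure an [rdc_structure()].
#' @param chain chain identifier (default: first chain present).
#' @return a `bond_vectors` object: an n x 3 matrix of unit vectors with
#'   residue numbers as rownames; attributes `missing` (residues skipped)
#'   and `chain`.
#' @export
extract_nh_vectors <- function(structure, chain = NULL) {
  stopifnot(inherits(structure, "rdc_structure"))
  a <- structure$atoms
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain, , drop = FALSE]
  rdc_assert(nrow(a) > 0, paste("no atoms in chain", chain))

  resnos <- sort(unique(a$resno))
  vec <- matrix(NA_real_, length(resnos), 3)
  keep <- logical(length(resnos))
  missing <- integer(0)
  for (i in seq_along(resnos)) {
    ri <- a[a$resno == resnos[i], , drop = FALSE]
    if (toupper(ri$resname[1]) == "PRO") next
    nN <- which(ri$atom == "N")
    nH <- which(ri$atom %in% c("H", "HN"))  # first match wins
    if (length(nN) == 0 || length(nH) == 0) {
      missing <- c(missing, resnos[i])
      next
    }
    d <- as.numeric(ri[nH[1], c("x", "y", "z")]) - as.numeric(ri[nN[1], c("x", "y", "z")])
    nd <- sqrt(sum(d^2))
    if (nd < 1e-6) {
      missing <- c(missing, resnos[i])
      next
    }
    vec[i, ] <- d / nd
    keep[i] <- TRUE
  }
  if (!any(keep)) rdc_abort("no extractable N-H vectors in chain", "no_vectors")
  out <- vec[keep, , drop = FALSE]
  rownames(out) <- resnos[keep]
  bond_vectors(out, chain = chain, missing = missing)
}

#' Construct a bond-vector set
#'
#' @param vectors n x 3 numeric matrix of (near-)unit vectors with residue
#'   numbers as rownames; rows are re-normalised to exactly unit length.
#' @param chain chain the vectors belong to.
#' @param missing residues that could not provide a vector.
#' @param source atom pair, default "N-H".
#' @return a `bond_vectors` object.
#' @export
bond_vectors <- function(vectors, chain = "A", missing = integer(0), source = "N-H") {
  rdc_assert(is.matrix(vectors) && ncol(vectors) == 3 && nrow(vectors) >= 1,
             "vectors must be an n x 3 matrix")
  rdc_assert(!is.null(rownames(vectors)), "vectors must have residue-number rownames")
  nrm <- sqrt(rowSums(vectors^2))
  rdc_assert(all(nrm > 0), "zero-length bond vector")
  vectors <- vectors / nrm
  structure(vectors, class = c("bond_vectors", "matrix"),
            chain = chain, missing = missing, source = source)
}

#' @export
print.bond_vectors <- function(x, ...) {
  cat(sprintf("bond_vectors: %d %s vectors, chain %s (%d residue(s) missing)\n",
              nrow(x), attr(x, "source"), attr(x, "chain"),
              length(attr(x, "missing"))))
  invisible(x)
}

residues_of <- function(vectors) as.integer(rownames(vectors))

#' Define secondary-structure elements
#'
#' @param label character vector of element labels.
#' @param kind element kinds, "helix" or "strand".
#' @param start,end first and last residue of each element (inclusive).
#' @return an `sse_definition` data.frame.
#' @export
sse_definition <- function(label, kind, start, end) {
  kind <- match.arg(kind, c("helix", "strand"), several.ok = TRUE)
  df <- data.frame(label = as.character(label), kind = kind,
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  rdc_assert(all(df$start <= df$end), "element start must be <= end")
  if (nrow(df) > 1) {
    o <- order(df$start)
    rdc_assert(all(df$end[o][-nrow(df)] < df$start[o][-1]),
               "secondary-structure elements must not overlap")
  }
  class(df) <- c("sse_definition", "data.frame")
  df
}

#' Read secondary-structure elements from a config file
#'
#' Plain-text format: one element per line, `label kind start end`
#' (whitespace-separated); `#` starts a comment.
#'
#' @param path config file path.
#' @return an [sse_definition()].
#' @export
read_sse <- function(path) {
  if (!file.exists(path)) rdc_abort(paste("SSE config not found:", path), "missing_file")
  ln <- readLines(path)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  rdc_assert(length(ln) > 0, "SSE config contains no elements")
  parts <- strsplit(ln, "[[:space:]]+")
  rdc_assert(all(lengths(parts) == 4), "each SSE line must be: label kind start end")
  m <- do.call(rbind, parts)
  sse_definition(m[, 1], m[, 2], as.integer(m[, 3]), as.integer(m[, 4]))
}

#' Write secondary-structure elements to a config file
#'
#' @param sses an [sse_definition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sse <- function(sses, path) {
  writeLines(sprintf("%s %s %d %d", sses$label, sses$kind, sses$start, sses$end), path)
  invisible(path)
}

sse_residues <- function(sses) {
  unlist(lapply(seq_len(nrow(sses)), function(i) sses$start[i]:sses$end[i]))
}

#' Restrict bond vectors to secondary-structure elements
#'
#' Keeps only vectors whose residue lies inside any element (endpoints
#' inclusive).
#'
#' @param vectors a `bond_vectors` object.
#' @param sses an [sse_definition()].
#' @return a `bond_vectors` object restricted to element residues.
#' @export
select_sse_vectors <- function(vectors, sses) {
  rdc_assert(inherits(sses, "sse_definition") && nrow(sses) > 0,
             "empty secondary-structure definition", "empty_selection")
  keep <- residues_of(vectors) %in% sse_residues(sses)
  if (!any(keep)) rdc_abort("no bond vectors inside the given elements", "empty_selection")
  bond_vectors(unclass(vectors)[keep, , drop = FALSE],
               chain = attr(vectors, "chain"),
               missing = attr(vectors, "missing"),
               source = attr(vectors, "source"))
}
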