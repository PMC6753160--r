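test_that("load_structure reads ATOM records and selects models", {
  f <- tempfile(fileext = ".pdb")
  lines <- c("MODEL     1",
             unlist(lapply(1:3, function(r) c(
               pdb_atom_line(4 * r - 3, "N", "ALA", "A", r, r, 0, 0),
               pdb_atom_line(4 * r - 2, "H", "ALA", "A", r, r, 0, 1.02),
               pdb_atom_line(4 * r - 1, "CA", "ALA", "A", r, r + 1, 0, 0),
               pdb_atom_line(4 * r, "C", "ALA", "A", r, r + 1, 1, 0)))),
             "ENDMDL",
             "MODEL     2",
             unlist(lapply(1:3, function(r) c(
               pdb_atom_line(4 * r - 3, "N", "ALA", "A", r, r + 10, 0, 0),
               pdb_atom_line(4 * r - 2, "H", "ALA", "A", r, r + 10, 0, 1.02),
               pdb_atom_line(4 * r - 1, "CA", "ALA", "A", r, r + 11, 0, 0),
               pdb_atom_line(4 * r, "C", "ALA", "A", r, r + 11, 1, 0)))),
             "ENDMDL", "END")
  write_mini_pdb(f, lines)

  st1 <- load_structure(f, model = 1)
  expect_equal(nrow(st1$atoms), 12)
  st2 <- load_structure(f, model = 2)
  expect_equal(nrow(st2$atoms), 12)
  expect_equal(st2$atoms$x[st2$atoms$atom == "N" & st2$atoms$resno == 1], 11)
  expect_error(load_structure(f, model = 3), class = "rdcalign_absent_model")
  expect_error(load_structure("no/such/file.pdb"), class = "rdcalign_missing_file")
})

test_that("insertion codes are rejected and altlocs resolved by occupancy", {
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(f, c(pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
                      pdb_atom_line(2, "CA", "ALA", "A", 1, 1, 0, 0, insert = "A"),
                      "END"))
  expect_error(load_structure(f), class = "rdcalign_insertion_codes")

  f2 <- tempfile(fileext = ".pdb")
  write_mini_pdb(f2, c(pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
                       pdb_atom_line(2, "N", "ALA", "A", 1, 5, 0, 0, occ = 0.6, alt = "B"),
                       pdb_atom_line(3, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.5, alt = "A"),
                       pdb_atom_line(4, "CA", "ALA", "A", 1, 6, 0, 0, occ = 0.5, alt = "B"),
                       "END"))
  st <- load_structure(f2)
  expect_equal(nrow(st$atoms), 2)
  expect_equal(st$atoms$x[st$atoms$atom == "N"], 5)   # higher occupancy wins
  expect_equal(st$atoms$x[st$atoms$atom == "CA"], 1)  # tie -> altloc A
})

test_that("PDB write/reload round trip preserves coordinates to 3 decimals", {
  st <- make_structure(fixture_spec("ideal_helix", n_residues = 8))
  f <- tempfile(fileext = ".pdb")
  write_structure(st, f)
  st2 <- load_structure(f)
  key <- function(s) order(s$atoms$resno, s$atoms$atom)
  m1 <- as.matrix(st$atoms[key(st), c("x", "y", "z")])
  m2 <- as.matrix(st2$atoms[key(st2), c("x", "y", "z")])
  expect_lt(max(abs(m1 - m2)), 5e-4 + 1e-12)
})

test_that("extract_nh_vectors normalises, omits incomplete residues and prolines", {
  atoms <- data.frame(
    chain = "A",
    resno = c(1, 1, 2, 2, 3, 3),
    resname = c("ALA", "ALA", "GLY", "GLY", "PRO", "PRO"),
    atom = c("N", "H", "N", "CA", "N", "H"),
    x = c(0, 0, 0, 1, 0, 0), y = c(0, 0, 2, 2, 4, 4), z = c(0, 1.02, 0, 0, 0, 1),
    stringsAsFactors = FALSE)
  st <- rdc_structure(atoms)
  v <- extract_nh_vectors(st, "A")
  expect_equal(rownames(v), "1")
  expect_equal(as.numeric(v[1, ]), c(0, 0, 1))
  expect_equal(attr(v, "missing"), 2L)  # residue 2 lacks H; proline never listed

  # HN dialect accepted
  atoms$atom[2] <- "HN"
  v2 <- extract_nh_vectors(rdc_structure(atoms), "A")
  expect_equal(as.numeric(v2[1, ]), c(0, 0, 1))

  # structures with no extractable vectors error
  atoms3 <- atoms[atoms$atom == "N", , drop = FALSE]
  expect_error(extract_nh_vectors(rdc_structure(atoms3), "A"),
               class = "rdcalign_no_vectors")
})

test_that("bond vectors from arbitrary coordinates are unit norm", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    atoms <- do.call(rbind, lapply(seq_len(n), function(r) {
      N <- stats::rnorm(3, sd = 5)
      H <- N + stats::rnorm(3, sd = 0.6)
      data.frame(chain = "A", resno = r, resname = "ALA",
                 atom = c("N", "H"), x = c(N[1], H[1]), y = c(N[2], H[2]),
                 z = c(N[3], H[3]), stringsAsFactors = FALSE)
    }))
    v <- extract_nh_vectors(rdc_structure(atoms), "A")
    expect_lt(max(abs(sqrt(rowSums(unclass(v)^2)) - 1)), 1e-9)
  }
})

test_that("SSE selection intersects residue ranges and errors when empty", {
  v <- random_vectors(20, seed = 1)
  s1 <- sse_definition("H1", "helix", 5, 10)
  out <- select_sse_vectors(v, s1)
  expect_equal(residues_of_test(out), 5:10)

  s2 <- sse_definition(c("H1", "S1"), c("helix", "strand"), c(1, 6), c(5, 9))
  out2 <- select_sse_vectors(v, s2)
  expect_equal(residues_of_test(out2), 1:9)

  s3 <- sse_definition("H9", "helix", 100, 110)
  expect_error(select_sse_vectors(v, s3), class = "rdcalign_empty_selection")
  expect_error(sse_definition(c("A", "B"), c("helix", "helix"), c(1, 4), c(5, 9)))
})

test_that("SSE config files round trip", {
  s <- sse_definition(c("H1", "S1"), c("helix", "strand"), c(2, 11), c(9, 15))
  f <- tempfile(fileext = ".cfg")
  write_sse(s, f)
  s2 <- read_sse(f)
  expect_equal(as.data.frame(s), as.data.frame(s2))
})
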