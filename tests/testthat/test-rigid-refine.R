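test_that("soft square-well energy: flat well, hand value, smooth edge", {
  obs <- rdc_dataset(data.frame(resno = 1:3, D = c(5, -3, 8), sigma_D = 1))
  w <- c("1" = 1, "2" = 1, "3" = 1)
  inside <- c("1" = 5.5, "2" = -3.9, "3" = 8)
  expect_equal(restraint_energy(obs, inside, w), 0)

  one <- rdc_dataset(data.frame(resno = 1, D = 0, sigma_D = 1))
  expect_equal(restraint_energy(one, c("1" = 3), c("1" = 1), k = 1), 4)
  expect_equal(restraint_energy(one, c("1" = 3), c("1" = 1), k = 2.5), 10)

  # continuous value and first derivative at the well edge
  E <- function(d) restraint_energy(one, c("1" = d), c("1" = 1))
  h <- 1e-6
  expect_lt(abs(E(1 + h) - E(1 - h)), 1e-10)
  dE_left <- (E(1) - E(1 - h)) / h
  dE_right <- (E(1 + h) - E(1)) / h
  expect_lt(abs(dE_left), 1e-5)
  expect_lt(abs(dE_right), 1e-5)
  # quadratic growth outside
  expect_equal(E(2), 1, tolerance = 1e-12)
})

test_that("refinement of self-consistent data leaves the template in place", {
  fx <- rotated_two_helix(angle = 0)
  t1 <- ref_tensor()
  ds <- simulate_rdcs(fx$template, t1, noise = 0, seed = 1)
  res <- refine_orientations(fx$template, fx$sse, ds,
                             refine_config(Da = 10, rhombicity = 0.3, seed = 1))
  for (r in res$rotations) expect_lt(r$angle, 0.5)
  expect_lt(res$ca_rmsd_all, 0.05)
})

test_that("a 10-degree helix rotation is recovered from noiseless data", {
  fx <- rotated_two_helix(angle = 10, axis = c(0, 0, 1))
  t1 <- ref_tensor()
  ds <- simulate_rdcs(fx$rotated, t1, noise = 0, seed = 1)
  cfg <- refine_config(Da = 10, rhombicity = 0.3, seed = 3,
                       max_sse_rotation = 3, max_tensor_rotation = 3)
  res <- refine_orientations(fx$template, fx$sse, ds, cfg)
  expect_lt(abs(res$rotations$H2$angle - 10), 2)
  expect_lt(res$rotations$H1$angle, 1)  # reference element anchors the gauge
  expect_lt(res$q_after, 0.05)
  expect_lt(res$q_after, res$q_before)
  # best-so-far energy trace is non-increasing
  expect_true(all(diff(res$energy_trace) <= 1e-12))
  expect_lte(res$energy_final, res$energy_initial)
})

test_that("refinement is deterministic and rigid within elements", {
  fx <- rotated_two_helix(angle = 10)
  ds <- simulate_rdcs(fx$rotated, ref_tensor(), noise = 0, seed = 1)
  cfg <- refine_config(Da = 10, rhombicity = 0.3, seed = 5,
                       steps_per_temp = 60, n_temperatures = 15, quench_steps = 500)
  r1 <- refine_orientations(fx$template, fx$sse, ds, cfg)
  r2 <- refine_orientations(fx$template, fx$sse, ds, cfg)
  expect_identical(r1$structure$atoms, r2$structure$atoms)
  expect_identical(r1$energy_trace, r2$energy_trace)

  # intra-element distances preserved (proper, centroid-anchored rotations)
  for (i in seq_len(nrow(fx$sse))) {
    rr <- fx$sse$start[i]:fx$sse$end[i]
    sel <- function(s) as.matrix(
      s$atoms[s$atoms$resno %in% rr, c("x", "y", "z")])
    d0 <- stats::dist(sel(fx$template))
    d1 <- stats::dist(sel(r1$structure))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("restraints outside elements and tiny elements are rejected", {
  fx <- rotated_two_helix(angle = 0)
  ds <- simulate_rdcs(fx$template, ref_tensor(), noise = 0, seed = 1)
  sse_short <- sse_definition("H1", "helix", fx$sse$start[1], fx$sse$end[1])
  expect_error(refine_orientations(fx$template, sse_short, ds, refine_config(seed = 1)),
               class = "rdcalign_restraint_outside_element")

  # restrict data to one element, then shrink the element below 3 vectors
  ds1 <- rdc_dataset(as.data.frame(ds)[as.data.frame(ds)$resno %in% 2:3, ])
  tiny <- sse_definition("H1", "helix", 2, 3)
  expect_error(refine_orientations(fx$template, tiny, ds1, refine_config(seed = 1)),
               class = "rdcalign_degenerate_element")
})

test_that("with zero restraints the template is returned unchanged", {
  fx <- rotated_two_helix(angle = 0)
  ds <- simulate_rdcs(fx$template, ref_tensor(), noise = 0, seed = 1)
  ds$excluded <- TRUE
  ds$reason <- "overlap"
  res <- refine_orientations(fx$template, fx$sse, rdc_dataset(as.data.frame(ds)),
                             refine_config(seed = 1))
  expect_identical(res$structure$atoms, fx$template$atoms)
  expect_equal(res$ca_rmsd_all, 0)
})

test_that("C-alpha RMSD handles translation and superposition", {
  st <- make_structure(fixture_spec("ideal_helix", n_residues = 8))
  expect_equal(ca_rmsd(st, st), 0)
  moved <- st
  moved$atoms$x <- moved$atoms$x + 1
  expect_equal(ca_rmsd(st, moved), 1, tolerance = 1e-12)
  expect_equal(ca_rmsd(st, moved, superpose = TRUE), 0, tolerance = 1e-9)
  expect_error(ca_rmsd(st, moved, selection = 999), class = "rdcalign_missing_ca")
})
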