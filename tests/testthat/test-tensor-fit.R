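test_that("back-calculation matches the principal-frame closed form", {
  zero <- alignment_tensor(matrix(0, 3, 3))
  v <- bond_vectors(rbind("1" = c(0, 0, 1), "2" = c(1, 0, 0),
                          "3" = c(0, 1, 0)))
  expect_equal(unname(back_calculate(zero, v)), c(0, 0, 0))

  ax <- tensor_from_parameters(10, 0)   # axially symmetric, principal z = lab z
  D <- back_calculate(ax, v)
  expect_equal(unname(D[["1"]]), 20, tolerance = 1e-12)  # theta = 0 -> 2 Da
  expect_equal(unname(D[["2"]]), -10, tolerance = 1e-12) # theta = 90 -> -Da
  expect_equal(unname(D[["3"]]), -10, tolerance = 1e-12)
})

test_that("SVD fit recovers a generating tensor exactly from noiseless data", {
  t1 <- ref_tensor()
  st <- make_structure(fixture_spec("two_helix", n_residues = 12))
  v <- extract_nh_vectors(st)
  ds <- simulate_rdcs(st, t1, noise = 0, seed = 1)
  fit <- svd_fit(ds, v)
  expect_lt(max(abs(fit$tensor$saupe - t1$saupe)), 1e-10)
  expect_lt(fit$Q, 1e-10)
  expect_equal(fit$parameters$Da, 10, tolerance = 1e-9)
  expect_equal(fit$parameters$rhombicity, 0.3, tolerance = 1e-9)
})

test_that("SVD fit is unbiased under Gaussian noise", {
  t1 <- ref_tensor()
  v <- random_vectors(50, seed = 3)
  da <- replicate(100, NA_real_)
  set.seed(99)
  seeds <- sample.int(1e6, 100)
  for (i in 1:100) {
    ds <- rdc_dataset(data.frame(resno = 1:50,
                                 D = {set.seed(seeds[i])
                                      back_calculate(t1, v) + stats::rnorm(50)},
                                 sigma_D = 1))
    da[i] <- svd_fit(ds, v)$parameters$Da
  }
  sem <- stats::sd(da) / sqrt(length(da))
  expect_lt(abs(mean(da) - 10), 3 * sem + 1e-12)
})

test_that("degenerate bond geometry is reported as rank deficiency", {
  v <- bond_vectors(matrix(rep(c(0, 0, 1), 6), ncol = 3, byrow = TRUE,
                           dimnames = list(1:6, NULL)))
  ds <- rdc_dataset(data.frame(resno = 1:6, D = rnorm(6), sigma_D = 1))
  expect_error(svd_fit(ds, v), class = "rdcalign_rank_deficient")

  ds4 <- rdc_dataset(data.frame(resno = 1:4, D = rnorm(4), sigma_D = 1))
  expect_error(svd_fit(ds4, random_vectors(4, seed = 2)),
               class = "rdcalign_too_few_rdcs")
})

test_that("Q factor conventions and invariances", {
  obs <- c("1" = 10, "2" = -10)
  calc <- c("1" = 8, "2" = -8)
  expect_equal(q_factor(obs, calc), 0.2, tolerance = 1e-12)
  expect_equal(q_factor(obs, obs), 0)
  expect_equal(q_factor(obs, c("1" = 0, "2" = 0)), 1)
  # scale invariance
  expect_equal(q_factor(3.7 * obs, 3.7 * calc), q_factor(obs, calc), tolerance = 1e-12)
  expect_equal(q_factor(-2 * obs, -2 * calc), q_factor(obs, calc), tolerance = 1e-12)
  expect_error(q_factor(obs, c("9" = 1)), class = "rdcalign_empty_intersection")
  expect_error(q_factor(c("1" = 0), c("1" = 1)), class = "rdcalign_zero_observed")
  # alternative normalisation is defined and positive
  q2 <- q_factor(obs, calc, convention = "da_r", Da = 5, rhombicity = 0.2)
  expect_gt(q2, 0)
})

test_that("principal-frame parameters: rhombicity bounds and Euler recovery", {
  s <- 1e-3
  ax <- alignment_tensor(diag(c(-1, -1, 2)) * s)
  p <- tensor_parameters(ax)
  expect_equal(p$rhombicity, 0, tolerance = 1e-12)
  expect_true(p$degenerate)

  mx <- alignment_tensor(diag(c(0, -1.5, 1.5)) * s)
  expect_equal(tensor_parameters(mx)$rhombicity, 2 / 3, tolerance = 1e-12)

  t1 <- tensor_from_parameters(8, 0.25, c(20, 30, 40))
  p1 <- tensor_parameters(t1)
  expect_equal(unname(p1$euler), c(20, 30, 40), tolerance = 1e-9)
  # recovered parameters rebuild the same tensor
  t2 <- tensor_from_parameters(p1$Da, p1$rhombicity, p1$euler)
  expect_lt(max(abs(t2$saupe - t1$saupe)), 1e-12)
  # an equivalent-frame representative is always among the four
  eq <- equivalent_frames(t1)
  expect_equal(nrow(eq), 4)
  rebuilt <- apply(eq, 1, function(e)
    max(abs(tensor_from_parameters(p1$Da, p1$rhombicity, e)$saupe - t1$saupe)))
  expect_lt(max(rebuilt), 1e-12)
})

test_that("rhombicity stays in [0, 2/3] for random tensors", {
  set.seed(11)
  for (i in 1:50) {
    s <- matrix(stats::rnorm(9, sd = 1e-3), 3, 3)
    s <- (s + t(s)) / 2
    s <- s - diag(3) * sum(diag(s)) / 3
    p <- tensor_parameters(alignment_tensor(s))
    expect_gte(p$rhombicity, -1e-12)
    expect_lte(p$rhombicity, 2 / 3 + 1e-12)
    expect_lte(p$euler[["beta"]], 90 + 1e-9)
  }
})

test_that("fit is rotation-equivariant and Q rotation-invariant", {
  t1 <- ref_tensor()
  v <- random_vectors(30, seed = 5)
  ds <- rdc_dataset(data.frame(resno = 1:30,
                               D = back_calculate(t1, v) + {set.seed(8); rnorm(30)},
                               sigma_D = 1))
  fit <- svd_fit(ds, v)
  set.seed(21)
  R <- random_rotations(1)[, , 1]
  vr <- bond_vectors(t(R %*% t(unclass(v))), chain = "A")
  rownames(vr) <- rownames(v)
  fit_r <- svd_fit(ds, bond_vectors(unclass(vr)))
  expect_lt(max(abs(fit_r$tensor$saupe - R %*% fit$tensor$saupe %*% t(R))), 1e-9)
  expect_equal(fit_r$Q, fit$Q, tolerance = 1e-9)
})

test_that("SVD solution matches normal equations and residuals are orthogonal", {
  t1 <- ref_tensor()
  for (seed in c(13, 17, 19)) {
    v <- random_vectors(25, seed = seed)
    set.seed(seed + 1)
    ds <- rdc_dataset(data.frame(resno = 1:25,
                                 D = back_calculate(t1, v) + rnorm(25, 0, 2),
                                 sigma_D = 1))
    fit <- svd_fit(ds, v)
    # independent normal-equations solve
    B <- unclass(v)
    A <- cbind(B[, 1]^2 - B[, 3]^2, B[, 2]^2 - B[, 3]^2,
               2 * B[, 1] * B[, 2], 2 * B[, 1] * B[, 3], 2 * B[, 2] * B[, 3])
    s_ne <- solve(crossprod(A), crossprod(A, ds$D / t1$scale))
    S_ne <- matrix(c(s_ne[1], s_ne[3], s_ne[4],
                     s_ne[3], s_ne[2], s_ne[5],
                     s_ne[4], s_ne[5], -s_ne[1] - s_ne[2]), 3, 3)
    expect_lt(max(abs(fit$tensor$saupe - S_ne)), 1e-9)
    # least-squares certificate: residuals orthogonal to the column space
    resid <- fit$back_calculated[as.character(1:25)] - ds$D
    expect_lt(max(abs(crossprod(A, resid / t1$scale))), 1e-12)
  }
})

test_that("analytic component uncertainties have the pseudoinverse form", {
  v <- random_vectors(12, seed = 31)
  ds <- rdc_dataset(data.frame(resno = 1:12, D = rnorm(12), sigma_D = 2))
  sdv <- analytic_saupe_sd(ds, v, scale = 21700)
  B <- unclass(v)
  A <- cbind(B[, 1]^2 - B[, 3]^2, B[, 2]^2 - B[, 3]^2,
             2 * B[, 1] * B[, 2], 2 * B[, 1] * B[, 3], 2 * B[, 2] * B[, 3])
  expect_equal(unname(sdv), sqrt(diag(solve(crossprod(A)))) * 2 / 21700,
               tolerance = 1e-10)
})
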