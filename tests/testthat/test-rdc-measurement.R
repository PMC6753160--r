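test_that("peak-position uncertainty follows LW/(2 SN)", {
  expect_equal(peak_position_uncertainty(10, 10), 0.5)
  expect_equal(peak_position_uncertainty(11, 55), 0.1)
  expect_error(peak_position_uncertainty(10, 0), class = "rdcalign_invalid_input")
  expect_error(peak(1, 0, SN = 5, LW = -1))
})

test_that("HSQC/TROSY splittings double the component displacement", {
  h <- peak(7, 6000, SN = 10, LW = 10)
  t <- peak(7, 6000 - 46.5, SN = 10, LW = 10)
  sp <- splitting_from_hsqc_trosy(h, t, "isotropic")
  expect_equal(sp$splitting, -93)
  expect_equal(sp$sigma, 2 * 0.5 * sqrt(2), tolerance = 1e-12)

  same <- splitting_from_hsqc_trosy(h, h, "isotropic")
  expect_equal(same$splitting, 0)

  expect_error(splitting_from_hsqc_trosy(h, peak(8, 0, 1, 1), "isotropic"),
               class = "rdcalign_residue_mismatch")
})

test_that("IPAP splittings are component differences", {
  up <- peak(3, 6000 - 46.5, SN = 10, LW = 10)
  dn <- peak(3, 6000 + 46.5, SN = 10, LW = 10)
  sp <- splitting_from_ipap(up, dn, "anisotropic")
  expect_equal(sp$splitting, 93)
  expect_equal(sp$sigma, 0.5 * sqrt(2), tolerance = 1e-12)
  expect_equal(splitting_from_ipap(up, up, "isotropic")$splitting, 0)
})

test_that("couplings are aniso minus iso splittings with quadrature errors", {
  mk <- function(split, sigma, cond) {
    structure(list(resno = 1L, splitting = split, sigma = sigma,
                   condition = cond, method = "hsqc_trosy", overlapped = FALSE),
              class = "splitting_measurement")
  }
  r <- rdc_from_splittings(mk(-93, 1, "isotropic"), mk(-85, 1, "anisotropic"))
  expect_equal(r$D, 8)
  expect_equal(r$sigma_D, sqrt(2), tolerance = 1e-12)
  r0 <- rdc_from_splittings(mk(-93, 0, "isotropic"), mk(-93, 0, "anisotropic"))
  expect_equal(r0$D, 0)
  expect_error(rdc_from_splittings(mk(-93, 1, "isotropic"),
                                   structure(list(resno = 2L, splitting = 0, sigma = 0,
                                                  condition = "anisotropic",
                                                  method = "hsqc_trosy", overlapped = FALSE),
                                             class = "splitting_measurement")),
               class = "rdcalign_residue_mismatch")
})

test_that("quality filters use strict thresholds with reason priority", {
  ds <- rdc_dataset(data.frame(
    resno = 1:6,
    D = c(5, 5, 5, 5, 5, 5),
    sigma_D = c(6, 1, 5.0, 1, 6, 1),
    overlapped = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)))
  s2 <- c("2" = 0.80, "3" = 0.9, "5" = 0.5, "6" = 0.85)
  out <- filter_rdcs(ds, s2_by_residue = s2, exchange_residues = c(4))
  expect_equal(out$reason,
               c("sigma_too_large",  # 1: sigma 6 > 5
                 "flexible",         # 2: S2 0.80 < 0.85
                 "none",             # 3: sigma exactly 5, S2 0.9 -> retained
                 "exchange",         # 4: exchange beats overlap
                 "flexible",         # 5: flexible beats overlap and sigma
                 "none"))            # 6: S2 exactly 0.85 -> retained
  expect_equal(out$excluded, out$reason != "none")
  # rms_sigma over survivors only
  expect_equal(rms_sigma(out), sqrt(mean(c(5, 1)^2)))
})

test_that("filtering is idempotent and monotone in its thresholds", {
  set.seed(7)
  ds <- rdc_dataset(data.frame(resno = 1:40, D = stats::rnorm(40, 0, 10),
                               sigma_D = stats::runif(40, 0, 8),
                               overlapped = stats::runif(40) < 0.2))
  s2 <- stats::setNames(stats::runif(40, 0.5, 1), 1:40)
  once <- filter_rdcs(ds, s2, exchange_residues = c(3, 9))
  twice <- filter_rdcs(once, s2, exchange_residues = c(3, 9))
  expect_identical(as.data.frame(once), as.data.frame(twice))

  surv <- function(x) sum(!x$excluded)
  s_prev <- Inf
  for (s2min in c(0.6, 0.75, 0.9, 1.0)) {
    s_now <- surv(filter_rdcs(ds, s2, s2_min = s2min))
    expect_lte(s_now, s_prev)
    s_prev <- s_now
  }
  s_prev <- -1
  for (smax in c(1, 3, 5, 9)) {
    s_now <- surv(filter_rdcs(ds, s2, sigma_max = smax))
    expect_gte(s_now, s_prev)
    s_prev <- s_now
  }
})

test_that("noiseless simulated peak lists round trip to the generating RDCs", {
  spec <- fixture_spec("ideal_helix", n_residues = 12, noise = 0)
  st <- make_structure(spec)
  t1 <- ref_tensor()
  for (method in c("hsqc_trosy", "ipap")) {
    pl <- simulate_peak_lists(st, t1, spec, method = method)
    ds <- rdcs_from_peak_lists(pl[[1]], pl[[2]], pl[[3]], pl[[4]], method = method)
    truth <- attr(pl, "truth")[as.character(ds$resno)]
    expect_lt(max(abs(ds$D - truth)), 1e-9)
  }
})

test_that("RDC tables and peak lists round trip through files", {
  ds <- rdc_dataset(data.frame(resno = c(2, 5, 9), D = c(4.25, -11.5, 0.125),
                               sigma_D = c(1, 2, 0.5),
                               excluded = c(FALSE, TRUE, FALSE),
                               reason = c("none", "overlap", "none")))
  f <- tempfile(fileext = ".tsv")
  write_rdc_table(ds, f, comment = "test provenance")
  ds2 <- read_rdc_table(f)
  expect_equal(ds2$D, ds$D)
  expect_equal(ds2$excluded, ds$excluded)
  expect_equal(ds2$reason, ds$reason)

  pk <- data.frame(resno = 1:3, nu15N = c(6000.5, 6025.25, 6050),
                   SN = c(30, 12, 40), LW = c(11, 9, 13),
                   overlapped = c(FALSE, TRUE, FALSE))
  fp <- tempfile(fileext = ".txt")
  write_peak_list(pk, fp)
  pk2 <- read_peak_list(fp)
  expect_equal(pk2$nu15N, pk$nu15N)
  expect_equal(pk2$overlapped, pk$overlapped)
})

test_that("PALES-style DC tables are parsed", {
  f <- tempfile(fileext = ".tab")
  writeLines(c(
    "REMARK synthetic table",
    "VARS RESID_I RESNAME_I ATOMNAME_I RESID_J RESNAME_J ATOMNAME_J D DD W",
    "FORMAT %5d %6s %6s %5d %6s %6s %9.3f %9.3f %.2f",
    "    2    ALA      H     2    ALA      N     8.250     1.000 1.00",
    "    3    GLY      H     3    GLY      N    -4.500     2.000 0.00",
    "    4    LEU      H     4    LEU      N    12.000     0.500 1.00"), f)
  ds <- read_dc_table(f)
  expect_equal(ds$resno, c(2L, 3L, 4L))
  expect_equal(ds$D, c(8.25, -4.5, 12))
  expect_equal(ds$sigma_D, c(1, 2, 0.5))
  expect_equal(ds$reason, c("none", "overlap", "none"))
})
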