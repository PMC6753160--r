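# Coupling measurement from peak lists and dataset-quality filtering.
#
# Peak positions are consumed in Hz (any ppm -> Hz conversion belongs to
# the reader configuration). A peak's position uncertainty follows the
# linewidth/signal-to-noise rule sigma_v = LW / (2 SN); splitting and
# coupling uncertainties are propagated in quadrature from there.

#' Construct a peak
#'
#' @param resno residue number.
#' @param nu15N 15N-dimension position in Hz.
#' @param SN signal-to-noise ratio (> 0).
#' @param LW 15N linewidth in Hz (> 0).
#' @param overlapped TRUE if the resonance is overlapped in the spectrum.
#' @return a `peak` object.
#' @export
peak <- function(resno, nu15N, SN, LW, overlapped = FALSE) {
  rdc_assert(SN > 0 && LW > 0, "peak SN and LW must be positive")
  structure(list(resno = as.integer(resno), nu15N = nu15N, SN = SN, LW = LW,
                 overlapped = isTRUE(overlapped)), class = "peak")
}

#' Peak-position uncertainty from linewidth and signal-to-noise
#'
#' `sigma_v = LW / (2 SN)`, in Hz.
#'
#' @param LW linewidth in Hz (> 0).
#' @param SN signal-to-noise ratio (> 0).
#' @return position uncertainty in Hz.
#' @export
peak_position_uncertainty <- function(LW, SN) {
  rdc_assert(all(LW > 0) && all(SN > 0), "LW and SN must be positive")
  LW / (2 * SN)
}

new_splitting <- function(resno, splitting, sigma, condition, method, overlapped) {
  condition <- match.arg(condition, c("isotropic", "anisotropic"))
  structure(list(resno = as.integer(resno), splitting = splitting, sigma = sigma,
                 condition = condition, method = method, overlapped = overlapped),
            class = "splitting_measurement")
}

#' 15N splitting from an HSQC/TROSY peak pair
#'
#' The decoupled HSQC peak sits at the multiplet centre and the TROSY peak
#' at one multiplet component, displaced by half the splitting; hence
#' `splitting = 2 (nu_trosy - nu_hsqc)` and
#' `sigma = 2 sqrt(sigma_hsqc^2 + sigma_trosy^2)`. The sign of the TROSY
#' displacement convention is carried by the data itself (see
#' [simulate_peak_lists()] for the simulated convention, `+(J+D)/2`).
#'
#' @param peak_hsqc,peak_trosy [peak()]s for the same residue.
#' @param condition "isotropic" or "anisotropic".
#' @return a `splitting_measurement`.
#' @export
splitting_from_hsqc_trosy <- function(peak_hsqc, peak_trosy, condition) {
  rdc_assert(peak_hsqc$resno == peak_trosy$resno,
             "HSQC and TROSY peaks must be for the same residue", "residue_mismatch")
  sv <- c(peak_position_uncertainty(peak_hsqc$LW, peak_hsqc$SN),
          peak_position_uncertainty(peak_trosy$LW, peak_trosy$SN))
  new_splitting(peak_hsqc$resno,
                splitting = 2 * (peak_trosy$nu15N - peak_hsqc$nu15N),
                sigma = 2 * sqrt(sum(sv^2)),
                condition = condition, method = "hsqc_trosy",
                overlapped = peak_hsqc$overlapped || peak_trosy$overlapped)
}

#' 15N splitting from an IPAP doublet
#'
#' The sum/difference sub-spectra give the two doublet components
#' directly: `splitting = nu_downfield - nu_upfield`,
#' `sigma = sqrt(sigma_up^2 + sigma_down^2)`.
#'
#' @param peak_upfield,peak_downfield [peak()]s of the two components.
#' @param condition "isotropic" or "anisotropic".
#' @return a `splitting_measurement`.
#' @export
splitting_from_ipap <- function(peak_upfield, peak_downfield, condition) {
  rdc_assert(peak_upfield$resno == peak_downfield$resno,
             "IPAP components must be for the same residue", "residue_mismatch")
  sv <- c(peak_position_uncertainty(peak_upfield$LW, peak_upfield$SN),
          peak_position_uncertainty(peak_downfield$LW, peak_downfield$SN))
  new_splitting(peak_upfield$resno,
                splitting = peak_downfield$nu15N - peak_upfield$nu15N,
                sigma = sqrt(sum(sv^2)),
                condition = condition, method = "ipap",
                overlapped = peak_upfield$overlapped || peak_downfield$overlapped)
}

#' Residual dipolar coupling from isotropic and anisotropic splittings
#'
#' `D = splitting_aniso - splitting_iso` with uncertainties combined in
#' quadrature. Both splittings must come from the same residue and the
#' same measurement method.
#'
#' @param iso,aniso `splitting_measurement`s.
#' @return a one-row [rdc_dataset()] record (data.frame row).
#' @export
rdc_from_splittings <- function(iso, aniso) {
  rdc_assert(iso$resno == aniso$resno,
             "isotropic and anisotropic splittings must share the residue",
             "residue_mismatch")
  rdc_assert(identical(iso$method, aniso$method),
             "isotropic and anisotropic splittings must share the method",
             "method_mismatch")
  rdc_assert(identical(iso$condition, "isotropic") &&
             identical(aniso$condition, "anisotropic"),
             "arguments must be one isotropic and one anisotropic measurement")
  data.frame(resno = iso$resno,
             D = aniso$splitting - iso$splitting,
             sigma_D = sqrt(iso$sigma^2 + aniso$sigma^2),
             overlapped = iso$overlapped || aniso$overlapped,
             excluded = FALSE, reason = "none",
             stringsAsFactors = FALSE)
}

#' Construct an RDC dataset
#'
#' @param records data.frame with columns `resno`, `D` (Hz), `sigma_D`
#'   (Hz, >= 0) and optionally `overlapped`, `excluded`, `reason`.
#' @return an `rdc_dataset` (a data.frame subclass). The RMS uncertainty
#'   over included records is available via [rms_sigma()].
#' @export
rdc_dataset <- function(records) {
  rdc_assert(is.data.frame(records) && all(c("resno", "D", "sigma_D") %in% names(records)),
             "records must have columns resno, D, sigma_D")
  rdc_assert(all(records$sigma_D >= 0), "sigma_D must be >= 0")
  if (is.null(records$overlapped)) records$overlapped <- FALSE
  if (is.null(records$excluded)) records$excluded <- FALSE
  if (is.null(records$reason)) records$reason <- "none"
  rdc_assert(all(records$excluded == (records$reason != "none")),
             "excluded flag must correspond to a non-'none' reason")
  rdc_assert(!anyDuplicated(records$resno), "duplicate residue numbers in dataset")
  records$resno <- as.integer(records$resno)
  rownames(records) <- NULL
  class(records) <- c("rdc_dataset", "data.frame")
  records
}

#' RMS experimental uncertainty of a dataset
#'
#' `sqrt(mean(sigma_D^2))` over the included (non-excluded) records.
#'
#' @param dataset an [rdc_dataset()].
#' @return RMS uncertainty in Hz (NA if no records survive).
#' @export
rms_sigma <- function(dataset) {
  s <- dataset$sigma_D[!dataset$excluded]
  if (length(s) == 0) return(NA_real_)
  sqrt(mean(s^2))
}

#' Apply dataset-quality filters to an RDC dataset
#'
#' Marks records excluded that correspond to locally flexible residues
#' (order parameter `S^2 < s2_min`), residues in conformational exchange,
#' overlapped resonances, or large experimental uncertainty
#' (`sigma_D > sigma_max`). Both thresholds are strict inequalities. When
#' several rules match, the recorded reason follows the priority
#' flexible > exchange > overlap > sigma_too_large.
#'
#' @param dataset an [rdc_dataset()].
#' @param s2_by_residue named numeric vector, residue -> order parameter
#'   S^2 (residues absent from the map are not tested for flexibility).
#' @param exchange_residues residues undergoing conformational exchange.
#' @param s2_min flexibility threshold (default 0.85).
#' @param sigma_max uncertainty threshold in Hz (default 5).
#' @return the filtered `rdc_dataset`; if no record survives, an attribute
#'   `empty_survivors` is set to TRUE.
#' @export
filter_rdcs <- function(dataset, s2_by_residue = numeric(0),
                        exchange_residues = integer(0),
                        s2_min = 0.85, sigma_max = 5) {
  ds <- as.data.frame(dataset)
  s2 <- s2_by_residue[as.character(ds$resno)]
  flexible <- !is.na(s2) & s2 < s2_min
  exchange <- ds$resno %in% exchange_residues
  overlap <- isTRUE_vec(ds$overlapped)
  sigma_big <- ds$sigma_D > sigma_max

  reason <- rep("none", nrow(ds))
  reason[sigma_big] <- "sigma_too_large"
  reason[overlap] <- "overlap"
  reason[exchange] <- "exchange"
  reason[flexible] <- "flexible"
  ds$reason <- reason
  ds$excluded <- reason != "none"
  out <- rdc_dataset(ds)
  if (all(out$excluded)) attr(out, "empty_survivors") <- TRUE
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# ---- file formats -----------------------------------------------------

#' Read a peak list
#'
#' Whitespace/tab-delimited text with columns
#' `residue nu15N_Hz SN LW_Hz overlapped(0/1)`; `#` starts a comment.
#'
#' @param path file path.
#' @return data.frame with columns `resno`, `nu15N`, `SN`, `LW`,
#'   `overlapped`.
#' @export
read_peak_list <- function(path) {
  if (!file.exists(path)) rdc_abort(paste("peak list not found:", path), "missing_file")
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("resno", "nu15N", "SN", "LW", "overlapped"))
  df$resno <- as.integer(df$resno)
  df$overlapped <- df$overlapped != 0
  rdc_assert(all(df$SN > 0) && all(df$LW > 0), "peak list contains non-positive SN or LW")
  df
}

#' Write a peak list
#'
#' @param peaks data.frame as returned by [read_peak_list()].
#' @param path output path.
#' @param comment optional provenance comment written as a `#` header.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines("# residue nu15N_Hz SN LW_Hz overlapped", con)
  writeLines(sprintf("%d\t%.6f\t%.3f\t%.3f\t%d", peaks$resno, peaks$nu15N,
                     peaks$SN, peaks$LW, as.integer(peaks$overlapped)), con)
  invisible(path)
}

#' Build splittings, then RDCs, from per-condition peak lists
#'
#' Convenience pipeline over [splitting_from_hsqc_trosy()] /
#' [splitting_from_ipap()] and [rdc_from_splittings()], keyed by residue.
#' For `method = "hsqc_trosy"` the four data.frames are the HSQC and TROSY
#' peaks under each condition; for `method = "ipap"` they are the upfield
#' and downfield components.
#'
#' @param iso_a,iso_b,aniso_a,aniso_b peak data.frames
#'   ([read_peak_list()] format). For "hsqc_trosy": a = HSQC, b = TROSY;
#'   for "ipap": a = upfield, b = downfield.
#' @param method "hsqc_trosy" or "ipap".
#' @return an [rdc_dataset()] over the residues common to all four lists.
#' @export
rdcs_from_peak_lists <- function(iso_a, iso_b, aniso_a, aniso_b,
                                 method = c("hsqc_trosy", "ipap")) {
  method <- match.arg(method)
  shared <- Reduce(intersect, list(iso_a$resno, iso_b$resno, aniso_a$resno, aniso_b$resno))
  rdc_assert(length(shared) > 0, "no residues common to all four peak lists")
  one <- function(df, r) {
    i <- match(r, df$resno)
    peak(df$resno[i], df$nu15N[i], df$SN[i], df$LW[i], df$overlapped[i])
  }
  splitter <- if (method == "hsqc_trosy") splitting_from_hsqc_trosy else splitting_from_ipap
  rows <- lapply(shared, function(r) {
    iso <- splitter(one(iso_a, r), one(iso_b, r), "isotropic")
    aniso <- splitter(one(aniso_a, r), one(aniso_b, r), "anisotropic")
    rdc_from_splittings(iso, aniso)
  })
  rdc_dataset(do.call(rbind, rows))
}

#' Read an RDC table
#'
#' Tab-delimited text with columns `residue D_Hz sigma_Hz excluded reason`
#' and `#` comment headers.
#'
#' @param path file path.
#' @return an [rdc_dataset()].
#' @export
read_rdc_table <- function(path) {
  if (!file.exists(path)) rdc_abort(paste("RDC table not found:", path), "missing_file")
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("resno", "D", "sigma_D", "excluded", "reason"),
                          stringsAsFactors = FALSE)
  df$excluded <- df$excluded != 0
  rdc_dataset(df)
}

#' Write an RDC table
#'
#' @param dataset an [rdc_dataset()].
#' @param path output path.
#' @param comment optional provenance line(s) for the `#` header.
#' @return `path`, invisibly.
#' @export
write_rdc_table <- function(dataset, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(sprintf("# rms_sigma_included_Hz %.6g", rms_sigma(dataset)), con)
  writeLines("# residue D_Hz sigma_Hz excluded reason", con)
  writeLines(sprintf("%d\t%.6f\t%.6f\t%d\t%s", dataset$resno, dataset$D,
                     dataset$sigma_D, as.integer(dataset$excluded), dataset$reason), con)
  invisible(path)
}

#' Read a PALES-style DC table
#'
#' Tolerant reader for the order-matrix "DC" dipolar-coupling table
#' dialect: `VARS`/`FORMAT`/`DATA`/`REMARK` header lines are skipped and
#' each data row is expected to carry
#' `resid_i resname_i atom_i resid_j resname_j atom_j D DD W`.
#'
#' @param path file path.
#' @return an [rdc_dataset()] (`sigma_D` from the DD column; rows with
#'   weight 0 are marked excluded with reason "overlap").
#' @export
read_dc_table <- function(path) {
  if (!file.exists(path)) rdc_abort(paste("DC table not found:", path), "missing_file")
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln)]
  ln <- ln[!grepl("^(#|VARS|FORMAT|DATA|REMARK)", ln)]
  rdc_assert(length(ln) > 0, "DC table contains no data rows")
  parts <- strsplit(ln, "[[:space:]]+")
  rdc_assert(all(lengths(parts) >= 9), "DC table rows must have >= 9 fields")
  m <- do.call(rbind, lapply(parts, `[`, 1:9))
  w <- as.numeric(m[, 9])
  df <- data.frame(resno = as.integer(m[, 1]),
                   D = as.numeric(m[, 7]),
                   sigma_D = as.numeric(m[, 8]),
                   overlapped = w == 0,
                   excluded = w == 0,
                   reason = ifelse(w == 0, "overlap", "none"),
                   stringsAsFactors = FALSE)
  rdc_dataset(df)
}
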