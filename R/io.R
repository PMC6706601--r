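# Spectrum file IO (two-column CSV and mzML), run configuration, and
# provenance-stamped table output.

.default_grid <- function(mz_range = c(120, 300), mz_step = 0.01) {
  seq(mz_range[1], mz_range[2], by = mz_step)
}

#' Read a spectrum from CSV or mzML
#'
#' CSV: two numeric columns (m/z, intensity), header optional, comment
#' lines starting with `#` ignored. mzML is read through the `mzR` package
#' (first spectrum of the file unless `scan` is given). Non-uniform m/z
#' axes are resampled onto the configured uniform grid by linear
#' interpolation, with a warning.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"` or `"mzml"`.
#' @param scan Scan number for mzML files.
#' @param mz_range,mz_step Grid used when resampling a non-uniform axis.
#' @return A `mass_spectrum`.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "mzml"),
                          scan = 1L, mz_range = c(120, 300), mz_step = 0.01) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
    else "csv"
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package")
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, scan)
    mz <- pk[, 1]; intensity <- pk[, 2]
  } else {
    first <- readLines(path, n = 50L)
    first <- first[!startsWith(trimws(first), "#")]
    has_header <- !grepl("^\\s*-?[0-9.]", first[1])
    d <- utils::read.csv(path, header = has_header, comment.char = "#")
    if (ncol(d) < 2L) stop("spectrum CSV needs two columns (m/z, intensity)")
    mz <- as.numeric(d[[1]]); intensity <- as.numeric(d[[2]])
  }
  if (anyNA(mz) || anyNA(intensity))
    stop("non-numeric values in spectrum data")
  if (any(diff(mz) <= 0))
    stop("m/z axis must be strictly increasing")
  if (any(intensity < 0)) stop("negative intensities in spectrum")
  d2 <- diff(mz)
  if (max(d2) - min(d2) > 1e-6 * stats::median(d2)) {
    warning("non-uniform m/z axis: resampling to the configured grid")
    grid <- .default_grid(mz_range, mz_step)
    intensity <- stats::approx(mz, intensity, xout = grid, rule = 2)$y
    mz <- grid
  }
  id <- sub("\\.[^.]+$", "", basename(path))
  sp <- regmatches(id, regexec("_spot([0-9]+)$", id))[[1]]
  spot <- if (length(sp) == 2L) as.integer(sp[2]) else 1L
  if (length(sp) == 2L) id <- sub("_spot[0-9]+$", "", id)
  mass_spectrum(mz, intensity, sample_id = id, spot = spot)
}

#' Write a spectrum to CSV or mzML
#'
#' CSV output is two columns (`mz`, `intensity`) with optional provenance
#' comment lines. mzML output goes through `mzR`.
#'
#' @param s A `mass_spectrum`.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"csv"` or `"mzml"`.
#' @param provenance Optional named character vector written as `# key=value`
#'   comment lines (CSV only).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("auto", "csv", "mzml"),
                           provenance = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
    else "csv"
  }
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("writing mzML requires the mzR package")
    hdr <- data.frame(
      seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 0L,
      peaksCount = length(s$mz), totIonCurrent = sum(s$intensity),
      retentionTime = 0, basePeakMZ = s$mz[which.max(s$intensity)],
      basePeakIntensity = max(s$intensity), collisionEnergy = 0,
      ionisationEnergy = 0, lowMZ = min(s$mz), highMZ = max(s$mz),
      precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
      precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
      mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
      injectionTime = 0, filterString = NA_character_,
      spectrumId = "scan=1", centroided = FALSE,
      ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = NA_real_,
      isolationWindowLowerOffset = NA_real_,
      isolationWindowUpperOffset = NA_real_,
      scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
    mzR::writeMSData(list(cbind(s$mz, s$intensity)), path, header = hdr)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(provenance))
      writeLines(sprintf("# %s=%s", names(provenance), provenance), con)
    writeLines("mz,intensity", con)
    writeLines(sprintf("%.6f,%.10g", s$mz, s$intensity), con)
  }
  invisible(path)
}

#' Default run configuration
#'
#' All tunable parameters of the workflow with their defaults; values from
#' a YAML file (if given) override the defaults. Unknown keys are
#' rejected; a seed is mandatory for any simulation command.
#'
#' @param path Optional YAML file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(
    seed = NULL,
    calibration_levels = c(0, 1, 5, 10, 25, 50, 75),
    interference_tnt_levels = c(0, 5, 25, 75),
    interference_adnt_levels = c(0, 5, 25, 75),
    n_spots = 3L,
    tolerance = 0.5,
    lod_factor = 3.3,
    spot_noise_cv = 0.08,
    channel_noise_cv = 0.03,
    baseline_noise_sd = 0.1,
    mass_jitter_sd = 0.1,
    peak_width_sigma = 0.05,
    soil_mass_g = 2,
    extract_volume_ml = 4,
    dilution_factor = 1,
    recalibration_references = c(216, 156, 157))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
    cfg[names(user)] <- user
  }
  stopifnot(cfg$tolerance > 0, cfg$n_spots >= 1, cfg$lod_factor > 0,
            cfg$spot_noise_cv >= 0, cfg$channel_noise_cv >= 0,
            cfg$soil_mass_g > 0, cfg$extract_volume_ml > 0,
            cfg$dilution_factor >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; stamped into every artifact so
#' reruns are traceable to their exact configuration.
#'
#' @param cfg A `run_config`.
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# Write a data frame as CSV with provenance comment lines; readers use
# comment.char = "#".
write_table_with_provenance <- function(df, path, cfg = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed=%s", seed), con)
  if (!is.null(cfg)) writeLines(sprintf("# config=%s", config_hash(cfg)), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
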