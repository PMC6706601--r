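# Preprocessing: mass recalibration, TIC normalization, peak detection and
# targeted ion extraction turning raw spectra into per-channel abundances.

#' Total-ion-current normalization
#'
#' Divides intensities by their sum so the spectrum integrates to 1.
#' Idempotent and scale-invariant; sets the `tic_normalized` flag.
#'
#' @param s A `mass_spectrum`.
#' @return The normalized spectrum.
#' @export
tic_normalize <- function(s) {
  stopifnot(inherits(s, "mass_spectrum"))
  tot <- sum(s$intensity)
  if (tot <= 0) stop("cannot TIC-normalize an all-zero spectrum")
  s$intensity <- s$intensity / tot
  add_flag(s, "tic_normalized")
}

# Robust baseline-noise estimate: MAD of the intensity vector (most of the
# axis is baseline in a targeted small-molecule spectrum).
noise_estimate <- function(s) {
  stats::mad(s$intensity, center = stats::median(s$intensity))
}

# Locate the apex of the most intense signal within +-window of an
# expected m/z. Returns NULL when nothing rises above 5x the noise.
.find_reference_apex <- function(s, expected, window = 0.5) {
  sel <- which(s$mz >= expected - window & s$mz <= expected + window)
  if (!length(sel)) return(NULL)
  noise <- noise_estimate(s)
  i <- sel[which.max(s$intensity[sel])]
  if (s$intensity[i] <= 5 * noise || s$intensity[i] <= 0) return(NULL)
  apex <- parabola_apex(s$mz, s$intensity, i)
  apex[["mz"]]
}

#' Recalibrate the m/z axis against reference ions
#'
#' Matches each expected reference m/z to the nearest strong apex within a
#' search window. One match corrects a constant shift; two or more matches
#' fit a least-squares linear (shift + stretch) map from true to observed
#' position. The intensities are then resampled onto the original uniform
#' grid by linear interpolation so that apexes land at their expected
#' positions.
#'
#' @param s A `mass_spectrum`.
#' @param references Expected reference m/z values. The default uses ions
#'   present in every acquisition: the internal standard (216) and the DAN
#'   matrix ions (156, 157).
#' @param window Search half-window in Da.
#' @return The recalibrated spectrum; attribute `recalibration` carries the
#'   matched references, the fitted map and per-reference residuals.
#' @export
recalibrate_mass_axis <- function(s, references = c(216, 156, 157),
                                  window = 0.5) {
  stopifnot(inherits(s, "mass_spectrum"), length(references) >= 1L)
  observed <- vapply(references, function(r) {
    a <- .find_reference_apex(s, r, window)
    if (is.null(a)) NA_real_ else a
  }, numeric(1))
  ok <- !is.na(observed)
  if (!any(ok))
    stop(sprintf(
      "mass recalibration failed: no reference matched within +-%g Da of {%s}",
      window, paste(references, collapse = ", ")))
  exp_ok <- references[ok]
  obs_ok <- observed[ok]
  if (sum(ok) == 1L) {
    alpha <- obs_ok - exp_ok
    beta <- 1
  } else {
    fit <- stats::lm(obs_ok ~ exp_ok)
    alpha <- unname(stats::coef(fit)[1])
    beta <- unname(stats::coef(fit)[2])
  }
  # intensity at true position g is found at observed position alpha+beta*g
  new_int <- stats::approx(s$mz, s$intensity, xout = alpha + beta * s$mz,
                           rule = 2)$y
  s$intensity <- pmax(new_int, 0)
  s <- add_flag(s, "recalibrated")
  attr(s, "recalibration") <- list(
    references = references, observed = observed,
    shift = alpha, stretch = beta,
    residuals = obs_ok - (alpha + beta * exp_ok))
  s
}

#' Detect peaks in a spectrum
#'
#' Local maxima whose intensity exceeds `median + snr_threshold * MAD` of
#' the intensity vector; apex position and height are refined by quadratic
#' interpolation of the three points around each maximum.
#'
#' @param s A `mass_spectrum`.
#' @param snr_threshold Signal-to-noise threshold (default 3).
#' @return A `peak_list`: data frame (mz, intensity, snr) sorted by m/z,
#'   with the provenance spectrum id as an attribute. May be empty.
#' @export
detect_peaks <- function(s, snr_threshold = 3) {
  stopifnot(inherits(s, "mass_spectrum"))
  y <- s$intensity
  n <- length(y)
  noise <- noise_estimate(s)
  med <- stats::median(y)
  thr <- max(med + snr_threshold * noise, 0)
  idx <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                 y[2:(n - 1L)] >= y[3:n] &
                 y[2:(n - 1L)] > thr) + 1L
  if (!length(idx)) {
    out <- data.frame(mz = numeric(0), intensity = numeric(0),
                      snr = numeric(0))
  } else {
    apex <- t(vapply(idx, function(i) parabola_apex(s$mz, y, i), numeric(2)))
    out <- data.frame(mz = apex[, 1], intensity = apex[, 2],
                      snr = if (noise > 0) (apex[, 2] - med) / noise else Inf)
    out <- out[order(out$mz), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "sample_id") <- s$metadata$sample_id
  attr(out, "spot") <- s$metadata$spot
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Extract targeted ion abundances and normalize to the internal standard
#'
#' For each target channel, the raw abundance is the maximum intensity
#' within `tolerance` of the channel m/z; normalized abundance is the ratio
#' to the raw abundance of the internal-standard channel (m/z 216) of the
#' same spectrum. Quantification is impossible without a detected IS peak:
#' if the IS raw abundance does not exceed 5x the robust baseline noise,
#' an error is raised.
#'
#' @param s A `mass_spectrum` (TIC-normalized; a warning is issued
#'   otherwise).
#' @param channels Data frame with columns `mz`, `label`, `group` (as from
#'   [quant_channels()]) or a numeric vector of m/z values.
#' @param tolerance Extraction half-window in Da (default 0.5).
#' @param is_mz Internal-standard channel m/z (default 216).
#' @return Data frame (sample_id, spot, channel_mz, channel_label, group,
#'   raw, normalized) including a row for the IS channel itself (normalized
#'   value 1); attribute `tolerance` records the window.
#' @export
extract_ion_abundance <- function(s, channels, tolerance = 0.5,
                                  is_mz = 216) {
  stopifnot(inherits(s, "mass_spectrum"), tolerance > 0)
  if (!has_flag(s, "tic_normalized"))
    warning("extracting from a spectrum that is not TIC-normalized")
  if (is.numeric(channels))
    channels <- data.frame(mz = channels,
                           label = sprintf("mz%g", channels),
                           group = NA_character_)
  window_max <- function(target) {
    sel <- which(s$mz >= target - tolerance & s$mz <= target + tolerance)
    if (!length(sel)) return(0)
    max(s$intensity[sel])
  }
  raw_is <- window_max(is_mz)
  noise <- noise_estimate(s)
  if (raw_is <= 5 * noise || raw_is <= 0)
    stop(sprintf(
      "internal standard channel (m/z %g) below detection (raw %.3g, 5x noise %.3g): quantification impossible",
      is_mz, raw_is, 5 * noise))
  raw <- vapply(channels$mz, window_max, numeric(1))
  out <- data.frame(
    sample_id = s$metadata$sample_id,
    spot = s$metadata$spot,
    channel_mz = c(channels$mz, is_mz),
    channel_label = c(channels$label, sprintf("IS_%g", is_mz)),
    group = c(channels$group, "IS"),
    raw = c(raw, raw_is),
    normalized = c(raw / raw_is, 1),
    stringsAsFactors = FALSE)
  attr(out, "tolerance") <- tolerance
  out
}

#' Normalize abundances to the internal standard
#'
#' Pipeline alias for [extract_ion_abundance()], which performs the
#' extraction and the IS normalization in one pass.
#'
#' @inheritParams extract_ion_abundance
#' @export
normalize_to_internal_standard <- function(s, channels, tolerance = 0.5,
                                           is_mz = 216) {
  extract_ion_abundance(s, channels, tolerance = tolerance, is_mz = is_mz)
}

#' Average replicate spots of one sample
#'
#' @param rows Ion-abundance rows (from [extract_ion_abundance()]) of one
#'   sample's spots.
#' @return Data frame (sample_id, channel_mz, channel_label, group,
#'   mean_normalized, sd_normalized, n) — arithmetic mean and sample SD of
#'   the per-spot IS-normalized abundances.
#' @export
average_replicates <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  if (length(unique(rows$sample_id)) != 1L)
    stop("average_replicates expects spots of a single sample")
  agg <- split(rows, rows$channel_mz)
  out <- do.call(rbind, lapply(agg, function(d) {
    data.frame(sample_id = d$sample_id[1],
               channel_mz = d$channel_mz[1],
               channel_label = d$channel_label[1],
               group = d$group[1],
               mean_normalized = mean(d$normalized),
               sd_normalized = if (nrow(d) > 1L) stats::sd(d$normalized)
               else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Preprocess a batch of spectra into an ion-abundance table
#'
#' Applies the fixed processing order — mass recalibration, TIC
#' normalization, targeted extraction with IS normalization — to each
#' spectrum and binds the per-spot rows.
#'
#' @param spectra List of `mass_spectrum` objects.
#' @param channels Channel table (see [extract_ion_abundance()]).
#' @param tolerance Extraction half-window (Da).
#' @param references Recalibration references; `NULL` skips recalibration.
#' @param is_mz Internal-standard channel m/z.
#' @return Ion-abundance data frame over all spectra.
#' @export
spectra_to_abundance <- function(spectra, channels, tolerance = 0.5,
                                 references = c(216, 156, 157),
                                 is_mz = 216) {
  rows <- lapply(spectra, function(s) {
    if (!is.null(references))
      s <- recalibrate_mass_axis(s, references)
    s <- tic_normalize(s)
    extract_ion_abundance(s, channels, tolerance = tolerance, is_mz = is_mz)
  })
  out <- do.call(rbind, rows)
  attr(out, "tolerance") <- tolerance
  out
}
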