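# Quantification: inversion of calibration models (simple and sequential
# TNT-then-ADNT interference correction), channel averaging, soil-unit
# conversion and replicate reporting.

#' Invert a simple calibration at one abundance
#'
#' `c = (A - a) / b_own`. Negative estimates are reported with a flag, not
#' clamped (preserves unbiased replicate averaging); estimates below the
#' model's LOD are flagged.
#'
#' @param m A fitted `calibration_model` with positive slope.
#' @param abundance IS-normalized abundance.
#' @return One-row data frame (channel_mz, group, estimate, below_lod,
#'   negative).
#' @export
invert_simple <- function(m, abundance) {
  stopifnot(inherits(m, "calibration_model"))
  if (is.na(m$b_own) || m$b_own <= 0)
    stop("cannot invert a calibration without a positive slope")
  est <- (abundance - m$a) / m$b_own
  data.frame(channel_mz = m$channel_mz, group = m$group, estimate = est,
             below_lod = !is.na(m$lod) && est < m$lod,
             negative = est < 0, stringsAsFactors = FALSE)
}

#' Average per-channel concentration estimates for one analyte
#'
#' Unweighted mean over the channel estimates (radical anion and
#' oxygen-loss fragment); channels flagged below-LOD are excluded unless
#' every channel is flagged, in which case the flagged mean is reported.
#'
#' @param estimates Data frame of per-channel rows as returned by
#'   [invert_simple()] (one analyte group).
#' @return One-row data frame (group, estimate, n_channels, below_lod,
#'   negative).
#' @export
average_channel_estimates <- function(estimates) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1L)
  if (length(unique(estimates$group)) != 1L)
    stop("average_channel_estimates expects a single analyte group")
  use <- estimates[!estimates$below_lod, , drop = FALSE]
  all_flagged <- nrow(use) == 0L
  if (all_flagged) use <- estimates
  data.frame(group = estimates$group[1],
             estimate = mean(use$estimate),
             n_channels = nrow(use),
             below_lod = all_flagged,
             negative = mean(use$estimate) < 0,
             stringsAsFactors = FALSE)
}

#' Sequential interference-corrected inversion
#'
#' The two-step scheme for TNT/ADNT mixtures: (1) estimate TNT by simple
#' inversion of its channels (m/z 227, 211) and average them; (2) for each
#' ADNT channel with an interference calibration, subtract the fitted TNT
#' contribution before inverting:
#' `c_ADNT = (A - a - b_tnt * c_TNT_hat) / b_own`; (3) average the ADNT
#' channels. All other analytes are simple-inverted. When the TNT estimate
#' is itself below the LOD, the point estimate is still propagated
#' (substituting 0 would bias ADNT upward). Results are isomer-group sums.
#'
#' @param models Named list of `calibration_model`s keyed by channel m/z;
#'   TNT channels must carry simple models when any interference model is
#'   present.
#' @param abundances Named numeric vector of IS-normalized abundances
#'   keyed by channel m/z (as character).
#' @return Data frame with one row per analyte group (group, estimate,
#'   n_channels, below_lod, negative) plus per-channel rows in the
#'   attribute `"channels"`.
#' @export
invert_sequential <- function(models, abundances) {
  keys <- names(models)
  has_interference <- any(vapply(models, function(m) m$kind == "interference",
                                 logical(1)))
  tnt_keys <- keys[vapply(models, function(m) m$group == "TNT", logical(1))]
  if (has_interference && !length(tnt_keys))
    stop("interference models present but no TNT channels to estimate TNT from")
  chan_rows <- list()
  # step 1: TNT from its own (simple) channels
  c_tnt_hat <- 0
  tnt_avg <- NULL
  if (length(tnt_keys)) {
    tnt_est <- do.call(rbind, lapply(tnt_keys, function(k) {
      invert_simple(models[[k]], abundances[[k]])
    }))
    tnt_avg <- average_channel_estimates(tnt_est)
    c_tnt_hat <- tnt_avg$estimate
    chan_rows[[length(chan_rows) + 1L]] <- tnt_est
  }
  # steps 2-3: remaining groups
  other_groups <- setdiff(unique(vapply(models, `[[`, character(1), "group")),
                          "TNT")
  out <- list()
  if (!is.null(tnt_avg)) out[["TNT"]] <- tnt_avg
  for (g in other_groups) {
    gkeys <- keys[vapply(models, function(m) m$group == g, logical(1))]
    est <- do.call(rbind, lapply(gkeys, function(k) {
      m <- models[[k]]
      if (m$kind == "interference") {
        val <- (abundances[[k]] - m$a - m$b_tnt * c_tnt_hat) / m$b_own
        data.frame(channel_mz = m$channel_mz, group = m$group,
                   estimate = val,
                   below_lod = !is.na(m$lod) && val < m$lod,
                   negative = val < 0, stringsAsFactors = FALSE)
      } else {
        invert_simple(m, abundances[[k]])
      }
    }))
    out[[g]] <- average_channel_estimates(est)
    chan_rows[[length(chan_rows) + 1L]] <- est
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "channels") <- do.call(rbind, chan_rows)
  res
}

#' Convert an extract concentration to a soil concentration
#'
#' `mg/kg = c_extract (ng/uL) x extract volume (mL) x dilution / soil mass
#' (g)` — the exact inverse of [soil_to_extract_concentration()]
#' (ng/uL = ug/mL, ug/g = mg/kg).
#'
#' @param c_extract Extract concentration (ng/uL).
#' @param soil_mass_g,extract_volume_ml,dilution_factor Extraction
#'   provenance (defaults 2 g, 4 mL, undiluted).
#' @return Soil concentration (mg/kg).
#' @examples
#' extract_to_soil_concentration(0.5, 2, 4) # 1 mg/kg
#' @export
extract_to_soil_concentration <- function(c_extract, soil_mass_g = 2,
                                          extract_volume_ml = 4,
                                          dilution_factor = 1) {
  if (soil_mass_g <= 0 || extract_volume_ml <= 0)
    stop("soil mass and extract volume must be > 0")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  c_extract * extract_volume_ml * dilution_factor / soil_mass_g
}

#' Summarize replicate estimates of one sample
#'
#' Mean, sample SD and RSD% of per-spot estimates per analyte group, with
#' optional deviation from a reference value (e.g. an LC-MS/MS
#' determination): `deviation% = 100 (estimate - reference) / reference`.
#'
#' @param estimates Data frame (spot, group, estimate) of per-spot
#'   estimates.
#' @param reference Optional named numeric vector of reference
#'   concentrations per group, in the same units as the estimates.
#' @return Data frame (group, n, mean, sd, rsd_pct, deviation_pct). With a
#'   single spot, SD and RSD are NA; RSD is reported only when the mean is
#'   positive.
#' @export
replicate_summary <- function(estimates, reference = NULL) {
  stopifnot(is.data.frame(estimates),
            all(c("spot", "group", "estimate") %in% names(estimates)))
  out <- do.call(rbind, lapply(split(estimates, estimates$group), function(d) {
    m <- mean(d$estimate)
    s <- if (nrow(d) > 1L) stats::sd(d$estimate) else NA_real_
    data.frame(group = d$group[1], n = nrow(d), mean = m, sd = s,
               rsd_pct = if (!is.na(s) && m > 0) 100 * s / m else NA_real_,
               deviation_pct = if (!is.null(reference) &&
                                     d$group[1] %in% names(reference))
                 100 * (m - reference[[d$group[1]]]) / reference[[d$group[1]]]
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Quantify one sample from its replicate spectra
#'
#' Full per-sample workflow: preprocess each spot (recalibrate, TIC
#' normalize, extract, IS-normalize), invert the calibration per spot
#' (`method = "simple"` inverts every channel's simple model;
#' `"sequential"` applies the TNT-then-ADNT interference correction),
#' average channels within each analyte group, then summarize across
#' spots. When extraction provenance is supplied the soil concentration is
#' reported alongside.
#'
#' @param spectra List of `mass_spectrum` objects (the spots of one
#'   sample).
#' @param models Calibration model set keyed by channel m/z.
#' @param channels Channel table for extraction (see
#'   [extract_ion_abundance()]).
#' @param method `"simple"` or `"sequential"`.
#' @param tolerance,references,is_mz Preprocessing parameters (see
#'   [spectra_to_abundance()]).
#' @param provenance Optional list (soil_mass_g, extract_volume_ml,
#'   dilution_factor) enabling soil-concentration reporting.
#' @param reference Optional named reference concentrations per group;
#'   either ng/uL extract (`reference_units = "extract"`) or mg/kg soil
#'   (`"soil"`, converted internally using `provenance`).
#' @param reference_units Units of `reference`.
#' @return A `quant_result` data frame: group, n, mean/sd/rsd_pct of the
#'   extract concentration (ng/uL), below_lod and negative flags,
#'   soil_mg_per_kg (if provenance given), deviation_pct (if reference
#'   given). Per-spot estimates are attached as attribute `"spots"`.
#' @export
quantify_sample <- function(spectra, models, channels,
                            method = c("simple", "sequential"),
                            tolerance = 0.5, references = c(216, 156, 157),
                            is_mz = 216,
                            provenance = NULL, reference = NULL,
                            reference_units = c("extract", "soil")) {
  method <- match.arg(method)
  reference_units <- match.arg(reference_units)
  ab <- spectra_to_abundance(spectra, channels, tolerance = tolerance,
                             references = references, is_mz = is_mz)
  if (length(unique(ab$sample_id)) != 1L)
    stop("quantify_sample expects the spots of one sample")
  spot_rows <- list()
  flags <- list()
  for (sp in unique(ab$spot)) {
    sub <- ab[ab$spot == sp & ab$group != "IS", ]
    abund <- stats::setNames(sub$normalized, as.character(sub$channel_mz))
    per_group <- if (method == "sequential") {
      invert_sequential(models, abund)
    } else {
      est <- do.call(rbind, lapply(names(models), function(k) {
        m <- models[[k]]
        if (m$kind == "interference") {
          # simple mode ignores the interference term deliberately
          val <- (abund[[k]] - m$a) / m$b_own
          data.frame(channel_mz = m$channel_mz, group = m$group,
                     estimate = val,
                     below_lod = !is.na(m$lod) && val < m$lod,
                     negative = val < 0, stringsAsFactors = FALSE)
        } else {
          invert_simple(m, abund[[k]])
        }
      }))
      res <- do.call(rbind, lapply(split(est, est$group),
                                   average_channel_estimates))
      rownames(res) <- NULL
      res
    }
    per_group$spot <- sp
    spot_rows[[length(spot_rows) + 1L]] <- per_group
  }
  spots <- do.call(rbind, spot_rows)
  ref_extract <- reference
  if (!is.null(reference) && reference_units == "soil") {
    if (is.null(provenance))
      stop("soil-unit references require extraction provenance")
    ref_extract <- soil_to_extract_concentration(
      reference, provenance$soil_mass_g, provenance$extract_volume_ml,
      provenance$dilution_factor %||% 1)
  }
  out <- replicate_summary(spots[c("spot", "group", "estimate")],
                           reference = ref_extract)
  # carry flags: a group is flagged if flagged in any spot
  out$below_lod <- vapply(out$group, function(g)
    any(spots$below_lod[spots$group == g]), logical(1))
  out$negative <- vapply(out$group, function(g)
    any(spots$negative[spots$group == g]), logical(1))
  if (!is.null(provenance)) {
    out$soil_mg_per_kg <- extract_to_soil_concentration(
      out$mean, provenance$soil_mass_g, provenance$extract_volume_ml,
      provenance$dilution_factor %||% 1)
  }
  out$sample_id <- ab$sample_id[1]
  out$method <- method
  attr(out, "spots") <- spots
  class(out) <- c("quant_result", "data.frame")
  out
}
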