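# Signal model: deterministic linear response of IS-normalized ion
# abundances to analyte concentration, plus the noise structure of spotted
# MALDI acquisition.

.default_channels <- function(registry = builtin_registry()) {
  # Per-channel response factors (normalized abundance per ng/uL) for the
  # channels the panel is quantified on. Radical anions respond more
  # strongly than the oxygen-loss fragments; NT ionizes poorly and gets the
  # lowest factor. TNB, DNB and NT are quantified on their molecular-anion
  # channel only: TNB's oxygen-loss fragment (m/z 197) would collide with
  # the ADNT radical anion, and the weak ionizers show no usable fragment.
  df <- data.frame(
    group = c("TNT", "TNT", "ADNT", "ADNT", "DNT", "DNT",
              "TNB", "DNB", "NT"),
    mz = c(227, 211, 197, 181, 182, 166, 213, 168, 137),
    kind = c("radical_anion", "oxygen_loss",
             "radical_anion", "oxygen_loss",
             "radical_anion", "oxygen_loss",
             "radical_anion", "radical_anion", "radical_anion"),
    response_factor = c(0.030, 0.020, 0.032, 0.018, 0.012, 0.008,
                        0.020, 0.010, 0.003),
    baseline_offset = 0,
    stringsAsFactors = FALSE)
  df$label <- sprintf("%s_%d", df$group, as.integer(df$mz))
  df
}

#' Construct a signal model for synthetic spectra
#'
#' Encodes the assumptions the downstream analysis relies on: each target
#' channel's IS-normalized abundance is linear in the concentration of its
#' own analyte (isomer-group total), the TNT concentration additionally
#' leaks into the ADNT channels (m/z 197 and 181, the documented
#' cross-interference), the internal standard at its nominal 25 ng/uL gives
#' a constant reference peak at m/z 216 (plus its fragment at 200), and the
#' DAN matrix contributes fixed peaks at m/z 156/157. Noise: a shared
#' lognormal multiplier per spot (crystallization/laser variability — the
#' component IS normalization cancels), an independent lognormal multiplier
#' per peak, a small half-normal additive baseline, and a global
#' per-spectrum mass shift.
#'
#' @param registry A `compound_registry`.
#' @param channels Data frame (group, mz, kind, response_factor,
#'   baseline_offset, label) of analyte channels. Defaults to the built-in
#'   nine-channel panel.
#' @param interference Data frame (mz, interferer, kappa): additional
#'   response of channel `mz` per ng/uL of the interfering analyte group.
#'   Default: TNT into the ADNT channels at 25% of their own response
#'   factors.
#' @param matrix_peaks Data frame (mz, height): DAN matrix ion heights
#'   relative to the IS peak.
#' @param is_fragment_height Height of the IS oxygen-loss fragment (m/z
#'   200) relative to the IS parent peak.
#' @param peak_width_sigma Gaussian peak sigma in Da.
#' @param spot_noise_cv CV of the shared per-spot multiplier.
#' @param channel_noise_cv CV of the independent per-peak multiplier.
#' @param baseline_noise_sd SD of the half-normal additive baseline, in
#'   intensity units (the IS peak height is `is_peak_height`).
#' @param mass_jitter_sd SD of the global per-spectrum mass shift (Da).
#' @param is_peak_height Absolute intensity of the IS peak at the nominal
#'   IS concentration (arbitrary instrument units; cancels under TIC
#'   normalization and IS referencing).
#' @param mz_range,mz_step Acquisition m/z window and grid step (Da).
#' @return A `signal_model` object.
#' @examples
#' m <- signal_model()
#' m$channels
#' @export
signal_model <- function(registry = builtin_registry(),
                         channels = .default_channels(registry),
                         interference = NULL,
                         matrix_peaks = data.frame(mz = c(156, 157),
                                                   height = c(0.8, 0.5)),
                         is_fragment_height = 0.5,
                         peak_width_sigma = 0.05,
                         spot_noise_cv = 0.08,
                         channel_noise_cv = 0.03,
                         baseline_noise_sd = 0.1,
                         mass_jitter_sd = 0.1,
                         is_peak_height = 1000,
                         mz_range = c(120, 300),
                         mz_step = 0.01) {
  if (is.null(interference)) {
    adnt <- channels[channels$group == "ADNT", ]
    interference <- data.frame(mz = adnt$mz, interferer = "TNT",
                               kappa = 0.25 * adnt$response_factor,
                               stringsAsFactors = FALSE)
  }
  stopifnot(all(channels$response_factor > 0),
            all(channels$baseline_offset >= 0),
            is.null(interference) || all(interference$kappa >= 0),
            peak_width_sigma > 0, spot_noise_cv >= 0, channel_noise_cv >= 0,
            baseline_noise_sd >= 0, mass_jitter_sd >= 0, is_peak_height > 0,
            mz_step > 0, length(mz_range) == 2L, mz_range[1] < mz_range[2])
  is_abbr <- registry$compounds$abbreviation[
    registry$compounds$role == "internal_standard"]
  is_ch <- registry$channels[registry$channels$abbreviation == is_abbr, ]
  structure(list(
    registry = registry,
    channels = channels,
    interference = interference,
    matrix_peaks = matrix_peaks,
    is_abbreviation = is_abbr,
    is_mz = is_ch$nominal_mz[is_ch$kind == "radical_anion"],
    is_fragment_mz = is_ch$nominal_mz[is_ch$kind == "oxygen_loss"],
    is_fragment_height = is_fragment_height,
    is_nominal_concentration = 25,
    peak_width_sigma = peak_width_sigma,
    spot_noise_cv = spot_noise_cv,
    channel_noise_cv = channel_noise_cv,
    baseline_noise_sd = baseline_noise_sd,
    mass_jitter_sd = mass_jitter_sd,
    is_peak_height = is_peak_height,
    mz_range = mz_range,
    mz_step = mz_step
  ), class = "signal_model")
}

#' @export
print.signal_model <- function(x, ...) {
  cat(sprintf(
    "<signal_model> %d analyte channels | IS %s at m/z %g | spot CV %.2g, peak CV %.2g\n",
    nrow(x$channels), x$is_abbreviation, x$is_mz,
    x$spot_noise_cv, x$channel_noise_cv))
  invisible(x)
}

#' Remove all stochastic components from a signal model
#'
#' Sets spot, per-peak, baseline and mass-jitter noise to zero; the forward
#' model then renders exactly the deterministic expected responses.
#'
#' @param model A `signal_model`.
#' @return The modified model.
#' @export
noiseless <- function(model) {
  model$spot_noise_cv <- 0
  model$channel_noise_cv <- 0
  model$baseline_noise_sd <- 0
  model$mass_jitter_sd <- 0
  model
}

#' Define the ground truth of one deposited sample
#'
#' @param concentrations Named numeric vector of analyte concentrations in
#'   the deposited solution (ng/uL). Names may be compound abbreviations
#'   (e.g. `"2-ADNT"`) or isomer-group labels (`"ADNT"`); members of a
#'   group are summed.
#' @param is_concentration Internal standard concentration (ng/uL),
#'   default 25.
#' @param sample_id Sample identifier.
#' @param soil_mass_g,extract_volume_ml,dilution_factor Optional extraction
#'   provenance for soil samples.
#' @return A `sample_truth` object.
#' @export
sample_truth <- function(concentrations = numeric(),
                         is_concentration = 25,
                         sample_id = "sample",
                         soil_mass_g = NULL, extract_volume_ml = NULL,
                         dilution_factor = 1) {
  if (length(concentrations) && is.null(names(concentrations)))
    stop("concentrations must be a named vector")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (is_concentration <= 0) stop("is_concentration must be > 0")
  structure(list(concentrations = concentrations,
                 is_concentration = is_concentration,
                 sample_id = sample_id,
                 soil_mass_g = soil_mass_g,
                 extract_volume_ml = extract_volume_ml,
                 dilution_factor = dilution_factor),
            class = "sample_truth")
}

# Resolve a truth's concentrations into isomer-group totals.
group_concentrations <- function(truth, registry) {
  conc <- truth$concentrations
  if (!length(conc)) return(stats::setNames(numeric(0), character(0)))
  groups <- isomer_group_of(names(conc), registry)
  tapply_res <- tapply(conc, groups, sum)
  stats::setNames(as.numeric(tapply_res), names(tapply_res))
}

#' Expected IS-normalized response of a channel
#'
#' The deterministic linear forward model: for channel \eqn{j},
#' \eqn{A_j = a_j + r_j c_{g(j)} + \sum_k \kappa_{jk} c_k}, where
#' \eqn{c_{g(j)}} is the isomer-group total concentration of the channel's
#' own analyte and the \eqn{\kappa} terms are cross-interferences (by
#' default TNT into the ADNT channels).
#'
#' @param truth A `sample_truth`.
#' @param model A `signal_model`.
#' @param channel Channel m/z (must be an analyte channel of the model, or
#'   the IS channel, which returns its defining value of 1 at the nominal
#'   IS concentration).
#' @return Expected normalized abundance (unitless, relative to the IS
#'   peak at its nominal concentration).
#' @export
expected_response <- function(truth, model, channel) {
  stopifnot(inherits(truth, "sample_truth"), inherits(model, "signal_model"))
  if (channel == model$is_mz)
    return(truth$is_concentration / model$is_nominal_concentration)
  i <- match(channel, model$channels$mz)
  if (is.na(i))
    stop(sprintf("unknown channel m/z %g", channel))
  gc <- group_concentrations(truth, model$registry)
  own <- model$channels$group[i]
  a <- model$channels$baseline_offset[i]
  r <- model$channels$response_factor[i]
  val <- a + r * (if (own %in% names(gc)) gc[[own]] else 0)
  intf <- model$interference
  if (!is.null(intf) && nrow(intf)) {
    rows <- intf[intf$mz == channel, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      g <- rows$interferer[k]
      if (g %in% names(gc)) val <- val + rows$kappa[k] * gc[[g]]
    }
  }
  unname(val)
}

#' Analyte quantification channels of a signal model
#'
#' @param model A `signal_model`.
#' @return Data frame with columns label, group, mz, kind.
#' @export
quant_channels <- function(model) {
  model$channels[c("label", "group", "mz", "kind")]
}
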