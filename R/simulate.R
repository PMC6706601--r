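# Forward simulator: renders seeded synthetic MALDI-TOF spectra and whole
# study designs (calibration series, interference grids, soil studies)
# with known ground truth.

# Add a Gaussian peak to an intensity vector on a uniform grid; only the
# +-6 sigma window is touched.
.add_peak <- function(intensity, grid, mu, height, sigma) {
  if (height <= 0) return(intensity)
  lo <- mu - 6 * sigma
  hi <- mu + 6 * sigma
  i1 <- max(1L, ceiling((lo - grid[1]) / (grid[2] - grid[1])) + 1L)
  i2 <- min(length(grid), floor((hi - grid[1]) / (grid[2] - grid[1])) + 1L)
  if (i1 > i2) return(intensity)
  idx <- i1:i2
  intensity[idx] <- intensity[idx] +
    height * exp(-((grid[idx] - mu)^2) / (2 * sigma^2))
  intensity
}

#' Render one synthetic spectrum
#'
#' Places Gaussian peaks (sigma = `model$peak_width_sigma`) at every active
#' channel: analyte channels at their deterministic [expected_response()]
#' scaled by the IS reference height, the internal standard at m/z 216 with
#' its fragment at 200, and the DAN matrix ions at 156/157. All peaks share
#' one lognormal per-spot multiplier and carry independent per-peak
#' multipliers; a global mass shift (sd `mass_jitter_sd`) displaces every
#' peak; a half-normal additive baseline is added. Reproducible for a fixed
#' seed.
#'
#' @param truth A [sample_truth()].
#' @param model A [signal_model()].
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param spot Spot replicate index stored in the metadata.
#' @return A `mass_spectrum`.
#' @examples
#' s <- render_spectrum(sample_truth(c(TNT = 10)), signal_model(), seed = 1)
#' @export
render_spectrum <- function(truth, model, seed = NULL, spot = 1L) {
  stopifnot(inherits(truth, "sample_truth"), inherits(model, "signal_model"))
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(model$mz_range[1], model$mz_range[2], by = model$mz_step)
  n_chan <- nrow(model$channels)
  n_matrix <- nrow(model$matrix_peaks)
  # fixed draw order: spot multiplier, mass shift, per-peak multipliers
  # (IS, IS fragment, matrix peaks, analyte channels), baseline
  spot_mult <- lognormal_multiplier(1L, model$spot_noise_cv)
  shift <- if (model$mass_jitter_sd > 0)
    stats::rnorm(1L, 0, model$mass_jitter_sd) else 0
  peak_mult <- lognormal_multiplier(2L + n_matrix + n_chan,
                                    model$channel_noise_cv)
  H <- model$is_peak_height
  # IS peak scales with the actual IS concentration relative to nominal
  h_is <- H * truth$is_concentration / model$is_nominal_concentration
  intensity <- if (model$baseline_noise_sd > 0)
    abs(stats::rnorm(length(grid), 0, model$baseline_noise_sd))
  else numeric(length(grid))
  sigma <- model$peak_width_sigma
  intensity <- .add_peak(intensity, grid, model$is_mz + shift,
                         h_is * spot_mult * peak_mult[1L], sigma)
  intensity <- .add_peak(intensity, grid, model$is_fragment_mz + shift,
                         h_is * model$is_fragment_height * spot_mult *
                           peak_mult[2L], sigma)
  for (k in seq_len(n_matrix)) {
    intensity <- .add_peak(intensity, grid, model$matrix_peaks$mz[k] + shift,
                           H * model$matrix_peaks$height[k] * spot_mult *
                             peak_mult[2L + k], sigma)
  }
  for (j in seq_len(n_chan)) {
    A <- expected_response(truth, model, model$channels$mz[j])
    intensity <- .add_peak(intensity, grid, model$channels$mz[j] + shift,
                           A * H * spot_mult * peak_mult[2L + n_matrix + j],
                           sigma)
  }
  mass_spectrum(grid, intensity, sample_id = truth$sample_id, spot = spot,
                seed = seed %||% NA_integer_)
}

#' Simulate a replicate set of spots for one sample
#'
#' Renders `n_spots` spectra of the same deposited solution with
#' independent spot multipliers; per-spot seeds are derived
#' deterministically from the master seed.
#'
#' @inheritParams render_spectrum
#' @param n_spots Number of target spots (default 3, the standard
#'   triplicate deposition).
#' @return List of `mass_spectrum` objects.
#' @export
simulate_replicate_set <- function(truth, model, n_spots = 3L, seed = 1L) {
  if (n_spots < 1L) stop("n_spots must be >= 1")
  lapply(seq_len(n_spots), function(i) {
    render_spectrum(truth, model, seed = derive_seed(seed, i), spot = i)
  })
}

#' Simulate a calibration series
#'
#' One replicate set per concentration level; at each level every analyte
#' group in the model is present at that level (a standard mixture diluted
#' as a whole), with the internal standard constant at 25 ng/uL. The
#' default levels span 0 (blank) to 75 ng/uL.
#'
#' @param levels Concentration levels in ng/uL; must include 0 (blank).
#' @param model A [signal_model()].
#' @param n_spots Spots per level.
#' @param seed Master seed.
#' @param analytes Analyte group labels to include; defaults to every
#'   group in the model's channel table.
#' @return List with `spectra` (flat list of `mass_spectrum`), `design`
#'   (data frame: sample_id, level, analyte, concentration) and `truths`.
#' @export
simulate_calibration_series <- function(levels = c(0, 1, 5, 10, 25, 50, 75),
                                        model = signal_model(),
                                        n_spots = 3L, seed = 1L,
                                        analytes = NULL) {
  if (!length(levels)) stop("empty level list")
  if (any(levels < 0)) stop("levels must be >= 0")
  analytes <- analytes %||% unique(model$channels$group)
  spectra <- list()
  design <- list()
  truths <- list()
  for (k in seq_along(levels)) {
    L <- levels[k]
    id <- sprintf("cal_%02d", k)
    truth <- sample_truth(stats::setNames(rep(L, length(analytes)), analytes),
                          sample_id = id)
    reps <- simulate_replicate_set(truth, model, n_spots,
                                   seed = derive_seed(seed, 100L + k))
    spectra <- c(spectra, reps)
    design[[k]] <- data.frame(sample_id = id, level = L, analyte = analytes,
                              concentration = L, stringsAsFactors = FALSE)
    truths[[id]] <- truth
  }
  list(spectra = spectra, design = do.call(rbind, design), truths = truths)
}

#' Simulate a TNT x ADNT interference calibration grid
#'
#' Full cross of TNT and ADNT levels (default 4 x 4), the design used to
#' fit the bivariate interference calibration of the ADNT channels.
#'
#' @param tnt_levels,adnt_levels Concentration levels (ng/uL).
#' @param model A [signal_model()].
#' @param n_spots Spots per grid point.
#' @param seed Master seed.
#' @return List with `spectra`, `design` (sample_id, c_tnt, c_adnt) and
#'   `truths`.
#' @export
simulate_interference_grid <- function(tnt_levels = c(0, 5, 25, 75),
                                       adnt_levels = c(0, 5, 25, 75),
                                       model = signal_model(),
                                       n_spots = 3L, seed = 1L) {
  spectra <- list()
  design <- list()
  truths <- list()
  k <- 0L
  for (t in tnt_levels) for (a in adnt_levels) {
    k <- k + 1L
    id <- sprintf("grid_%02d", k)
    truth <- sample_truth(c(TNT = t, ADNT = a), sample_id = id)
    reps <- simulate_replicate_set(truth, model, n_spots,
                                   seed = derive_seed(seed, 500L + k))
    spectra <- c(spectra, reps)
    design[[k]] <- data.frame(sample_id = id, c_tnt = t, c_adnt = a,
                              stringsAsFactors = FALSE)
    truths[[id]] <- truth
  }
  list(spectra = spectra, design = do.call(rbind, design), truths = truths)
}

#' Convert a soil concentration to the extract concentration
#'
#' Unit bookkeeping for the standard extraction (2 g soil shaken in 4 mL
#' solvent): mg/kg soil x soil mass (g) / extract volume (mL) / dilution =
#' ng/uL extract (mg/kg = ug/g and ng/uL = ug/mL).
#'
#' @param c_soil Soil concentration (mg/kg).
#' @param soil_mass_g Extracted soil mass (g).
#' @param extract_volume_ml Extraction solvent volume (mL).
#' @param dilution_factor Dilution applied to the extract before spotting
#'   (>= 1).
#' @return Extract concentration (ng/uL).
#' @examples
#' soil_to_extract_concentration(1, 2, 4) # 0.5 ng/uL
#' @export
soil_to_extract_concentration <- function(c_soil, soil_mass_g = 2,
                                          extract_volume_ml = 4,
                                          dilution_factor = 1) {
  if (soil_mass_g <= 0 || extract_volume_ml <= 0)
    stop("soil mass and extract volume must be > 0")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  c_soil * soil_mass_g / extract_volume_ml / dilution_factor
}

#' Simulate a soil contamination study
#'
#' Converts per-sample soil truths (mg/kg) to extract concentrations via
#' the extraction parameters, renders triplicate spectra of each extract,
#' and returns a truth sidecar recording both scales.
#'
#' @param soil_truths Named list: sample id -> named vector of soil
#'   concentrations in mg/kg per analyte (group).
#' @param soil_mass_g,extract_volume_ml,dilution_factor Extraction
#'   parameters (defaults: 2 g, 4 mL, undiluted).
#' @param model A [signal_model()].
#' @param n_spots Spots per sample.
#' @param seed Master seed.
#' @return List with `spectra`, `truths` and `sidecar` (data frame:
#'   sample_id, analyte, soil_mg_per_kg, extract_ng_per_ul, seed).
#' @export
simulate_soil_study <- function(soil_truths,
                                soil_mass_g = 2, extract_volume_ml = 4,
                                dilution_factor = 1,
                                model = signal_model(),
                                n_spots = 3L, seed = 1L) {
  stopifnot(is.list(soil_truths), length(soil_truths) >= 1L,
            !is.null(names(soil_truths)))
  spectra <- list()
  truths <- list()
  sidecar <- list()
  for (k in seq_along(soil_truths)) {
    id <- names(soil_truths)[k]
    soil <- soil_truths[[k]]
    if (any(soil < 0)) stop("soil concentrations must be >= 0")
    extract <- soil_to_extract_concentration(soil, soil_mass_g,
                                             extract_volume_ml,
                                             dilution_factor)
    sample_seed <- derive_seed(seed, 900L + k)
    truth <- sample_truth(extract, sample_id = id,
                          soil_mass_g = soil_mass_g,
                          extract_volume_ml = extract_volume_ml,
                          dilution_factor = dilution_factor)
    spectra <- c(spectra,
                 simulate_replicate_set(truth, model, n_spots,
                                        seed = sample_seed))
    truths[[id]] <- truth
    sidecar[[k]] <- data.frame(sample_id = id, analyte = names(soil),
                               soil_mg_per_kg = as.numeric(soil),
                               extract_ng_per_ul = as.numeric(extract),
                               seed = sample_seed, stringsAsFactors = FALSE)
  }
  list(spectra = spectra, truths = truths,
       sidecar = do.call(rbind, sidecar))
}
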