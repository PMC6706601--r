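# Shared fixtures, built once per run and memoized. All simulations are
# seeded; fixtures are deterministic.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env, inherits = FALSE)
}

# noiseless default model (TNT -> ADNT interference active)
nf_model <- function() get_fixture("nf_model", function() {
  noiseless(signal_model())
})

# noiseless model without any cross-interference
nf_model_k0 <- function() get_fixture("nf_model_k0", function() {
  noiseless(signal_model(interference = data.frame(
    mz = numeric(0), interferer = character(0), kappa = numeric(0))))
})

# simple calibration set fitted on a noiseless series (kappa = 0 model)
nf_models_k0 <- function() get_fixture("nf_models_k0", function() {
  m <- nf_model_k0()
  cal <- simulate_calibration_series(model = m, seed = 101)
  ab <- spectra_to_abundance(cal$spectra, quant_channels(m))
  fit_calibration_set(ab, cal$design)
})

# calibration set under the default (kappa > 0) noiseless model:
# simple models for every channel, ADNT channels refitted on an
# interference grid
nf_models_seq <- function() get_fixture("nf_models_seq", function() {
  m <- nf_model()
  cal <- simulate_calibration_series(model = m, seed = 101)
  ab <- spectra_to_abundance(cal$spectra, quant_channels(m))
  models <- fit_calibration_set(ab, cal$design)
  grid <- simulate_interference_grid(model = m, seed = 102)
  gab <- spectra_to_abundance(grid$spectra, quant_channels(m))
  fit_interference_set(models, gab, grid$design)
})

# simple-only calibration set under the default noiseless model (used to
# demonstrate the interference bias of the simple route)
nf_models_simple <- function() get_fixture("nf_models_simple", function() {
  m <- nf_model()
  cal <- simulate_calibration_series(model = m, seed = 101)
  ab <- spectra_to_abundance(cal$spectra, quant_channels(m))
  fit_calibration_set(ab, cal$design)
})

# default-noise study conditions: calibration series + interference grid
# at the default noise model (spot CV 0.08, per-peak CV 0.03)
noisy_models <- function() get_fixture("noisy_models", function() {
  m <- signal_model()
  cal <- simulate_calibration_series(model = m, seed = 201)
  ab <- spectra_to_abundance(cal$spectra, quant_channels(m))
  models <- fit_calibration_set(ab, cal$design)
  grid <- simulate_interference_grid(model = m, seed = 202)
  gab <- spectra_to_abundance(grid$spectra, quant_channels(m))
  fit_interference_set(models, gab, grid$design)
})
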