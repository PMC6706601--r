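test_that("expected response is linear with baseline and interference terms", {
  m <- signal_model()
  # zero concentration -> baseline offset (0 by default)
  blank <- sample_truth()
  for (mz in m$channels$mz) expect_equal(expected_response(blank, m, mz), 0)
  # custom offset shows through at zero concentration
  ch <- nitroquant:::.default_channels()
  ch$baseline_offset <- 0.002
  m2 <- signal_model(channels = ch)
  expect_equal(expected_response(blank, m2, 227), 0.002)
  # direct linear arithmetic: r = 0.02, a = 0, kappa = 0, c_TNT = 10
  ch3 <- ch
  ch3$baseline_offset <- 0
  ch3$response_factor[ch3$mz == 227] <- 0.02
  m3 <- signal_model(channels = ch3, interference = data.frame(
    mz = numeric(0), interferer = character(0), kappa = numeric(0)))
  expect_equal(expected_response(sample_truth(c(TNT = 10)), m3, 227), 0.2)
  # interference: A(197) = a + kappa * c_TNT with c_ADNT = 0
  m4 <- signal_model(interference = data.frame(mz = 197, interferer = "TNT",
                                               kappa = 0.005))
  expect_equal(expected_response(sample_truth(c(TNT = 20)), m4, 197), 0.1)
  expect_error(expected_response(blank, m, 999), "unknown channel")
})

test_that("isomer-group members contribute their summed concentration", {
  m <- signal_model()
  t_members <- sample_truth(c(`2-ADNT` = 3, `4-ADNT` = 4))
  t_group <- sample_truth(c(ADNT = 7))
  expect_equal(expected_response(t_members, m, 197),
               expected_response(t_group, m, 197))
})

test_that("noise-free rendering places apexes exactly on the channel grid", {
  m <- nf_model()
  s <- render_spectrum(sample_truth(c(TNT = 10), sample_id = "t"), m, seed = 1)
  for (mu in c(227, 211, 216, 200, 156, 157)) {
    i <- which.min(abs(s$mz - mu))
    # local maximum exactly at the nominal position
    expect_gt(s$intensity[i], s$intensity[i - 1])
    expect_gte(s$intensity[i], s$intensity[i + 1])
  }
  # peak height encodes the expected response relative to the IS peak
  h227 <- max(s$intensity[abs(s$mz - 227) < 0.5])
  h216 <- max(s$intensity[abs(s$mz - 216) < 0.5])
  expect_equal(h227 / h216, expected_response(sample_truth(c(TNT = 10)), m, 227),
               tolerance = 1e-12)
})

test_that("rendering is deterministic in the seed", {
  m <- signal_model()
  tr <- sample_truth(c(TNT = 5, ADNT = 2))
  s1 <- render_spectrum(tr, m, seed = 42)
  s2 <- render_spectrum(tr, m, seed = 42)
  expect_identical(s1$intensity, s2$intensity)
  s3 <- render_spectrum(tr, m, seed = 43)
  expect_false(identical(s1$intensity, s3$intensity))
})

test_that("replicate sets have distinct spots with derived seeds", {
  m <- signal_model()
  tr <- sample_truth(c(TNT = 5))
  reps <- simulate_replicate_set(tr, m, n_spots = 3, seed = 7)
  expect_length(reps, 3)
  expect_identical(vapply(reps, function(s) s$metadata$spot, integer(1)), 1:3)
  # different spots differ; different master seeds differ
  expect_false(identical(reps[[1]]$intensity, reps[[2]]$intensity))
  reps2 <- simulate_replicate_set(tr, m, n_spots = 3, seed = 8)
  expect_false(identical(reps[[1]]$intensity, reps2[[1]]$intensity))
  # reproducible
  reps3 <- simulate_replicate_set(tr, m, n_spots = 3, seed = 7)
  expect_identical(reps[[2]]$intensity, reps3[[2]]$intensity)
  expect_error(simulate_replicate_set(tr, m, n_spots = 0, seed = 1), "n_spots")
  # a single noise-free spot equals a direct render
  m0 <- nf_model()
  one <- simulate_replicate_set(tr, m0, n_spots = 1, seed = 3)[[1]]
  expect_equal(one$intensity, render_spectrum(tr, m0, seed = 99)$intensity)
})

test_that("spectrum total intensity scales linearly with the shared multiplier", {
  # the spot multiplier scales every peak; doubling the common intensity
  # scale doubles the TIC
  tr <- sample_truth(c(TNT = 10, ADNT = 5))
  m1 <- noiseless(signal_model(is_peak_height = 1000))
  m2 <- noiseless(signal_model(is_peak_height = 2000))
  s1 <- render_spectrum(tr, m1, seed = 1)
  s2 <- render_spectrum(tr, m2, seed = 1)
  expect_equal(s2$intensity, 2 * s1$intensity, tolerance = 1e-12)
})

test_that("raw IS abundance variability matches the closed-form noise model", {
  # product of independent lognormals: CV = sqrt((1+cv_s^2)(1+cv_c^2) - 1)
  m <- signal_model(spot_noise_cv = 0.2, channel_noise_cv = 0.05,
                    baseline_noise_sd = 0, mass_jitter_sd = 0)
  tr <- sample_truth(c(TNT = 10))
  raw_is <- vapply(1:1000, function(i) {
    s <- render_spectrum(tr, m, seed = i)
    max(s$intensity[abs(s$mz - 216) < 0.5])
  }, numeric(1))
  cv_obs <- stats::sd(raw_is) / mean(raw_is)
  cv_exp <- sqrt((1 + 0.2^2) * (1 + 0.05^2) - 1)
  expect_lt(abs(cv_obs - cv_exp) / cv_exp, 0.2)
})

test_that("IS normalization cancels the shared spot variability", {
  m <- signal_model(spot_noise_cv = 0.2, channel_noise_cv = 0.02,
                    baseline_noise_sd = 0, mass_jitter_sd = 0)
  tr <- sample_truth(c(TNT = 25))
  raw <- norm <- numeric(200)
  for (i in 1:200) {
    s <- render_spectrum(tr, m, seed = 5000 + i)
    h227 <- max(s$intensity[abs(s$mz - 227) < 0.5])
    h216 <- max(s$intensity[abs(s$mz - 216) < 0.5])
    raw[i] <- h227
    norm[i] <- h227 / h216
  }
  cv_raw <- stats::sd(raw) / mean(raw)
  cv_norm <- stats::sd(norm) / mean(norm)
  expect_lt(cv_norm * 3, cv_raw)
})

test_that("calibration series covers the design with a constant IS", {
  m <- nf_model()
  sim <- simulate_calibration_series(model = m, n_spots = 3, seed = 9)
  expect_length(sim$spectra, 7 * 3)
  expect_setequal(unique(sim$design$level), c(0, 1, 5, 10, 25, 50, 75))
  # design bookkeeping: ADNT concentration at level L is the group total L
  adnt <- sim$design[sim$design$analyte == "ADNT", ]
  expect_equal(adnt$concentration, adnt$level)
  expect_true(all(vapply(sim$truths, function(t) t$is_concentration == 25,
                         logical(1))))
  # blank spectra contain only matrix + IS peaks
  blank <- sim$spectra[[1]]
  pk <- detect_peaks(blank)
  expect_setequal(round(pk$mz), c(156, 157, 200, 216))
  expect_error(simulate_calibration_series(levels = numeric(0), model = m),
               "empty")
})

test_that("soil-to-extract unit bookkeeping is exact and invertible", {
  expect_equal(soil_to_extract_concentration(1, 2, 4, 1), 0.5)
  expect_equal(soil_to_extract_concentration(500, 2, 4, 10), 25)
  expect_equal(soil_to_extract_concentration(0, 2, 4, 1), 0)
  expect_error(soil_to_extract_concentration(1, 0, 4), "must be > 0")
  # inverse composition is the identity
  for (c_soil in c(0.3, 1, 17.5, 500)) {
    expect_equal(soil_to_extract_concentration(
      extract_to_soil_concentration(c_soil, 2, 4, 3), 2, 4, 3),
      c_soil, tolerance = 1e-12)
  }
})

test_that("soil study renders extracts at the converted concentrations", {
  m <- nf_model()
  sim <- simulate_soil_study(list(a = c(TNT = 1), b = c(TNT = 0)),
                             model = m, n_spots = 2, seed = 4)
  expect_equal(sim$truths$a$concentrations[["TNT"]], 0.5)
  expect_equal(sim$sidecar$extract_ng_per_ul[sim$sidecar$sample_id == "a"], 0.5)
  # zero soil concentration -> blank-equivalent spectrum
  blank_like <- sim$spectra[[3]]
  pk <- detect_peaks(blank_like)
  expect_setequal(round(pk$mz), c(156, 157, 200, 216))
})
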