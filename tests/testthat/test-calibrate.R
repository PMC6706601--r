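test_that("simple calibration recovers an exact line", {
  m <- fit_simple_calibration(c(1, 2, 3), c(2, 4, 6), channel_mz = 227)
  expect_equal(m$b_own, 2, tolerance = 1e-12)
  expect_equal(m$a, 0, tolerance = 1e-12)
  expect_equal(m$r2, 1)
  expect_equal(m$range, c(1, 3))
  expect_error(fit_simple_calibration(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_simple_calibration(c(2, 2, 2), c(1, 2, 3)),
               "variance|distinct")
})

test_that("noise-free simulated series recovers the generating coefficients", {
  ch <- nitroquant:::.default_channels()
  ch$response_factor[ch$mz == 227] <- 0.02
  ch$baseline_offset[ch$mz == 227] <- 0.001
  m0 <- noiseless(signal_model(channels = ch, interference = data.frame(
    mz = numeric(0), interferer = character(0), kappa = numeric(0))))
  sim <- simulate_calibration_series(model = m0, seed = 11)
  ab <- spectra_to_abundance(sim$spectra, quant_channels(m0))
  models <- fit_calibration_set(ab, sim$design)
  m227 <- models[["227"]]
  expect_equal(m227$b_own, 0.02, tolerance = 1e-8)
  expect_equal(m227$a, 0.001, tolerance = 1e-8)
  expect_gt(m227$r2, 1 - 1e-10)
})

test_that("constant response degrades to a flagged degenerate model", {
  m <- fit_simple_calibration(c(0, 1, 5, 10), rep(0.3, 4))
  expect_equal(m$b_own, 0, tolerance = 1e-12)
  expect_equal(m$r2, 0)
  expect_true(m$lod_undefined)
})

test_that("interference calibration recovers a bivariate forward model", {
  grid <- expand.grid(cA = c(0, 5, 25, 75), cT = c(0, 5, 25, 75))
  A <- 0.10 + 0.020 * grid$cA + 0.005 * grid$cT
  m <- fit_interference_calibration(grid$cA, grid$cT, A, channel_mz = 197)
  expect_equal(m$a, 0.10, tolerance = 1e-10)
  expect_equal(m$b_own, 0.020, tolerance = 1e-10)
  expect_equal(m$b_tnt, 0.005, tolerance = 1e-10)
  # kappa = 0 data: interference coefficient vanishes, own slope matches
  # the simple fit
  A0 <- 0.10 + 0.020 * grid$cA
  m0 <- fit_interference_calibration(grid$cA, grid$cT, A0)
  expect_lt(abs(m0$b_tnt), 1e-8)
  ms <- fit_simple_calibration(grid$cA, A0)
  expect_equal(m0$b_own, ms$b_own, tolerance = 1e-10)
  # collinear design is rejected by name
  expect_error(fit_interference_calibration(1:8, 2 * (1:8), rnorm(8)),
               "collinear")
  expect_error(fit_interference_calibration(1:4, c(1, 2, 1, 2), rnorm(4)),
               ">= 6")
})

test_that("TNT channel shows no dependence on ADNT concentration", {
  # fit the TNT radical-anion channel on the full interference grid with
  # ADNT as the candidate interferer: its coefficient is null
  m <- nf_model()
  grid <- simulate_interference_grid(model = m, n_spots = 1, seed = 21)
  ab <- spectra_to_abundance(grid$spectra, quant_channels(m))
  sub <- ab[ab$channel_mz == 227, ]
  idx <- match(sub$sample_id, grid$design$sample_id)
  fit <- fit_interference_calibration(c_own = grid$design$c_tnt[idx],
                                      c_tnt = grid$design$c_adnt[idx],
                                      abundance = sub$normalized,
                                      channel_mz = 227)
  expect_lt(abs(fit$b_tnt), 1e-8)
  expect_equal(fit$b_own, 0.030, tolerance = 1e-6)
})

test_that("coefficients match the normal-equation oracle", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    x <- runif(n, 0, 50)
    y <- 0.3 + 0.02 * x + rnorm(n, 0, 0.05)
    m <- fit_simple_calibration(x, y)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(c(m$a, m$b_own), as.numeric(beta), tolerance = 1e-9)
  }
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    x1 <- runif(n, 0, 50); x2 <- runif(n, 0, 50)
    y <- 0.1 + 0.02 * x1 + 0.005 * x2 + rnorm(n, 0, 0.05)
    m <- fit_interference_calibration(x1, x2, y)
    X <- cbind(1, x1, x2)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(c(m$a, m$b_own, m$b_tnt), as.numeric(beta), tolerance = 1e-9)
  }
})

test_that("LOD follows the 3.3 sigma / slope rule", {
  m <- fit_simple_calibration(c(1, 2, 3), c(2, 4, 6))
  m$resid_sd <- 0.1
  m$b_own <- 1.0
  expect_equal(estimate_lod(m), 0.33)
  # noise-free limit
  m2 <- fit_simple_calibration(c(1, 2, 3), c(2, 4, 6))
  expect_equal(estimate_lod(m2), 0, tolerance = 1e-12)
  m$b_own <- -1
  expect_error(estimate_lod(m), "positive")
  # simulated default-noise series: LOD positive, at or below the lowest
  # calibration level's order of magnitude, and equal to the formula
  models <- noisy_models()
  m227 <- models[["227"]]
  expect_gt(m227$lod, 0)
  expect_lt(m227$lod, 10)  # lowest nonzero level is 1 ng/uL
  expect_equal(m227$lod, 3.3 * m227$resid_sd / m227$b_own, tolerance = 1e-12)
})

test_that("R-squared stays in [0,1] and residual SD grows with noise", {
  # Monte-Carlo on directly generated normalized abundances (the response
  # model plus per-peak lognormal noise), 50 reps per noise level
  levels <- c(0, 1, 5, 10, 25, 50, 75)
  r <- 0.03
  med_sd <- vapply(c(0.01, 0.05, 0.15), function(cv) {
    sds <- vapply(1:50, function(i) {
      set.seed(3000 + i + round(cv * 1e4))
      A <- r * levels * nitroquant:::lognormal_multiplier(length(levels), cv)
      m <- fit_simple_calibration(levels, A)
      expect_gte(m$r2, 0); expect_lte(m$r2, 1)
      m$resid_sd
    }, numeric(1))
    stats::median(sds)
  }, numeric(1))
  expect_true(all(diff(med_sd) > 0))
})

test_that("calibration tables serialize and deserialize", {
  models <- nf_models_seq()
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- calibration_table(models, path)
  expect_true(all(c("simple", "interference") %in% tab$kind))
  back <- read_calibration_table(path)
  expect_setequal(names(back), names(models))
  m1 <- models[["197"]]; m2 <- back[["197"]]
  expect_equal(m2$b_own, m1$b_own, tolerance = 1e-12)
  expect_equal(m2$b_tnt, m1$b_tnt, tolerance = 1e-12)
  expect_identical(m2$kind, "interference")
})
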