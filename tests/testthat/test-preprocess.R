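test_that("TIC normalization sums to one, is idempotent and scale-invariant", {
  s <- mass_spectrum(seq(120, 121, 0.01), rep(2, 101))
  n1 <- tic_normalize(s)
  expect_equal(sum(n1$intensity), 1)
  expect_equal(tic_normalize(n1)$intensity, n1$intensity)
  s2 <- s; s2$intensity <- 7.3 * s$intensity
  expect_equal(tic_normalize(s2)$intensity, n1$intensity)
  # two-point arithmetic
  tp <- mass_spectrum(c(120, 120.01), c(3, 1))
  expect_equal(tic_normalize(tp)$intensity, c(0.75, 0.25))
  z <- mass_spectrum(c(120, 120.01), c(0, 0))
  expect_error(tic_normalize(z), "all-zero")
})

test_that("mass recalibration corrects a known constant shift", {
  m <- nf_model()
  s <- render_spectrum(sample_truth(c(TNT = 20), sample_id = "t"), m, seed = 1)
  # displace every peak by exactly +0.30 Da (30 grid steps)
  shifted <- s
  shifted$intensity <- c(rep(0, 30), s$intensity[1:(length(s$intensity) - 30)])
  rec <- recalibrate_mass_axis(shifted, references = c(216, 156, 157))
  info <- attr(rec, "recalibration")
  expect_equal(info$shift, 0.30, tolerance = 0.01)
  # post-alignment apex error at the IS channel <= 0.02 Da
  i <- which(abs(rec$mz - 216) < 0.5)
  apex <- rec$mz[i[which.max(rec$intensity[i])]]
  expect_lt(abs(apex - 216), 0.02)
})

test_that("recalibration with zero shift leaves the spectrum unchanged", {
  m <- nf_model()
  s <- render_spectrum(sample_truth(c(TNT = 20), sample_id = "t"), m, seed = 1)
  rec <- recalibrate_mass_axis(s)
  expect_equal(rec$intensity, s$intensity, tolerance = 1e-9)
  expect_identical(rec$mz, s$mz)
})

test_that("recalibration fails loudly when no reference is present", {
  grid <- seq(120, 300, 0.01)
  int <- numeric(length(grid))
  int[abs(grid - 250) < 0.2] <- exp(-((grid[abs(grid - 250) < 0.2] - 250)^2) /
                                      (2 * 0.05^2))
  s <- mass_spectrum(grid, int)
  expect_error(recalibrate_mass_axis(s, references = c(216, 156)),
               "no reference matched")
})

test_that("peak detection finds the targeted channels of a TNT spectrum", {
  m <- nf_model_k0()
  s <- render_spectrum(sample_truth(c(TNT = 20), sample_id = "t"), m, seed = 1)
  pk <- detect_peaks(s)
  expect_setequal(round(pk$mz), c(227, 211, 216, 200, 156, 157))
  expect_true(all(abs(pk$mz - round(pk$mz)) < 0.005))
  # flat spectrum yields nothing
  flat <- mass_spectrum(seq(120, 130, 0.01), rep(0, 1001))
  expect_identical(nrow(detect_peaks(flat)), 0L)
})

test_that("quadratic apex interpolation matches the brute-force oracle", {
  # exact Gaussian sampled on the grid, apex off-grid
  grid <- seq(190, 210, 0.01)
  mu <- 200.0037
  int <- 5 * exp(-((grid - mu)^2) / (2 * 0.05^2))
  s <- mass_spectrum(grid, int)
  pk <- detect_peaks(s)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$mz - mu), 0.005)
  # independent oracle: argmax plus parabola through the three top points
  i <- which.max(int)
  y0 <- int[i - 1]; y1 <- int[i]; y2 <- int[i + 1]
  oracle <- grid[i] + 0.5 * (y0 - y2) / (y0 - 2 * y1 + y2) * 0.01
  expect_equal(pk$mz, oracle, tolerance = 1e-12)
  # oracle agreement across a rendered multi-peak fixture
  m <- nf_model()
  sp <- render_spectrum(sample_truth(c(TNT = 20, ADNT = 10), sample_id = "t"),
                        m, seed = 1)
  pks <- detect_peaks(sp)
  for (k in seq_len(nrow(pks))) {
    sel <- which(abs(sp$mz - pks$mz[k]) < 0.4)
    i <- sel[which.max(sp$intensity[sel])]
    y0 <- sp$intensity[i - 1]; y1 <- sp$intensity[i]; y2 <- sp$intensity[i + 1]
    oracle <- sp$mz[i] + 0.5 * (y0 - y2) / (y0 - 2 * y1 + y2) * 0.01
    expect_equal(pks$mz[k], oracle, tolerance = 1e-9)
  }
})

test_that("targeted extraction normalizes to the internal standard", {
  # constructed spectrum with A(227)/A(216) = 0.4 exactly
  grid <- seq(120, 300, 0.01)
  int <- numeric(length(grid))
  for (p in list(c(216, 1.0), c(227, 0.4))) {
    sel <- abs(grid - p[1]) < 0.3
    int[sel] <- int[sel] + p[2] * exp(-((grid[sel] - p[1])^2) / (2 * 0.05^2))
  }
  s <- tic_normalize(mass_spectrum(grid, int, sample_id = "x"))
  ch <- data.frame(mz = 227, label = "TNT_227", group = "TNT")
  tab <- extract_ion_abundance(s, ch)
  expect_equal(tab$normalized[tab$channel_mz == 227], 0.4, tolerance = 1e-6)
  # IS channel normalizes to exactly 1
  expect_identical(tab$normalized[tab$channel_mz == 216], 1)
  # delegation alias returns bit-identical results
  expect_identical(normalize_to_internal_standard(s, ch), tab)
})

test_that("normalized abundances are invariant under global intensity scaling", {
  m <- nf_model()
  s <- render_spectrum(sample_truth(c(TNT = 20), sample_id = "t"), m, seed = 1)
  ch <- quant_channels(m)
  t1 <- extract_ion_abundance(tic_normalize(s), ch)
  s2 <- s; s2$intensity <- 3.7 * s$intensity
  t2 <- extract_ion_abundance(tic_normalize(s2), ch)
  expect_equal(t1$normalized, t2$normalized, tolerance = 1e-12)
})

test_that("extraction errors when the internal standard is undetectable", {
  grid <- seq(120, 300, 0.01)
  int <- numeric(length(grid))
  sel <- abs(grid - 250) < 0.3
  int[sel] <- exp(-((grid[sel] - 250)^2) / (2 * 0.05^2))
  s <- tic_normalize(mass_spectrum(grid, int, sample_id = "x"))
  expect_error(extract_ion_abundance(s, data.frame(mz = 227, label = "a",
                                                   group = "TNT")),
               "internal standard")
})

test_that("extraction is monotone in the true channel response", {
  m <- nf_model()
  ch <- quant_channels(m)
  vals <- vapply(c(1, 5, 10, 50), function(conc) {
    s <- render_spectrum(sample_truth(c(TNT = conc), sample_id = "t"), m)
    tab <- extract_ion_abundance(tic_normalize(s), ch)
    tab$normalized[tab$channel_mz == 227]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("replicate averaging returns mean, SD and n per channel", {
  rows <- data.frame(sample_id = "s", spot = 1:3, channel_mz = 227,
                     channel_label = "TNT_227", group = "TNT",
                     raw = c(9, 10, 11) / 100,
                     normalized = c(0.9, 1.0, 1.1))
  avg <- average_replicates(rows)
  expect_equal(avg$mean_normalized, 1.0)
  expect_equal(avg$sd_normalized, 0.1)
  expect_identical(avg$n, 3L)
  # identical spots -> zero SD
  rows0 <- rows; rows0$normalized <- 0.5
  expect_equal(average_replicates(rows0)$sd_normalized, 0)
  rows$sample_id <- c("a", "a", "b")
  expect_error(average_replicates(rows), "single sample")
})

test_that("processing order (recalibrate vs TIC first) does not change abundances", {
  m <- signal_model(spot_noise_cv = 0, channel_noise_cv = 0,
                    baseline_noise_sd = 0, mass_jitter_sd = 0.1)
  s <- render_spectrum(sample_truth(c(TNT = 20), sample_id = "t"), m, seed = 3)
  ch <- quant_channels(m)
  a <- extract_ion_abundance(tic_normalize(recalibrate_mass_axis(s)), ch)
  b <- extract_ion_abundance(recalibrate_mass_axis(tic_normalize(s)), ch)
  expect_equal(a$normalized, b$normalized, tolerance = 1e-9)
})
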