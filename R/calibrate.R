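# Calibration: per-channel classical least-squares models (simple, and
# bivariate with a TNT interference term), diagnostics, linear range and
# limit of detection.

new_calibration_model <- function(channel_mz, channel_label, group, kind,
                                  a, b_own, b_tnt = NA_real_,
                                  resid_sd, r2, range, n, lod = NA_real_,
                                  lod_undefined = FALSE,
                                  interferer = NA_character_) {
  structure(list(channel_mz = channel_mz, channel_label = channel_label,
                 group = group, kind = kind,
                 a = a, b_own = b_own, b_tnt = b_tnt,
                 resid_sd = resid_sd, r2 = r2, range = range, n = n,
                 lod = lod, lod_undefined = lod_undefined,
                 interferer = interferer),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model %s> m/z %g (%s)\n", x$kind, x$channel_mz,
              x$channel_label))
  cat(sprintf("  A = %.5g + %.5g * c", x$a, x$b_own))
  if (x$kind == "interference")
    cat(sprintf(" + %.5g * c_%s", x$b_tnt, x$interferer))
  cat(sprintf("\n  resid SD %.3g | R2 %.4f | range %g-%g ng/uL | LOD %s | n %d\n",
              x$resid_sd, x$r2, x$range[1], x$range[2],
              if (x$lod_undefined) "undefined" else sprintf("%.3g", x$lod),
              x$n))
  invisible(x)
}

#' Fit a simple linear calibration for one channel
#'
#' Unweighted ordinary least squares of mean IS-normalized abundance on
#' concentration (classical linear calibration). Blank (0 ng/uL) points
#' are included in the fit; the reported linear range runs from the lowest
#' nonzero level to the highest level. A constant response (no slope
#' information) is handled as a degenerate model with slope 0, R-squared 0
#' and an undefined LOD flag rather than an error.
#'
#' @param concentration Concentrations (ng/uL), >= 3 distinct values.
#' @param abundance Mean normalized abundances, same length.
#' @param channel_mz Channel m/z the model belongs to.
#' @param channel_label,group Channel metadata carried on the model.
#' @param weights Optional regression weights (e.g. 1/x); default
#'   unweighted.
#' @return A `calibration_model` of kind `"simple"` with intercept `a`,
#'   slope `b_own`, residual SD (n-2 dof), R-squared, range and LOD
#'   (see [estimate_lod()]).
#' @export
fit_simple_calibration <- function(concentration, abundance,
                                   channel_mz = NA_real_,
                                   channel_label = NA_character_,
                                   group = NA_character_,
                                   weights = NULL) {
  stopifnot(length(concentration) == length(abundance))
  if (length(unique(concentration)) < 3L)
    stop("simple calibration needs >= 3 distinct concentrations")
  if (stats::var(concentration) == 0)
    stop("zero concentration variance")
  fit <- if (is.null(weights)) stats::lm(abundance ~ concentration)
  else stats::lm(abundance ~ concentration, weights = weights)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  n <- length(abundance)
  resid_sd <- sqrt(sum(stats::resid(fit)^2) / (n - 2L))
  ss_tot <- sum((abundance - mean(abundance))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 0
  rng <- c(min(concentration[concentration > 0]), max(concentration))
  m <- new_calibration_model(channel_mz, channel_label, group, "simple",
                             a = a, b_own = b, resid_sd = resid_sd, r2 = r2,
                             range = rng, n = n)
  if (b > 0) {
    m$lod <- 3.3 * resid_sd / b
  } else {
    m$lod_undefined <- TRUE
  }
  m
}

#' Fit a bivariate interference calibration for one channel
#'
#' Classical least squares of the channel abundance on its own analyte
#' concentration and the TNT concentration (the documented interferer for
#' the ADNT channels): `A = a + b_own * c_own + b_tnt * c_tnt`.
#'
#' @param c_own Own-analyte concentrations (ng/uL).
#' @param c_tnt Interferer (TNT) concentrations (ng/uL).
#' @param abundance Mean normalized abundances.
#' @param channel_mz,channel_label,group Channel metadata.
#' @param interferer Interfering analyte label (default `"TNT"`).
#' @return A `calibration_model` of kind `"interference"` (residual SD with
#'   n-3 dof).
#' @export
fit_interference_calibration <- function(c_own, c_tnt, abundance,
                                         channel_mz = NA_real_,
                                         channel_label = NA_character_,
                                         group = NA_character_,
                                         interferer = "TNT") {
  n <- length(abundance)
  stopifnot(length(c_own) == n, length(c_tnt) == n)
  if (n < 6L)
    stop("interference calibration needs >= 6 design points")
  X <- cbind(1, c_own, c_tnt)
  if (qr(X)$rank < 3L)
    stop("rank-deficient design: own and interferer concentrations are collinear")
  fit <- stats::lm(abundance ~ c_own + c_tnt)
  cf <- unname(stats::coef(fit))
  resid_sd <- sqrt(sum(stats::resid(fit)^2) / (n - 3L))
  ss_tot <- sum((abundance - mean(abundance))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 0
  rng <- c(min(c_own[c_own > 0]), max(c_own))
  m <- new_calibration_model(channel_mz, channel_label, group,
                             "interference",
                             a = cf[1], b_own = cf[2], b_tnt = cf[3],
                             resid_sd = resid_sd, r2 = r2, range = rng,
                             n = n, interferer = interferer)
  if (cf[2] > 0) m$lod <- 3.3 * resid_sd / cf[2] else m$lod_undefined <- TRUE
  m
}

#' Limit of detection of a fitted calibration
#'
#' ICH-style formula: LOD = 3.3 x residual SD / slope (ng/uL). Stored on
#' the model at fit time; this accessor recomputes it.
#'
#' @param m A `calibration_model` with positive slope.
#' @return LOD in ng/uL.
#' @export
estimate_lod <- function(m) {
  stopifnot(inherits(m, "calibration_model"))
  if (is.na(m$b_own) || m$b_own <= 0)
    stop("LOD requires a positive calibration slope")
  3.3 * m$resid_sd / m$b_own
}

#' Fit simple calibrations for every analyte channel of a series
#'
#' Joins the per-sample mean abundances of a processed calibration series
#' with the design table and fits one simple model per channel, using the
#' channel's own isomer-group concentration as the regressor.
#'
#' @param abundance Ion-abundance table (per spot) of the calibration
#'   spectra, as from [spectra_to_abundance()].
#' @param design Design data frame (sample_id, analyte, concentration).
#' @return Named list of `calibration_model`s keyed by channel m/z (as
#'   character).
#' @export
fit_calibration_set <- function(abundance, design) {
  samples <- unique(abundance$sample_id)
  means <- do.call(rbind, lapply(samples, function(id) {
    average_replicates(abundance[abundance$sample_id == id, , drop = FALSE])
  }))
  channels <- unique(means[means$group != "IS",
                           c("channel_mz", "channel_label", "group")])
  models <- list()
  for (i in seq_len(nrow(channels))) {
    ch <- channels[i, ]
    sub <- means[means$channel_mz == ch$channel_mz, ]
    conc <- vapply(sub$sample_id, function(id) {
      hit <- design$concentration[design$sample_id == id &
                                    design$analyte == ch$group]
      if (length(hit) != 1L)
        stop(sprintf("design has no concentration for %s / %s", id, ch$group))
      hit
    }, numeric(1))
    models[[as.character(ch$channel_mz)]] <-
      fit_simple_calibration(conc, sub$mean_normalized,
                             channel_mz = ch$channel_mz,
                             channel_label = ch$channel_label,
                             group = ch$group)
  }
  models
}

#' Replace ADNT-channel models with interference calibrations
#'
#' Processes an interference-grid series (TNT x ADNT cross) and refits the
#' ADNT channels with the bivariate model; all other channels keep their
#' simple calibrations.
#'
#' @param models Model set from [fit_calibration_set()].
#' @param abundance Ion-abundance table of the interference-grid spectra.
#' @param design Grid design (sample_id, c_tnt, c_adnt).
#' @param groups Analyte groups to refit (default `"ADNT"`).
#' @return The updated model set.
#' @export
fit_interference_set <- function(models, abundance, design,
                                 groups = "ADNT") {
  samples <- unique(abundance$sample_id)
  means <- do.call(rbind, lapply(samples, function(id) {
    average_replicates(abundance[abundance$sample_id == id, , drop = FALSE])
  }))
  for (key in names(models)) {
    m <- models[[key]]
    if (!m$group %in% groups) next
    sub <- means[means$channel_mz == m$channel_mz, ]
    idx <- match(sub$sample_id, design$sample_id)
    models[[key]] <- fit_interference_calibration(
      c_own = design$c_adnt[idx], c_tnt = design$c_tnt[idx],
      abundance = sub$mean_normalized,
      channel_mz = m$channel_mz, channel_label = m$channel_label,
      group = m$group)
  }
  models
}

#' Serialize a calibration model set to a data frame / CSV
#'
#' @param models Named list of `calibration_model`s.
#' @param path Optional CSV path; when given, the table is also written.
#' @return Data frame (channel_mz, channel_label, group, kind, a, b_own,
#'   b_tnt, resid_sd, r2, range_min, range_max, lod, n).
#' @export
calibration_table <- function(models, path = NULL) {
  df <- do.call(rbind, lapply(models, function(m) {
    data.frame(channel_mz = m$channel_mz, channel_label = m$channel_label,
               group = m$group, kind = m$kind, a = m$a, b_own = m$b_own,
               b_tnt = m$b_tnt, resid_sd = m$resid_sd, r2 = m$r2,
               range_min = m$range[1], range_max = m$range[2],
               lod = m$lod, n = m$n, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE, na = "")
  df
}

#' Read a calibration model set from CSV
#'
#' Inverse of [calibration_table()] with a `path`.
#'
#' @param path CSV path.
#' @return Named list of `calibration_model`s keyed by channel m/z.
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    new_calibration_model(r$channel_mz, r$channel_label, r$group, r$kind,
                          a = r$a, b_own = r$b_own, b_tnt = r$b_tnt,
                          resid_sd = r$resid_sd, r2 = r$r2,
                          range = c(r$range_min, r$range_max), n = r$n,
                          lod = r$lod, lod_undefined = is.na(r$lod),
                          interferer = if (r$kind == "interference") "TNT"
                          else NA_character_)
  })
  stats::setNames(models, as.character(df$channel_mz))
}
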