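# The mass_spectrum container: a uniform m/z axis with intensities plus
# acquisition/processing metadata.

#' Construct a mass spectrum
#'
#' @param mz Strictly increasing, uniformly spaced m/z axis (Da).
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param sample_id Sample identifier.
#' @param spot Spot replicate index (1-based).
#' @param seed Seed the spectrum was generated with, if synthetic.
#' @param processed Character vector of processing flags already applied
#'   (subset of `"recalibrated"`, `"tic_normalized"`).
#' @return A `mass_spectrum` object.
#' @export
mass_spectrum <- function(mz, intensity, sample_id = NA_character_,
                          spot = 1L, seed = NA_integer_,
                          processed = character()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) < 2L) stop("a spectrum needs at least two points")
  d <- diff(mz)
  if (any(d <= 0)) stop("m/z axis must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * stats::median(d))
    stop("m/z axis must be uniformly spaced")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(mz = mz, intensity = intensity,
                 metadata = list(sample_id = sample_id,
                                 spot = as.integer(spot),
                                 seed = seed,
                                 processed = processed)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<mass_spectrum> %s spot %s | m/z %.2f-%.2f (%d points) | TIC %.4g%s\n",
    md$sample_id, md$spot, min(x$mz), max(x$mz), length(x$mz),
    sum(x$intensity),
    if (length(md$processed)) paste0(" | ", paste(md$processed, collapse = ","))
    else ""))
  invisible(x)
}

has_flag <- function(s, flag) flag %in% s$metadata$processed

add_flag <- function(s, flag) {
  s$metadata$processed <- union(s$metadata$processed, flag)
  s
}
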