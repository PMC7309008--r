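#' Generate a synthetic LED emission spectrum
#'
#' Emulates a dark-corrected spectrometer acquisition of a real LED: the
#' primary band (Gaussian or skewed), any stray secondary bands, sampled at
#' the instrument resolution, plus additive Gaussian noise, clipped at zero
#' and normalized to unit maximum. Measured LEDs commonly lean left or right
#' of their peak and carry a small secondary feature (for a red emitter,
#' often a faint infrared one); both are reproducible here.
#'
#' @param source An [ox_light_source][light_source].
#' @param resolution Sampling step in nm (default 0.6, a typical fibre
#'   spectrometer resolution).
#' @param noise_sd Standard deviation of the additive noise, relative to the
#'   unit peak (default 0, noiseless).
#' @param seed Integer seed for the noise; required when `noise_sd > 0` for
#'   reproducibility. Identical seeds give bitwise-identical spectra.
#' @param span Half-width of the generated window around the primary band,
#'   in multiples of its FWHM (default 6); widened to cover stray bands.
#' @return An [ox_spectrum] of kind `"emission"`.
#' @examples
#' src <- light_source("red-with-ir-stray", gaussian_band(660, 20),
#'                     stray_bands = list(gaussian_band(940, 60, 0.05)))
#' s <- synth_led_spectrum(src, noise_sd = 0.005, seed = 7)
#' peak_fwhm(s)  # recovers the main band, not the stray one
#' @export
synth_led_spectrum <- function(source, resolution = 0.6, noise_sd = 0,
                               seed = NULL, span = 6) {
  stopifnot(inherits(source, "ox_light_source"))
  if (resolution <= 0) stop("`resolution` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")

  pb <- source$primary_band
  ctr <- nominal_wavelength(source)
  lo <- ctr - span * pb$fwhm
  hi <- ctr + span * pb$fwhm
  for (sb in source$stray_bands) {
    lo <- min(lo, sb$center - span * sb$fwhm)
    hi <- max(hi, sb$center + span * sb$fwhm)
  }
  lo <- max(lo, 1)  # wavelengths are physical
  grid <- seq(lo, hi, by = resolution)

  v <- if (inherits(pb, "ox_skewed_band"))
    evaluate_skewed_band(pb, grid)$value
  else
    evaluate_band(pb, grid)$value
  for (sb in source$stray_bands)
    v <- v + evaluate_band(sb, grid)$value

  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(seed)
    }
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  v <- pmax(v, 0)
  normalize_spectrum(
    ox_spectrum(grid, v, kind = "emission", label = source$name))
}
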