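#' Gaussian spectral band
#'
#' The standard parametric model for an LED emission line or a photodetector
#' responsivity lobe: `I(lambda) = amplitude * exp(-4 ln 2 ((lambda - center)/fwhm)^2)`,
#' i.e. a Gaussian parameterized directly by its peak wavelength and full
#' width at half maximum.
#'
#' @param center Peak wavelength in nm (> 0).
#' @param fwhm Full width at half maximum in nm (> 0).
#' @param amplitude Relative peak amplitude (default 1).
#' @return An object of class `ox_band`.
#' @examples
#' b <- gaussian_band(660, 20)
#' evaluate_band(b, c(650, 660, 670))$value  # 0.5, 1, 0.5
#' @export
gaussian_band <- function(center, fwhm, amplitude = 1) {
  if (!is.finite(center) || center <= 0) stop("`center` must be positive")
  if (!is.finite(fwhm) || fwhm <= 0) stop("`fwhm` must be positive")
  if (!is.finite(amplitude) || amplitude < 0)
    stop("`amplitude` must be non-negative")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude),
            class = "ox_band")
}

#' @export
print.ox_band <- function(x, ...) {
  cat(sprintf("<gaussian band: center %.1f nm, FWHM %.1f nm, amplitude %.3g>\n",
              x$center, x$fwhm, x$amplitude))
  invisible(x)
}

#' Evaluate a Gaussian band on a wavelength grid
#'
#' @param band An [ox_band][gaussian_band].
#' @param grid Strictly ascending wavelengths (nm).
#' @param kind Spectrum kind for the result (default `"emission"`).
#' @return An [ox_spectrum]. The value at `center` (when on the grid) equals
#'   `amplitude`; at `center +/- fwhm/2` it equals `amplitude / 2` exactly.
#' @export
evaluate_band <- function(band, grid, kind = "emission") {
  stopifnot(inherits(band, "ox_band"))
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be strictly ascending")
  v <- band$amplitude *
    exp(-4 * log(2) * ((grid - band$center) / band$fwhm)^2)
  ox_spectrum(grid, v, kind = kind,
              label = sprintf("gaussian(%.0f, %.0f)", band$center, band$fwhm))
}

# Mode and FWHM of the standardized skew-normal density
# 2*dnorm(x)*pnorm(alpha*x), computed numerically. Used to reparameterize
# the skew-normal by (mode, fwhm, shape).
.sn_shape_constants <- function(alpha) {
  d <- function(x) 2 * stats::dnorm(x) * stats::pnorm(alpha * x)
  opt <- stats::optimize(d, interval = c(-4, 4), maximum = TRUE,
                         tol = 1e-10)
  m0 <- opt$maximum
  half <- opt$objective / 2
  f <- function(x) d(x) - half
  left <- stats::uniroot(f, lower = m0 - 20, upper = m0, tol = 1e-10)$root
  right <- stats::uniroot(f, lower = m0, upper = m0 + 20, tol = 1e-10)$root
  list(mode = m0, fwhm = right - left)
}

#' Skewed spectral band
#'
#' Real LED emission lines lean left or right of their peak, which is why
#' datasheets quote both a peak wavelength and a dominant (centroid)
#' wavelength. This model is a skew-normal lineshape reparameterized by the
#' mode (peak wavelength), the FWHM and a signed shape parameter, and
#' numerically renormalized to unit maximum. `skew = 0` reduces exactly to
#' [gaussian_band()]; positive skew puts the longer tail (and hence the
#' centroid) on the long-wavelength side. No single skewed lineshape fits
#' every measured LED, so the model is deliberately a pluggable
#' parameterization rather than a physical claim.
#'
#' @param mode Peak wavelength in nm.
#' @param fwhm Full width at half maximum in nm (> 0).
#' @param skew Signed shape parameter (skew-normal alpha); 0 means
#'   symmetric.
#' @return An object of class `ox_skewed_band` (also `ox_band` when
#'   `skew == 0` would be wasteful, so it is kept distinct).
#' @export
skewed_band <- function(mode, fwhm, skew = 0) {
  if (!is.finite(mode) || mode <= 0) stop("`mode` must be positive")
  if (!is.finite(fwhm) || fwhm <= 0) stop("`fwhm` must be positive")
  if (!is.finite(skew)) stop("`skew` must be finite")
  structure(list(mode = mode, fwhm = fwhm, skew = skew),
            class = "ox_skewed_band")
}

#' @export
print.ox_skewed_band <- function(x, ...) {
  cat(sprintf("<skewed band: mode %.1f nm, FWHM %.1f nm, skew %.2f>\n",
              x$mode, x$fwhm, x$skew))
  invisible(x)
}

#' Evaluate a skewed band on a wavelength grid
#'
#' @param band An [ox_skewed_band][skewed_band].
#' @param grid Strictly ascending wavelengths (nm).
#' @param kind Spectrum kind for the result.
#' @return An [ox_spectrum], normalized to unit maximum, unimodal with its
#'   mode at `band$mode` (within the grid step). With `skew = 0` the result
#'   is identical to `evaluate_band(gaussian_band(mode, fwhm), grid)`.
#' @export
evaluate_skewed_band <- function(band, grid, kind = "emission") {
  stopifnot(inherits(band, "ox_skewed_band"))
  if (band$skew == 0)
    return(evaluate_band(gaussian_band(band$mode, band$fwhm), grid,
                         kind = kind))
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be strictly ascending")
  k <- .sn_shape_constants(band$skew)
  omega <- band$fwhm / k$fwhm
  xi <- band$mode - omega * k$mode
  z <- (grid - xi) / omega
  v <- 2 * stats::dnorm(z) * stats::pnorm(band$skew * z)
  if (max(v) <= 0)
    stop("skewed band has no support on the supplied grid")
  ox_spectrum(grid, v / max(v), kind = kind,
              label = sprintf("skewed(%.0f, %.0f, %.1f)",
                              band$mode, band$fwhm, band$skew))
}

#' Centroid (dominant) wavelength of a spectrum
#'
#' The intensity-weighted mean wavelength, computed by trapezoidal
#' quadrature. For a skewed emission line this is the datasheet's
#' "dominant"/"centroid" wavelength, which sits on the heavy-tail side of
#' the peak.
#'
#' @param s An [ox_spectrum].
#' @return Centroid wavelength in nm.
#' @export
centroid_wavelength <- function(s) {
  stopifnot(inherits(s, "ox_spectrum"))
  w <- s$wavelength; v <- s$value
  dw <- diff(w)
  num <- sum(dw * (w[-length(w)] * v[-length(v)] + w[-1] * v[-1]) / 2)
  den <- sum(dw * (v[-length(v)] + v[-1]) / 2)
  if (den <= 0) stop("cannot compute the centroid of an all-zero spectrum")
  num / den
}

#' Light source with a primary band and optional stray bands
#'
#' Measured LED spectra frequently show a secondary (stray) emission feature
#' in addition to the main line — e.g. a red emitter with a small infrared
#' feature. Stray bands are carried here so that synthetic spectra can
#' reproduce them; datasheet Gaussian models ignore them.
#'
#' @param name Component name.
#' @param primary_band [gaussian_band()] or [skewed_band()].
#' @param stray_bands List of [gaussian_band()] objects, each with amplitude
#'   no greater than the primary band's.
#' @param drive_current Forward current in mA (metadata; 20 mA is the usual
#'   standard test condition).
#' @return An object of class `ox_light_source`.
#' @export
light_source <- function(name, primary_band, stray_bands = list(),
                         drive_current = 20) {
  if (!inherits(primary_band, c("ox_band", "ox_skewed_band")))
    stop("`primary_band` must be a gaussian_band() or skewed_band()")
  if (!is.list(stray_bands) ||
      !all(vapply(stray_bands, inherits, logical(1), what = "ox_band")))
    stop("`stray_bands` must be a list of gaussian_band() objects")
  pa <- if (inherits(primary_band, "ox_band")) primary_band$amplitude else 1
  sa <- vapply(stray_bands, `[[`, numeric(1), "amplitude")
  if (length(sa) && any(sa > pa))
    stop("stray band amplitude exceeds the primary band amplitude")
  structure(list(name = as.character(name)[1], primary_band = primary_band,
                 stray_bands = stray_bands, drive_current = drive_current),
            class = "ox_light_source")
}

#' @export
print.ox_light_source <- function(x, ...) {
  ctr <- if (inherits(x$primary_band, "ox_skewed_band"))
    x$primary_band$mode else x$primary_band$center
  cat(sprintf("<light source '%s': %.0f nm, FWHM %.0f nm, %d stray band(s), %g mA>\n",
              x$name, ctr, x$primary_band$fwhm, length(x$stray_bands),
              x$drive_current))
  invisible(x)
}

#' Nominal center wavelength of a light source
#' @param source An [ox_light_source][light_source].
#' @return The primary band's peak (mode) wavelength in nm.
#' @export
nominal_wavelength <- function(source) {
  stopifnot(inherits(source, "ox_light_source"))
  b <- source$primary_band
  if (inherits(b, "ox_skewed_band")) b$mode else b$center
}

#' Photodetector with a parametric or sampled responsivity
#'
#' @param name Detector name.
#' @param response A [gaussian_band()] (parametric model) or an
#'   [ox_spectrum] of kind `"sensitivity"` (measured curve).
#' @return An object of class `ox_photodetector`.
#' @export
photodetector <- function(name, response) {
  if (!inherits(response, c("ox_band", "ox_spectrum")))
    stop("`response` must be a gaussian_band() or an ox_spectrum")
  structure(list(name = as.character(name)[1], response = response),
            class = "ox_photodetector")
}

#' @export
print.ox_photodetector <- function(x, ...) {
  kind <- if (inherits(x$response, "ox_band")) "gaussian model"
          else "sampled curve"
  cat(sprintf("<photodetector '%s' (%s)>\n", x$name, kind))
  invisible(x)
}

#' Detector responsivity as a sampled spectrum on a grid
#' @param pd An [ox_photodetector][photodetector].
#' @param grid Wavelength grid (nm).
#' @return An [ox_spectrum] of kind `"sensitivity"`.
#' @export
detector_spectrum <- function(pd, grid = default_grid()) {
  stopifnot(inherits(pd, "ox_photodetector"))
  if (inherits(pd$response, "ox_band"))
    evaluate_band(pd$response, grid, kind = "sensitivity")
  else
    resample_to_grid(pd$response, grid)
}

#' Synthetic photodetector stand-ins
#'
#' Silicon photodiode responsivity curves are manufacturer data and are not
#' bundled; these synthetic shapes reproduce the qualitative families seen
#' in practice so that pairing analyses can be exercised without
#' proprietary curves:
#' \describe{
#'   \item{`flat`}{uniform response — the idealized detector of the
#'     monochromatic theory; produces zero wavelength shift.}
#'   \item{`gaussian`}{a broad bell response peaking near 780 nm
#'     (typical small photo-IC behaviour).}
#'   \item{`midpeak`}{a narrower symmetric peak at 800 nm, halfway between
#'     the usual 660/940 nm oximetry channels, so the red channel is pulled
#'     up in wavelength and the IR channel pulled down.}
#'   \item{`ramp`}{a quasi-linear rise from 400 nm to the end of the grid,
#'     emulating large-area silicon photodiodes whose response climbs toward
#'     the NIR; it has no half-maximum crossing on the long-wavelength side,
#'     which exercises the numeric (non-Gaussian) weighting path.}
#' }
#'
#' @param shape One of `"flat"`, `"gaussian"`, `"midpeak"`, `"ramp"`.
#' @param grid Wavelength grid for sampled shapes.
#' @return An [ox_photodetector][photodetector].
#' @export
synthetic_detector <- function(shape = c("flat", "gaussian", "midpeak",
                                         "ramp"),
                               grid = default_grid()) {
  shape <- match.arg(shape)
  name <- paste0("synthetic-", shape)
  switch(shape,
    flat = photodetector(name,
      ox_spectrum(range(grid), c(1, 1), kind = "sensitivity", label = name)),
    gaussian = photodetector(name, gaussian_band(780, 400)),
    midpeak = photodetector(name, gaussian_band(800, 260)),
    ramp = {
      v <- pmax(0, grid - 400)
      if (max(v) <= 0) stop("ramp detector needs grid points above 400 nm")
      photodetector(name,
        ox_spectrum(grid, v / max(v), kind = "sensitivity", label = name))
    })
}

#' Emission spectrum of a light source on a grid
#'
#' Evaluates the source's parametric model. Stray bands are excluded by
#' default, matching datasheet-style modelling; include them to emulate a
#' measured spectrum.
#'
#' @param source An [ox_light_source][light_source].
#' @param grid Wavelength grid (nm).
#' @param include_stray Add the stray bands to the primary band?
#' @return An [ox_spectrum] of kind `"emission"`.
#' @export
source_spectrum <- function(source, grid = default_grid(),
                            include_stray = FALSE) {
  stopifnot(inherits(source, "ox_light_source"))
  pb <- source$primary_band
  s <- if (inherits(pb, "ox_skewed_band"))
    evaluate_skewed_band(pb, grid)
  else
    evaluate_band(pb, grid)
  if (include_stray && length(source$stray_bands)) {
    v <- s$value
    for (sb in source$stray_bands)
      v <- v + evaluate_band(sb, grid)$value
    s <- ox_spectrum(grid, v, kind = "emission", label = source$name)
  }
  s$label <- source$name
  s
}
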