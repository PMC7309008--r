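#' Sampled optical spectrum
#'
#' The common currency of the package: a wavelength grid (nm, strictly
#' ascending) with non-negative relative values. Emission spectra of light
#' sources, responsivity curves of photodetectors and molar extinction
#' curves are all carried as `ox_spectrum` objects.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly ascending.
#' @param value Numeric vector of relative intensities, same length as
#'   `wavelength`, finite and >= 0.
#' @param kind One of `"emission"`, `"sensitivity"`, `"extinction"`,
#'   `"derived"`.
#' @param label Free-text label used in printing and plots.
#' @return An object of class `ox_spectrum` with elements `wavelength`,
#'   `value`, `kind`, `label`.
#' @examples
#' s <- ox_spectrum(seq(600, 700, 0.5),
#'                  exp(-4 * log(2) * ((seq(600, 700, 0.5) - 660) / 20)^2))
#' peak_fwhm(s)
#' @export
ox_spectrum <- function(wavelength, value,
                        kind = c("emission", "sensitivity", "extinction",
                                 "derived"),
                        label = "") {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("`wavelength` and `value` must have the same length")
  if (length(wavelength) < 1L)
    stop("spectrum must contain at least one point")
  if (anyNA(wavelength) || any(!is.finite(wavelength)))
    stop("wavelengths must be finite")
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly ascending")
  if (anyNA(value) || any(!is.finite(value)))
    stop("spectrum values must be finite")
  if (any(value < 0))
    stop("spectrum values must be non-negative")
  structure(list(wavelength = wavelength, value = value,
                 kind = kind, label = as.character(label)[1]),
            class = "ox_spectrum")
}

#' @export
print.ox_spectrum <- function(x, ...) {
  rng <- range(x$wavelength)
  cat(sprintf("<ox_spectrum: %s%s, %d points, %.1f-%.1f nm, max %.4g>\n",
              x$kind, if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$wavelength), rng[1], rng[2], max(x$value)))
  invisible(x)
}

#' @export
plot.ox_spectrum <- function(x, ..., xlab = "wavelength (nm)",
                             ylab = "relative value", type = "l",
                             main = x$label) {
  graphics::plot(x$wavelength, x$value, type = type,
                 xlab = xlab, ylab = ylab, main = main, ...)
  invisible(x)
}

#' @export
as.data.frame.ox_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, value = x$value)
}

#' Default working wavelength grid
#'
#' A 300-1100 nm grid at 0.2 nm, finer than the 0.6 nm resolution of a
#' typical fibre spectrometer, so that resampled instrument curves are not
#' degraded by the working grid.
#'
#' @param step Grid step in nm (default 0.2).
#' @param from,to Grid limits in nm.
#' @return Numeric vector of wavelengths.
#' @export
default_grid <- function(step = 0.2, from = 300, to = 1100) {
  if (step <= 0) stop("`step` must be positive")
  seq(from, to, by = step)
}

#' Normalize a spectrum to unit maximum
#'
#' @param s An [ox_spectrum].
#' @return The spectrum scaled so that `max(value) == 1`. Idempotent.
#' @export
normalize_spectrum <- function(s) {
  stopifnot(inherits(s, "ox_spectrum"))
  m <- max(s$value)
  if (m <= 0)
    stop("cannot normalize an all-zero spectrum")
  s$value <- s$value / m
  s
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; wavelengths outside the spectrum's support map to
#' zero (spectra are physically negligible far from their band, and zero
#' padding avoids extrapolation artifacts in effective-coefficient sums).
#'
#' @param s An [ox_spectrum] with at least two points.
#' @param grid Ascending numeric vector of target wavelengths (nm).
#' @return An [ox_spectrum] on `grid`.
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "ox_spectrum"))
  if (length(s$wavelength) < 2L)
    stop("cannot resample a single-point spectrum")
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE))
    stop("target grid must be strictly ascending")
  v <- stats::approx(s$wavelength, s$value, xout = grid,
                     method = "linear", yleft = 0, yright = 0)$y
  ox_spectrum(grid, v, kind = s$kind, label = s$label)
}

#' Pointwise product of two spectra on a common grid
#'
#' Both operands are resampled (linear interpolation, zero outside support)
#' onto a shared grid spanning the union of their supports at the finer of
#' the two native steps, then multiplied pointwise. This is the spectral
#' weighting that turns an LED emission curve and a photodetector
#' responsivity curve into the pairing weight used for effective extinction
#' coefficients.
#'
#' @param a,b [ox_spectrum] objects.
#' @param grid Optional explicit common grid; when `NULL` (default) a grid
#'   is constructed as described above.
#' @return An [ox_spectrum] of kind `"derived"`. If the supports are
#'   disjoint the result is all zeros and a warning is raised.
#' @export
spectral_product <- function(a, b, grid = NULL) {
  stopifnot(inherits(a, "ox_spectrum"), inherits(b, "ox_spectrum"))
  if (is.null(grid)) {
    step <- min(stats::median(diff(a$wavelength)),
                stats::median(diff(b$wavelength)))
    lo <- min(a$wavelength[1], b$wavelength[1])
    hi <- max(a$wavelength[length(a$wavelength)],
              b$wavelength[length(b$wavelength)])
    grid <- seq(lo, hi, by = step)
  }
  av <- resample_to_grid(a, grid)$value
  bv <- resample_to_grid(b, grid)$value
  v <- av * bv
  if (all(v == 0))
    warning("spectral supports are disjoint; product is identically zero")
  ox_spectrum(grid, v, kind = "derived",
              label = paste(a$label, "x", b$label))
}

#' Peak wavelength and FWHM of a sampled spectrum
#'
#' The peak is the grid argmax (ties resolved to the lowest wavelength); the
#' full width at half maximum is the distance between the two half-maximum
#' crossings nearest the peak, each located by linear interpolation between
#' the bracketing samples. Secondary (stray) peaks below half maximum do not
#' affect the result. This mirrors the peak/FWHM identification a
#' spectrometer's companion software performs on a measured emission curve.
#'
#' @param s An [ox_spectrum] whose main lobe crosses half maximum on both
#'   sides of the peak.
#' @return Named numeric vector `c(peak = , fwhm = )` in nm.
#' @export
peak_fwhm <- function(s) {
  stopifnot(inherits(s, "ox_spectrum"))
  w <- s$wavelength
  v <- s$value
  if (length(w) < 3L) stop("spectrum too short for peak/FWHM extraction")
  i <- which.max(v)                      # ties -> lowest wavelength index
  half <- v[i] / 2
  if (v[i] <= 0) stop("cannot extract peak from an all-zero spectrum")

  # walk outward from the peak to the first sample below half maximum
  cross <- function(from, dir) {
    j <- from
    while (j + dir >= 1L && j + dir <= length(v) && v[j + dir] >= half)
      j <- j + dir
    if (j + dir < 1L || j + dir > length(v))
      stop("no half-maximum crossing on ",
           if (dir < 0) "the short-wavelength" else "the long-wavelength",
           " side of the peak")
    j2 <- j + dir
    # linear interpolation between the bracketing samples
    w[j] + (half - v[j]) * (w[j2] - w[j]) / (v[j2] - v[j])
  }
  left <- cross(i, -1L)
  right <- cross(i, 1L)
  c(peak = w[i], fwhm = right - left)
}
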