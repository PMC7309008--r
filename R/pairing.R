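#' Red + IR source pair with a shared photodetector
#'
#' A pulse oximeter pairs one red-region emitter with one near-infrared
#' emitter on a single photodetector; the detector's non-uniform
#' responsivity weights both channels.
#'
#' @param red_source,ir_source [ox_light_source][light_source] objects; the
#'   red primary center must lie below the IR primary center.
#' @param detector An [ox_photodetector][photodetector].
#' @param label Pair label (defaults to "red/ir" names).
#' @return An object of class `ox_pair`.
#' @export
source_detector_pair <- function(red_source, ir_source,
                                 detector = synthetic_detector("flat"),
                                 label = NULL) {
  stopifnot(inherits(red_source, "ox_light_source"),
            inherits(ir_source, "ox_light_source"),
            inherits(detector, "ox_photodetector"))
  if (nominal_wavelength(red_source) >= nominal_wavelength(ir_source))
    stop("the red source must peak below the IR source")
  if (is.null(label))
    label <- paste(red_source$name, ir_source$name, sep = "/")
  structure(list(red_source = red_source, ir_source = ir_source,
                 detector = detector, label = label),
            class = "ox_pair")
}

#' @export
print.ox_pair <- function(x, ...) {
  cat(sprintf("<source-detector pair '%s': %.0f nm + %.0f nm on '%s'>\n",
              x$label, nominal_wavelength(x$red_source),
              nominal_wavelength(x$ir_source), x$detector$name))
  invisible(x)
}

#' The generic 660/940 nm oximetry pair
#'
#' A generic red emitter at 660 nm with 20 nm FWHM and a generic IR emitter
#' at 940 nm with 50 nm FWHM — the canonical design point of dual-wavelength
#' oximetry and the reference pair for shift analyses.
#'
#' @param detector An [ox_photodetector][photodetector] (default flat).
#' @return An [ox_pair][source_detector_pair].
#' @export
generic_pair <- function(detector = synthetic_detector("flat")) {
  source_detector_pair(
    light_source("generic-red", gaussian_band(660, 20)),
    light_source("generic-ir", gaussian_band(940, 50)),
    detector, label = "generic")
}

.effective_band <- function(lambda_eff, fwhm_eff, lambda_led, method) {
  structure(list(lambda_eff = lambda_eff, fwhm_eff = fwhm_eff,
                 delta_lambda = lambda_eff - lambda_led,
                 lambda_led = lambda_led, method = method),
            class = "ox_effective_band")
}

#' @export
print.ox_effective_band <- function(x, ...) {
  cat(sprintf(
    "<effective band (%s): lambda_eff %.2f nm, FWHM_eff %.2f nm, shift %+.2f nm>\n",
    x$method, x$lambda_eff, x$fwhm_eff, x$delta_lambda))
  invisible(x)
}

#' Exact effective band of a Gaussian LED-detector pairing
#'
#' The product of two Gaussian curves is again a Gaussian. Writing the LED
#' line as a Gaussian at `lambda_LED` with width `fwhm_LED` and the detector
#' lobe at `lambda_PD` with `fwhm_PD`, the product has
#' \deqn{\lambda_{eff} = \lambda_{LED} + w (\lambda_{PD} - \lambda_{LED}),
#'   \quad w = \frac{\Delta\lambda_{LED}^2}
#'   {\Delta\lambda_{LED}^2 + \Delta\lambda_{PD}^2}}
#' \deqn{\Delta\lambda_{eff} = \frac{\Delta\lambda_{LED}\,\Delta\lambda_{PD}}
#'   {\sqrt{\Delta\lambda_{LED}^2 + \Delta\lambda_{PD}^2}}}
#' so the effective center is always pulled from the LED toward the
#' detector peak: the pairing "tends to bring the center wavelengths
#' together", and `sign(delta_lambda) == sign(lambda_PD - lambda_LED)`.
#'
#' @param led,pd [gaussian_band()] objects for the LED line and the
#'   detector lobe.
#' @return An `ox_effective_band` with elements `lambda_eff`, `fwhm_eff`,
#'   `delta_lambda` (signed shift from the LED center), `lambda_led`,
#'   `method = "exact"`.
#' @export
effective_band_exact <- function(led, pd) {
  stopifnot(inherits(led, "ox_band"), inherits(pd, "ox_band"))
  w <- led$fwhm^2 / (led$fwhm^2 + pd$fwhm^2)
  lambda_eff <- led$center + w * (pd$center - led$center)
  fwhm_eff <- led$fwhm * pd$fwhm / sqrt(led$fwhm^2 + pd$fwhm^2)
  .effective_band(lambda_eff, fwhm_eff, led$center, "exact")
}

#' First-order effective band for a narrow LED on a broad detector
#'
#' The design-phase shortcut: when the LED line is much narrower than the
#' detector lobe, the shift reduces to
#' \deqn{\delta\lambda \approx (\lambda_{PD} - \lambda_{LED})
#'   \left(\frac{\Delta\lambda_{LED}}{\Delta\lambda_{PD}}\right)^2}
#' with `fwhm_eff ~ fwhm_LED (1 - (fwhm_LED/fwhm_PD)^2 / 2)`. This is the
#' first-order expansion of [effective_band_exact()] in
#' `(fwhm_LED/fwhm_PD)^2`; it obeys the same sign rule and vanishes in the
#' flat-detector limit. Outside its regime (`fwhm_LED > fwhm_PD`) a warning
#' is raised and the exact form is returned instead.
#'
#' @inheritParams effective_band_exact
#' @return An `ox_effective_band` with `method = "approx"` (or `"exact"`
#'   after a regime violation).
#' @export
effective_band_approx <- function(led, pd) {
  stopifnot(inherits(led, "ox_band"), inherits(pd, "ox_band"))
  if (led$fwhm > pd$fwhm) {
    warning("approximation regime requires fwhm_LED <= fwhm_PD; ",
            "returning the exact Gaussian-product form")
    return(effective_band_exact(led, pd))
  }
  r2 <- (led$fwhm / pd$fwhm)^2
  delta <- (pd$center - led$center) * r2
  fwhm_eff <- led$fwhm * (1 - r2 / 2)
  .effective_band(led$center + delta, fwhm_eff, led$center, "approx")
}

# Effective band of a source-detector channel computed numerically from the
# sampled spectral product. Used whenever either side is not a clean
# Gaussian (skewed sources, measured or ramp-like detector curves).
.effective_band_numeric <- function(led_spec, pd_spec, lambda_led) {
  prod <- spectral_product(led_spec, pd_spec)
  pf <- peak_fwhm(prod)
  .effective_band(pf[["peak"]], pf[["fwhm"]], lambda_led, "numeric")
}

#' Effective coefficients of an oximetry pair
#'
#' Evaluates both channels of a red/IR source pair against an extinction
#' table: the effective extinction coefficients under the LED x detector
#' weighting, the reference (table) values at each source's nominal
#' wavelength, and the shift between them — the quantity that corrupts an
#' uncalibrated SpO2 computation.
#'
#' @param pair An [ox_pair][source_detector_pair].
#' @param table An [ox_chromophore_table][chromophore_table] (default: the
#'   bundled synthetic hemoglobin table).
#' @param grid Working wavelength grid.
#' @param include_stray Include the sources' stray bands in the weighting?
#' @return An object of class `ox_effective_coefficients`: per channel
#'   (`red`, `ir`) the effective and reference `eps_hbo2`/`eps_hb`, their
#'   differences (`shift_hbo2`, `shift_hb`) and the nominal wavelength.
#' @export
effective_coefficients <- function(pair, table = hemoglobin_extinction(),
                                   grid = default_grid(),
                                   include_stray = FALSE) {
  stopifnot(inherits(pair, "ox_pair"),
            inherits(table, "ox_chromophore_table"))
  pd_spec <- detector_spectrum(pair$detector, grid)
  channel <- function(src) {
    led_spec <- source_spectrum(src, grid, include_stray = include_stray)
    lam0 <- nominal_wavelength(src)
    eff <- effective_extinction(table, led_spec, pd_spec)
    ref <- interpolate_extinction(table, lam0)
    list(lambda_nominal = lam0,
         eps_hbo2 = eff[["eps_hbo2"]], eps_hb = eff[["eps_hb"]],
         ref_hbo2 = ref[["eps_hbo2"]], ref_hb = ref[["eps_hb"]],
         shift_hbo2 = eff[["eps_hbo2"]] - ref[["eps_hbo2"]],
         shift_hb = eff[["eps_hb"]] - ref[["eps_hb"]])
  }
  structure(list(label = pair$label, detector = pair$detector$name,
                 red = channel(pair$red_source),
                 ir = channel(pair$ir_source),
                 source_tag = table$source_tag),
            class = "ox_effective_coefficients")
}

#' Effective coefficients at fixed (monochromatic) wavelengths
#'
#' The idealized narrow-source, flat-detector limit: the extinction table
#' evaluated pointwise at the two channel wavelengths, with zero shift.
#' These are the coefficients the textbook Beer-Lambert SpO2 formula
#' assumes.
#'
#' @param table An [ox_chromophore_table][chromophore_table].
#' @param lambda_red,lambda_ir Channel wavelengths in nm (defaults 660 and
#'   940).
#' @return An `ox_effective_coefficients`.
#' @export
nominal_coefficients <- function(table = hemoglobin_extinction(),
                                 lambda_red = 660, lambda_ir = 940) {
  channel <- function(lam) {
    e <- interpolate_extinction(table, lam)
    list(lambda_nominal = lam,
         eps_hbo2 = e[["eps_hbo2"]], eps_hb = e[["eps_hb"]],
         ref_hbo2 = e[["eps_hbo2"]], ref_hb = e[["eps_hb"]],
         shift_hbo2 = 0, shift_hb = 0)
  }
  structure(list(label = sprintf("monochromatic %g/%g", lambda_red,
                                 lambda_ir),
                 detector = "flat (ideal)",
                 red = channel(lambda_red), ir = channel(lambda_ir),
                 source_tag = table$source_tag),
            class = "ox_effective_coefficients")
}

#' @export
print.ox_effective_coefficients <- function(x, ...) {
  cat(sprintf("<effective coefficients: pair '%s', detector '%s'>\n",
              x$label, x$detector))
  for (ch in c("red", "ir")) {
    c_ <- x[[ch]]
    cat(sprintf(
      "  %-3s (%g nm): eps_HbO2 %8.1f (shift %+7.1f), eps_Hb %8.1f (shift %+7.1f) L/mol/cm\n",
      ch, c_$lambda_nominal, c_$eps_hbo2, c_$shift_hbo2, c_$eps_hb,
      c_$shift_hb))
  }
  invisible(x)
}

#' Shift table for a set of source pairs
#'
#' For every source of every pair, the effective extinction coefficients
#' under the shared detector's weighting and the shift from the table value
#' at the source's nominal wavelength — the design-phase overview of how far
#' each candidate component pulls the coefficients away from their textbook
#' values.
#'
#' @param pairs A single [ox_pair][source_detector_pair] or a list of them.
#' @param table An [ox_chromophore_table][chromophore_table].
#' @param detector Optional detector overriding each pair's own.
#' @param ... Passed to [effective_coefficients()].
#' @return A data.frame with one row per source: pair label, channel,
#'   source name, nominal wavelength, effective and reference coefficients,
#'   shifts.
#' @export
shift_table <- function(pairs, table = hemoglobin_extinction(),
                        detector = NULL, ...) {
  if (inherits(pairs, "ox_pair")) pairs <- list(pairs)
  stopifnot(all(vapply(pairs, inherits, logical(1), "ox_pair")))
  rows <- lapply(pairs, function(p) {
    if (!is.null(detector))
      p <- source_detector_pair(p$red_source, p$ir_source, detector,
                                label = p$label)
    ec <- effective_coefficients(p, table, ...)
    do.call(rbind, lapply(c("red", "ir"), function(ch) {
      c_ <- ec[[ch]]
      src <- if (ch == "red") p$red_source else p$ir_source
      data.frame(pair = p$label, channel = ch, source = src$name,
                 lambda_nominal = c_$lambda_nominal,
                 eps_hbo2_eff = c_$eps_hbo2, eps_hb_eff = c_$eps_hb,
                 eps_hbo2_ref = c_$ref_hbo2, eps_hb_ref = c_$ref_hb,
                 shift_hbo2 = c_$shift_hbo2, shift_hb = c_$shift_hb)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structured pairing report for one source-detector pair
#'
#' Per channel: the effective band (exact closed form when both the source
#' and the detector are representable as Gaussians, otherwise numerically
#' from the sampled spectral product, with the fallback flagged) and the
#' effective extinction coefficients. When the detector is supplied as a
#' measured curve, a Gaussian summary is fitted via [peak_fwhm()] for
#' reporting; curves without a half-maximum crossing (ramp-like detectors)
#' trigger the fully numeric path.
#'
#' @param pair An [ox_pair][source_detector_pair].
#' @param table An [ox_chromophore_table][chromophore_table].
#' @param grid Working wavelength grid.
#' @return An object of class `ox_pair_report`.
#' @export
pair_report <- function(pair, table = hemoglobin_extinction(),
                        grid = default_grid()) {
  stopifnot(inherits(pair, "ox_pair"))
  pd_spec <- detector_spectrum(pair$detector, grid)

  pd_band <- if (inherits(pair$detector$response, "ox_band")) {
    pair$detector$response
  } else {
    tryCatch({
      pf <- peak_fwhm(pd_spec)
      gaussian_band(pf[["peak"]], pf[["fwhm"]])
    }, error = function(e) NULL)
  }
  gaussian_detector <- !is.null(pd_band)
  flat_detector <- inherits(pair$detector$response, "ox_spectrum") &&
    length(unique(pair$detector$response$value)) == 1L

  channel_band <- function(src) {
    lam0 <- nominal_wavelength(src)
    if (flat_detector)
      return(.effective_band(lam0, src$primary_band$fwhm, lam0, "exact"))
    if (gaussian_detector && inherits(src$primary_band, "ox_band") &&
        !length(src$stray_bands))
      return(effective_band_exact(src$primary_band, pd_band))
    .effective_band_numeric(
      source_spectrum(src, grid, include_stray = TRUE), pd_spec, lam0)
  }

  bands <- list(red = channel_band(pair$red_source),
                ir = channel_band(pair$ir_source))
  coefs <- effective_coefficients(pair, table, grid)
  structure(list(pair = pair$label, detector = pair$detector$name,
                 detector_gaussian_fit = gaussian_detector,
                 numeric_fallback = vapply(bands, function(b)
                   identical(b$method, "numeric"), logical(1)),
                 bands = bands, coefficients = coefs),
            class = "ox_pair_report")
}

#' @export
print.ox_pair_report <- function(x, ...) {
  cat(sprintf("Pairing report: %s on detector '%s'\n", x$pair, x$detector))
  if (!x$detector_gaussian_fit)
    cat("  [detector has no Gaussian summary; numeric weighting used]\n")
  for (ch in c("red", "ir")) {
    b <- x$bands[[ch]]
    cat(sprintf(
      "  %-3s: lambda_eff %7.2f nm (shift %+6.2f nm, FWHM_eff %6.2f nm, %s)\n",
      ch, b$lambda_eff, b$delta_lambda, b$fwhm_eff, b$method))
  }
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.ox_pair_report <- function(object, ...) {
  b <- object$bands; co <- object$coefficients
  out <- data.frame(
    channel = c("red", "ir"),
    lambda_nominal = c(co$red$lambda_nominal, co$ir$lambda_nominal),
    lambda_eff = c(b$red$lambda_eff, b$ir$lambda_eff),
    delta_lambda = c(b$red$delta_lambda, b$ir$delta_lambda),
    fwhm_eff = c(b$red$fwhm_eff, b$ir$fwhm_eff),
    eps_hbo2_eff = c(co$red$eps_hbo2, co$ir$eps_hbo2),
    eps_hb_eff = c(co$red$eps_hb, co$ir$eps_hb),
    shift_hbo2 = c(co$red$shift_hbo2, co$ir$shift_hbo2),
    shift_hb = c(co$red$shift_hb, co$ir$shift_hb))
  rownames(out) <- NULL
  out
}

#' Extract one channel's extinction coefficients
#'
#' @param eps An [ox_effective_coefficients][effective_coefficients].
#' @param channel `"red"` or `"ir"`.
#' @return Named vector `c(eps_hbo2 = , eps_hb = )`, suitable for
#'   [synth_ppg()].
#' @export
channel_eps <- function(eps, channel = c("red", "ir")) {
  stopifnot(inherits(eps, "ox_effective_coefficients"))
  channel <- match.arg(channel)
  c(eps_hbo2 = eps[[channel]]$eps_hbo2, eps_hb = eps[[channel]]$eps_hb)
}
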