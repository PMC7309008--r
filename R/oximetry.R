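#' Absorbance from measured and incident intensity
#'
#' Beer-Lambert absorbance `A = -ln(I / I0)`; for a single chromophore
#' `A = eps * concentration * pathlength`.
#'
#' @param i Measured intensity (> 0), any units.
#' @param i0 Incident intensity (> 0), same units.
#' @return Absorbance (unitless), vectorized.
#' @export
absorbance <- function(i, i0) {
  if (any(i <= 0) || any(i0 <= 0))
    stop("intensities must be positive")
  -log(i / i0)
}

# Extract the four channel coefficients (red/IR x HbO2/Hb) from an
# ox_effective_coefficients object or a named vector/list.
.eps4 <- function(eps) {
  if (inherits(eps, "ox_effective_coefficients"))
    return(list(hb1 = eps$red$eps_hb, hbo21 = eps$red$eps_hbo2,
                hb2 = eps$ir$eps_hb, hbo22 = eps$ir$eps_hbo2))
  eps <- as.list(eps)
  need <- c("eps_hb_red", "eps_hbo2_red", "eps_hb_ir", "eps_hbo2_ir")
  if (!all(need %in% names(eps)))
    stop("`eps` must be an ox_effective_coefficients object or carry ",
         paste(need, collapse = ", "))
  list(hb1 = eps$eps_hb_red, hbo21 = eps$eps_hbo2_red,
       hb2 = eps$eps_hb_ir, hbo22 = eps$eps_hbo2_ir)
}

#' SpO2 from the ratio of ratios by the Beer-Lambert model
#'
#' The closed-form dual-wavelength solution
#' \deqn{SpO_2 = 100\,\frac{\varepsilon_{Hb}(\lambda_1) -
#'   \varepsilon_{Hb}(\lambda_2) R}{\varepsilon_{Hb}(\lambda_1) -
#'   \varepsilon_{HbO_2}(\lambda_1) + (\varepsilon_{HbO_2}(\lambda_2) -
#'   \varepsilon_{Hb}(\lambda_2)) R}}
#' Using effective (spectrally weighted) coefficients here gives the
#' "effective Beer-Lambert" estimate a real component pairing would
#' produce.
#'
#' @param eps An [ox_effective_coefficients][effective_coefficients] object,
#'   or a named list/vector with `eps_hb_red`, `eps_hbo2_red`, `eps_hb_ir`,
#'   `eps_hbo2_ir` (L mol^-1 cm^-1).
#' @param r Ratio of ratios, vectorized.
#' @return SpO2 in percent (unclamped; can exceed 100 or fall below 0
#'   outside the physiological range of `r`).
#' @export
spo2_bll <- function(eps, r) {
  e <- .eps4(eps)
  den <- (e$hb1 - e$hbo21) + (e$hbo22 - e$hb2) * r
  tol <- 1e-9 * max(abs(e$hb1 - e$hbo21), abs(e$hbo22 - e$hb2), 1)
  if (any(abs(den) <= tol))
    stop("ratio of ratios at (or numerically near) the singularity of the ",
         "Beer-Lambert solution")
  100 * (e$hb1 - e$hb2 * r) / den
}

#' Linear SpO2 calibration line
#'
#' The ubiquitous low-cost approximation `SpO2 = a R + b`. The default
#' coefficients are the widely deployed `SpO2 = 110 - 25 R`, derived from
#' the extinction coefficients at the canonical 660/940 nm channels.
#'
#' @param a Slope in percent per unit R (negative for physiological
#'   extinction orderings).
#' @param b Intercept in percent.
#' @return An object of class `ox_calibration`.
#' @seealso [fit_linear_calibration()] to fit a line to the Beer-Lambert
#'   curve of a specific component pairing.
#' @export
calibration_line <- function(a = -25, b = 110) {
  stopifnot(is.finite(a), is.finite(b))
  structure(list(coefficients = c(a = a, b = b), fitted = FALSE),
            class = "ox_calibration")
}

#' @export
print.ox_calibration <- function(x, ...) {
  cat(sprintf("<calibration line: SpO2 = %.4g + %.4g R%s>\n",
              x$coefficients[["b"]], x$coefficients[["a"]],
              if (isTRUE(x$fitted))
                sprintf(" (least squares on R in [%.3g, %.3g], n = %d)",
                        x$r_range[1], x$r_range[2], x$n) else ""))
  invisible(x)
}

#' @export
coef.ox_calibration <- function(object, ...) object$coefficients

#' @export
predict.ox_calibration <- function(object, r, clamp = FALSE, ...) {
  spo2_linear(object, r, clamp = clamp)
}

#' SpO2 by the linear approximation
#'
#' @param line An [ox_calibration][calibration_line].
#' @param r Ratio of ratios, vectorized.
#' @param clamp Clamp the result to `[0, 100]` for display? Default `FALSE`:
#'   the default line exceeds 100% at small R, and that unclamped behaviour
#'   is part of the error being quantified.
#' @return SpO2 in percent.
#' @export
spo2_linear <- function(line, r, clamp = FALSE) {
  stopifnot(inherits(line, "ox_calibration"))
  out <- line$coefficients[["a"]] * r + line$coefficients[["b"]]
  if (clamp) out <- pmin(pmax(out, 0), 100)
  out
}

#' Ratio of ratios at which the Beer-Lambert model gives a target SpO2
#'
#' Inverts the Beer-Lambert SpO2 formula for a coefficient set; used to map
#' saturation windows (e.g. the clinically critical 90-100%) onto the R
#' axis.
#'
#' @inheritParams spo2_bll
#' @param spo2 Target saturation(s) in percent.
#' @return Ratio(s) of ratios.
#' @export
ratio_at_spo2 <- function(eps, spo2) {
  e <- .eps4(eps)
  den <- spo2 * (e$hbo22 - e$hb2) + 100 * e$hb2
  if (any(abs(den) <= .Machine$double.eps * 100))
    stop("target saturation at the singularity of the inversion")
  (100 * e$hb1 - spo2 * (e$hb1 - e$hbo21)) / den
}

#' Fit a linear calibration to the Beer-Lambert curve
#'
#' Ordinary least squares of the Beer-Lambert SpO2 on R, sampled uniformly
#' over an R range. By default the range is chosen so that the Beer-Lambert
#' saturation spans 70-100% — the region a design-phase calibration line
#' should represent.
#'
#' @inheritParams spo2_bll
#' @param r_range Length-2 R interval; default maps to SpO2 in `[70, 100]`.
#' @param n_points Number of uniformly spaced sample points (default 200).
#' @return An [ox_calibration][calibration_line] with `fitted = TRUE`.
#' @export
fit_linear_calibration <- function(eps, r_range = NULL, n_points = 200) {
  if (is.null(r_range))
    r_range <- sort(ratio_at_spo2(eps, c(100, 70)))
  stopifnot(length(r_range) == 2L, r_range[1] < r_range[2], n_points >= 2)
  r <- seq(r_range[1], r_range[2], length.out = n_points)
  s <- spo2_bll(eps, r)
  fit <- stats::lm(s ~ r)
  out <- calibration_line(a = unname(stats::coef(fit)[2]),
                          b = unname(stats::coef(fit)[1]))
  out$fitted <- TRUE
  out$r_range <- r_range
  out$n <- n_points
  out
}

#' SpO2 error profile of the linear approximation
#'
#' Evaluates the Beer-Lambert SpO2 (with the supplied, typically effective,
#' coefficients) and the linear approximation on a grid of ratio-of-ratios
#' values and forms the relative deviation
#' \deqn{\Delta SpO_2 = \frac{BLL - Approx}{BLL} \times 100\%}
#' flagging the grid points whose Beer-Lambert saturation falls in the
#' clinically critical window (default 90-100%), where an error of 2% can
#' already mislead a diagnosis.
#'
#' @inheritParams spo2_bll
#' @param line An [ox_calibration][calibration_line]; default the
#'   `110 - 25 R` line.
#' @param r_grid R grid; default 400 points over `[0.3, 3]`.
#' @param window Saturation window in percent (default `c(90, 100)`).
#' @return An object of class `ox_error_profile`: a list with vectors `r`,
#'   `spo2_bll`, `spo2_linear`, `delta_spo2` (percent) and logical
#'   `in_window`. Grid points where the Beer-Lambert solution is singular
#'   or zero are dropped with a warning.
#' @export
error_profile <- function(eps, line = calibration_line(),
                          r_grid = seq(0.3, 3, length.out = 400),
                          window = c(90, 100)) {
  stopifnot(inherits(line, "ox_calibration"), length(window) == 2L)
  e <- .eps4(eps)
  den <- (e$hb1 - e$hbo21) + (e$hbo22 - e$hb2) * r_grid
  tol <- 1e-9 * max(abs(e$hb1 - e$hbo21), abs(e$hbo22 - e$hb2), 1)
  bll <- 100 * (e$hb1 - e$hb2 * r_grid) / den
  bad <- abs(den) <= tol | !is.finite(bll) | bll == 0
  if (any(bad)) {
    warning(sum(bad), " singular grid point(s) dropped from the error ",
            "profile")
    r_grid <- r_grid[!bad]
    bll <- bll[!bad]
  }
  lin <- spo2_linear(line, r_grid)
  delta <- (bll - lin) / bll * 100
  structure(list(r = r_grid, spo2_bll = bll, spo2_linear = lin,
                 delta_spo2 = delta,
                 in_window = bll >= window[1] & bll <= window[2],
                 window = window,
                 eps_label = if (inherits(eps, "ox_effective_coefficients"))
                   eps$label else "custom",
                 line = line),
            class = "ox_error_profile")
}

#' @export
print.ox_error_profile <- function(x, ...) {
  cat(sprintf(
    "<error profile '%s': %d R points, window %g-%g%% (%d points)>\n",
    x$eps_label, length(x$r), x$window[1], x$window[2], sum(x$in_window)))
  if (any(x$in_window))
    cat(sprintf("  max |DeltaSpO2| in window: %.3f%%\n",
                max(abs(x$delta_spo2[x$in_window]))))
  invisible(x)
}

#' @export
as.data.frame.ox_error_profile <- function(x, ...) {
  data.frame(r = x$r, spo2_bll = x$spo2_bll, spo2_linear = x$spo2_linear,
             delta_spo2 = x$delta_spo2, in_window = x$in_window)
}

#' @export
summary.ox_error_profile <- function(object, ...) {
  w <- object$in_window
  out <- list(
    label = object$eps_label,
    n = length(object$r),
    n_window = sum(w),
    max_abs_error_window = if (any(w)) max(abs(object$delta_spo2[w]))
                           else NA_real_,
    max_abs_error_overall = max(abs(object$delta_spo2)),
    mean_error_window = if (any(w)) mean(object$delta_spo2[w]) else NA_real_)
  class(out) <- "summary.ox_error_profile"
  out
}

#' @export
print.summary.ox_error_profile <- function(x, ...) {
  cat(sprintf("Error profile '%s'\n", x$label))
  cat(sprintf("  grid points: %d (%d in window)\n", x$n, x$n_window))
  cat(sprintf("  max |DeltaSpO2| in window:  %.3f%%\n",
              x$max_abs_error_window))
  cat(sprintf("  mean DeltaSpO2 in window:   %+.3f%%\n",
              x$mean_error_window))
  cat(sprintf("  max |DeltaSpO2| overall:    %.3f%%\n",
              x$max_abs_error_overall))
  invisible(x)
}

#' @export
plot.ox_error_profile <- function(x, against = c("spo2", "r"), ...) {
  against <- match.arg(against)
  xv <- if (against == "spo2") x$spo2_bll else x$r
  xlab <- if (against == "spo2") "SpO2 (Beer-Lambert, %)"
          else "ratio of ratios R"
  graphics::plot(xv, x$delta_spo2, type = "l", xlab = xlab,
                 ylab = "DeltaSpO2 (%)",
                 main = sprintf("Linear approximation error: %s",
                                x$eps_label), ...)
  if (any(x$in_window)) {
    graphics::abline(v = range(xv[x$in_window]), lty = 3,
                     col = "grey40")
  }
  graphics::abline(h = 0, lty = 2, col = "grey60")
  invisible(x)
}

#' Maximum absolute SpO2 error inside the saturation window
#'
#' @param profile An [ox_error_profile][error_profile].
#' @return Maximum of `|DeltaSpO2|` (percent) over the grid points whose
#'   Beer-Lambert saturation lies in the profile's window.
#' @export
max_abs_error_in_window <- function(profile) {
  stopifnot(inherits(profile, "ox_error_profile"))
  if (!any(profile$in_window))
    stop("no grid points fall inside the saturation window")
  max(abs(profile$delta_spo2[profile$in_window]))
}
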