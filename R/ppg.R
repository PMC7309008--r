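#' Forward-model parameters for synthetic photoplethysmograms
#'
#' The transmission-mode Beer-Lambert forward model: a static tissue path of
#' length `d_static` plus a pulsatile arterial path `delta_d_amp * pulse(t)`
#' whose periodic expansion at the heart rate modulates the transmitted
#' intensity. The pulsatile path increment is taken identical at both
#' wavelengths, the assumption that underlies the ratio-of-ratios method.
#'
#' @param sao2 True arterial saturation as a fraction in `[0, 1]`.
#' @param c_hb_total Total hemoglobin concentration in mol/L (default
#'   2.3e-3, i.e. ~150 g/L at 64500 g/mol); `[HbO2] = sao2 * c_hb_total`,
#'   `[Hb] = (1 - sao2) * c_hb_total`.
#' @param d_static Baseline optical path length in cm (default 1).
#' @param delta_d_amp Pulsatile path amplitude in cm (default 0.01; must be
#'   small against `d_static` for the small-signal theory to hold).
#' @param heart_rate Heart rate in beats per minute (default 60).
#' @param i0 Incident intensity in arbitrary detector units (default 1).
#' @param waveform Cardiac pulse shape: `"raised-cosine"` (symmetric) or
#'   `"systolic"` (asymmetric, fast upstroke).
#' @param noise_sd Additive intensity noise SD in units of `i0` (default 0).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return An object of class `ox_forward_params`.
#' @export
forward_model_params <- function(sao2, c_hb_total = 2.3e-3, d_static = 1,
                                 delta_d_amp = 0.01, heart_rate = 60,
                                 i0 = 1,
                                 waveform = c("raised-cosine", "systolic"),
                                 noise_sd = 0, seed = NULL) {
  waveform <- match.arg(waveform)
  if (sao2 < 0 || sao2 > 1) stop("`sao2` must be a fraction in [0, 1]")
  if (c_hb_total <= 0 || d_static <= 0 || i0 <= 0)
    stop("`c_hb_total`, `d_static` and `i0` must be positive")
  if (delta_d_amp < 0) stop("`delta_d_amp` must be non-negative")
  if (delta_d_amp >= d_static)
    stop("`delta_d_amp` must be small against `d_static`")
  if (heart_rate <= 0) stop("`heart_rate` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(sao2 = sao2, c_hb_total = c_hb_total,
                 d_static = d_static, delta_d_amp = delta_d_amp,
                 heart_rate = heart_rate, i0 = i0, waveform = waveform,
                 noise_sd = noise_sd, seed = seed),
            class = "ox_forward_params")
}

# Periodic unimodal cardiac pulse in [0, 1] at frequency f (Hz).
.pulse_wave <- function(t, f, waveform) {
  phase <- (t * f) %% 1
  switch(waveform,
    "raised-cosine" = 0.5 - 0.5 * cos(2 * pi * phase),
    "systolic" = {
      # fast upstroke, slow decay; periodic and unimodal per cycle
      shape <- function(p) exp(-((p - 0.30)^2) / (2 * 0.12^2)) +
        0.25 * exp(-((p - 0.65)^2) / (2 * 0.18^2))
      # normalize by the shape's true peak (not the sampled max) so the
      # amplitude does not depend on the sampling grid
      shape(phase) / stats::optimize(shape, c(0, 1),
                                     maximum = TRUE)$objective
    })
}

#' Synthesize a photoplethysmogram channel by the Beer-Lambert forward model
#'
#' Transmitted intensity
#' `I(t) = i0 * exp(-eps_mix * c_hb_total * (d_static + delta_d_amp * pulse(t)))`
#' with `eps_mix = eps_hbo2 * sao2 + eps_hb * (1 - sao2)` for the channel's
#' effective extinction coefficients, plus optional seeded Gaussian noise.
#' The pulsatile absorption produces the AC component riding on the large
#' DC baseline set by the static tissue path.
#'
#' @param params An [ox_forward_params][forward_model_params].
#' @param eps_channel Named vector `c(eps_hbo2 = , eps_hb = )` in
#'   L mol^-1 cm^-1 for this wavelength channel.
#' @param duration Trace duration in seconds (default 10).
#' @param sampling_rate Sampling rate in Hz (default 125).
#' @return An object of class `ox_ppg` with `time` (s), `intensity`
#'   (detector units) and `sampling_rate`.
#' @export
synth_ppg <- function(params, eps_channel, duration = 10,
                      sampling_rate = 125) {
  stopifnot(inherits(params, "ox_forward_params"))
  if (!all(c("eps_hbo2", "eps_hb") %in% names(eps_channel)))
    stop("`eps_channel` must carry `eps_hbo2` and `eps_hb`")
  if (duration <= 0 || sampling_rate <= 0)
    stop("`duration` and `sampling_rate` must be positive")
  t <- seq(0, duration, by = 1 / sampling_rate)
  f <- params$heart_rate / 60
  eps_mix <- eps_channel[["eps_hbo2"]] * params$sao2 +
    eps_channel[["eps_hb"]] * (1 - params$sao2)
  path <- params$d_static +
    params$delta_d_amp * .pulse_wave(t, f, params$waveform)
  intensity <- params$i0 * exp(-eps_mix * params$c_hb_total * path)
  if (params$noise_sd > 0) {
    if (!is.null(params$seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(params$seed)
    }
    intensity <- pmax(intensity +
                        stats::rnorm(length(t), sd = params$noise_sd *
                                       params$i0),
                      .Machine$double.xmin)
  }
  structure(list(time = t, intensity = intensity,
                 sampling_rate = sampling_rate, params = params),
            class = "ox_ppg")
}

#' @export
print.ox_ppg <- function(x, ...) {
  cat(sprintf(
    "<PPG trace: %.1f s at %g Hz, DC ~ %.4g, PI ~ %.3g%%>\n",
    max(x$time), x$sampling_rate, mean(x$intensity),
    100 * perfusion_index(x)))
  invisible(x)
}

#' @export
plot.ox_ppg <- function(x, ..., xlab = "time (s)",
                        ylab = "intensity (detector units)") {
  graphics::plot(x$time, x$intensity, type = "l", xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Whole-trace perfusion index
#'
#' AC-to-DC ratio computed over the full trace (peak-to-peak over mean).
#' For a stationary periodic PPG this equals the per-cycle definition; it
#' also remains defined for a pulseless (flat) trace, where it is 0.
#'
#' @param ppg An [ox_ppg][synth_ppg].
#' @return Perfusion index (unitless fraction).
#' @export
perfusion_index <- function(ppg) {
  stopifnot(inherits(ppg, "ox_ppg"))
  dc <- mean(ppg$intensity)
  if (dc <= 0) stop("trace has non-positive mean intensity")
  diff(range(ppg$intensity)) / dc
}

# Indices of local minima separated by at least `min_sep` samples,
# used for minima-to-minima cardiac cycle segmentation.
.local_minima <- function(v, min_sep) {
  n <- length(v)
  cand <- which(v[2:(n - 1)] < v[1:(n - 2)] &
                  v[2:(n - 1)] <= v[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  keep <- cand[1]
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= min_sep) keep <- c(keep, i)
    else if (v[i] < v[keep[length(keep)]]) keep[length(keep)] <- i
  }
  keep
}

# Per-cycle AC (peak-to-peak) and DC (mean) of a trace given cycle
# boundary indices.
.cycle_ac_dc <- function(v, bounds) {
  t(vapply(seq_len(length(bounds) - 1L), function(k) {
    seg <- v[bounds[k]:bounds[k + 1L]]
    c(ac = diff(range(seg)), dc = mean(seg))
  }, numeric(2)))
}

#' Ratio of ratios from a red and an IR photoplethysmogram
#'
#' The peak-and-valley method: cardiac cycles are segmented
#' minima-to-minima on the IR trace (the convention adopted here; the IR
#' channel typically has the better signal-to-noise ratio), and within each
#' cycle AC is the peak-to-peak excursion and DC the mean of each channel.
#' The per-cycle ratios `(AC_red/DC_red)/(AC_ir/DC_ir)` are averaged across
#' cycles.
#'
#' @param ppg_red,ppg_ir [ox_ppg][synth_ppg] traces on a common time base
#'   covering at least one full cardiac cycle.
#' @return The averaged ratio of ratios (unitless).
#' @export
ratio_of_ratios <- function(ppg_red, ppg_ir) {
  stopifnot(inherits(ppg_red, "ox_ppg"), inherits(ppg_ir, "ox_ppg"))
  if (length(ppg_red$intensity) != length(ppg_ir$intensity))
    stop("traces must share a common time base")
  # minimum separation: half the expected cycle if the heart rate is known,
  # otherwise a conservative 0.25 s
  hr <- tryCatch(ppg_ir$params$heart_rate, error = function(e) NULL)
  min_sep <- if (!is.null(hr))
    floor(0.5 * ppg_ir$sampling_rate * 60 / hr)
  else
    floor(0.25 * ppg_ir$sampling_rate)
  mins <- .local_minima(ppg_ir$intensity, max(min_sep, 2L))
  if (length(mins) < 2L)
    stop("could not segment a full cardiac cycle on the IR trace")
  red <- .cycle_ac_dc(ppg_red$intensity, mins)
  ir <- .cycle_ac_dc(ppg_ir$intensity, mins)
  if (any(ir[, "ac"] <= 0))
    stop("degenerate IR trace: zero pulsatile (AC) component")
  if (any(red[, "dc"] <= 0) || any(ir[, "dc"] <= 0))
    stop("degenerate trace: non-positive DC component")
  mean((red[, "ac"] / red[, "dc"]) / (ir[, "ac"] / ir[, "dc"]))
}

#' Analytic small-signal ratio of ratios at a given saturation
#'
#' In the small-modulation limit the ratio of ratios equals the ratio of
#' the pulsatile absorbance increments,
#' `R = eps_mix(red) / eps_mix(ir)` with
#' `eps_mix = eps_hbo2 * SaO2 + eps_hb * (1 - SaO2)` (the common pulsatile
#' path increment cancels). Feeding this R back into [spo2_bll()] with the
#' same coefficients recovers the saturation exactly — the closed loop used
#' to validate the simulator.
#'
#' @inheritParams spo2_bll
#' @param sao2 Arterial saturation as a fraction.
#' @return Ratio of ratios (unitless).
#' @export
ratio_from_saturation <- function(eps, sao2) {
  e <- .eps4(eps)
  num <- e$hbo21 * sao2 + e$hb1 * (1 - sao2)
  den <- e$hbo22 * sao2 + e$hb2 * (1 - sao2)
  if (any(den <= 0)) stop("non-positive IR absorbance increment")
  num / den
}
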