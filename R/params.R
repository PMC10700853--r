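# Default oscillator and reporter parameter sets for the three reporter
# channels recorded in SCN slices: cytosolic Ca (jRGECO1a, mApple-based),
# Per2 (Venus-based) and Bmal1 (Venus-based). All temperature maps are
# piecewise-linear through anchors and held constant outside the anchor
# range.

lin_map <- function(temp_C, values) {
  force(temp_C); force(values)
  function(T) stats::approx(temp_C, values, xout = T, rule = 2)$y
}

#' Default oscillator parameters
#'
#' One Stuart-Landau (Hopf normal form) oscillator per channel, with
#' temperature-dependent bifurcation parameter `mu(T)`, intrinsic period,
#' and baseline (fixed-point) level. Above the Hopf point (`mu > 0`) each
#' channel runs on a limit cycle of radius `sqrt(mu)`; below it the
#' oscillation damps toward a displaced fixed point (the "parking" state
#' whose elevated level models the cold Ca rise). The coupling graph is the
#' cycle Ca -> Per2 -> Bmal1 -> Ca with weak phase-lagged additive forcing;
#' the default phase lags hold the network at the observed offsets (Per2
#' peaks 7.9 h after Ca, Bmal1 13.2 h after Ca).
#'
#' `mu(T)` runs through anchors (35, 1.0), (22, 0.15), (18.5, 0), (15, -0.3)
#' so the Hopf bifurcation sits between 15 and 22 degC; the Bmal1 channel
#' damps more slowly below the bifurcation (`mu(15) = -0.1`). Periods at
#' 35 degC are 23.2 h for every channel (the coupled network shares the
#' pacemaker frequency); cold lengthening follows the Ca/Bmal1 anchors at
#' 28 and 22 degC. Where `mu <= 0` the angular frequency is frozen (the
#' phase holds while the amplitude decays).
#'
#' @param channels Character vector of channels to include (subset of
#'   `c("Ca", "Per2", "Bmal1")`).
#' @return A named list (class `oscillator_params`), one entry per channel
#'   with elements `period_h` (function of degC), `mu` (function of degC),
#'   `baseline_level` (function of degC), `relaxation_rate` (1/h),
#'   `amp_scale`, `initial_phase_h`, `park`, `critical_temp_C`, `coupling`
#'   (list of `source`, `gain`, `phase_lag_h`).
#' @export
default_oscillator_params <- function(channels = c("Ca", "Per2", "Bmal1")) {
  channels <- match.arg(channels, c("Ca", "Per2", "Bmal1"), several.ok = TRUE)
  mu_main  <- lin_map(c(15, 18.5, 22, 35), c(-0.3, 0, 0.15, 1.0))
  mu_bmal  <- lin_map(c(15, 18.5, 22, 35), c(-0.03, 0, 0.15, 1.0))
  per_ca   <- lin_map(c(22, 28, 35), c(25.3, 23.9, 23.2))
  per_bmal <- lin_map(c(22, 28, 35), c(28.4, 23.9, 23.2))

  p <- list(
    Ca = list(
      period_h        = per_ca,
      mu              = mu_main,
      # 15 degC anchor calibrated so the measured Day-1 dF/F0 baseline comes
      # out near the observed 196.7 % once the mApple-like brightness gain
      # and expression drift are composed on top; 22/28 degC anchors encode
      # that the apparent Ca baseline rise at moderate cold is explained by
      # the brightness artifact, not a true elevation
      baseline_level  = lin_map(c(15, 22, 28, 35), c(1.758, 1.08, 1.10, 1.30)),
      relaxation_rate = 0.08,
      amp_scale       = 0.3,
      initial_phase_h = 6,
      park            = 0.5,
      critical_temp_C = 18.5,
      # lags around the cycle sum to the 23.2-h period (zero net rotation):
      # Ca -> Per2 7.9 h, Per2 -> Bmal1 5.3 h, Bmal1 -> Ca 23.2 - 13.2 = 10.0 h
      coupling        = list(list(source = "Bmal1", gain = 0.05, phase_lag_h = 10.0))
    ),
    Per2 = list(
      period_h        = per_ca,
      mu              = mu_main,
      baseline_level  = lin_map(c(15, 22, 28, 35), c(23.61, 21.0, 20.7, 20.3)),
      relaxation_rate = 0.08,
      amp_scale       = 0.3,
      initial_phase_h = 13.9,
      park            = 0.5,
      critical_temp_C = 18.5,
      coupling        = list(list(source = "Ca", gain = 0.05, phase_lag_h = 7.9))
    ),
    Bmal1 = list(
      period_h        = per_bmal,
      mu              = mu_bmal,
      baseline_level  = lin_map(c(15, 22, 28, 35), c(18.31, 32.1, 28.8, 20.3)),
      relaxation_rate = 0.08,
      amp_scale       = 0.3,
      initial_phase_h = 19.2,
      park            = 0.5,
      critical_temp_C = 18.5,
      coupling        = list(list(source = "Per2", gain = 0.05, phase_lag_h = 5.3))
    )
  )
  p <- p[channels]
  # drop couplings whose source is not among the selected channels, so a
  # single-channel simulation runs the uncoupled oscillator
  for (ch in names(p)) {
    p[[ch]]$coupling <- purrr::keep(p[[ch]]$coupling,
                                    ~ .x$source %in% channels)
  }
  structure(p, class = "oscillator_params")
}

#' Default reporter (observation) parameters
#'
#' Maps each channel's oscillator state to fluorescence:
#' `F(t) = fp_gain(T) * drift(t) * (baseline + amp_scale * Re z) + noise`.
#' `fp_gain` is the intrinsic fluorescent-protein brightness gain at low
#' temperature (Venus-like +27.7 % and mApple-like +67.1 % at 15 degC,
#' interpolated linearly to 1 at 35 degC); `drift` is a slow multiplicative
#' expression increase (default 2 %/day, capped at x2); noise is additive
#' Gaussian with sd expressed as a fraction of the 35 degC dynamic range
#' (default 2 %); `baseline_tau_h` is the relaxation time of the baseline
#' toward its temperature target after a temperature step.
#'
#' @param channels Channels to include.
#' @return Named list (class `reporter_params`) with per-channel elements
#'   `fp_gain` (function of degC), `drift_rate` (fraction/day),
#'   `noise_sd` (fraction of dynamic range), `baseline_tau_h` (hours).
#' @export
default_reporter_params <- function(channels = c("Ca", "Per2", "Bmal1")) {
  channels <- match.arg(channels, c("Ca", "Per2", "Bmal1"), several.ok = TRUE)
  venus  <- lin_map(c(15, 35), c(1.277, 1))
  mapple <- lin_map(c(15, 35), c(1.671, 1))
  one_ch <- function(gain) list(fp_gain = gain, drift_rate = 0.02,
                                noise_sd = 0.02, baseline_tau_h = 2)
  p <- list(Ca = one_ch(mapple), Per2 = one_ch(venus), Bmal1 = one_ch(venus))
  structure(p[channels], class = "reporter_params")
}
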