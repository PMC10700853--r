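# Shared fixtures: small deterministic traces built in code.

# noiseless cosine "recording" with a given period and peak at t = phase_h
cosine_trace <- function(total_h = 96, period_h = 24, phase_h = 0,
                         amplitude = 1, step_h = 1) {
  t <- seq(0, total_h, by = step_h)
  tibble::tibble(time_h = t,
                 values = amplitude * cos(2 * pi * (t - phase_h) / period_h))
}

# quick single-channel Ca simulation under the standard chilling protocol
sim_ca <- function(cold_temp_C = 15, cold_h = 96, seed = 1, pre_h = 96,
                   post_h = 96, noise_sd = NULL, drift_rate = NULL) {
  osc <- default_oscillator_params("Ca")
  rep <- default_reporter_params("Ca")
  if (!is.null(noise_sd)) rep$Ca$noise_sd <- noise_sd
  if (!is.null(drift_rate)) rep$Ca$drift_rate <- drift_rate
  prot <- build_protocol(pre_h, cold_temp_C, cold_h, post_h)
  simulate_network(osc, rep, prot, seed = seed)
}

# brute-force centred running mean with shrinking edge windows (independent
# of the package implementation: plain per-window loop). Integer half-width
# windows half-weight the two endpoints; half-integer ones are plain means.
brute_running_mean <- function(values, time_h, window_h) {
  step <- time_h[2] - time_h[1]
  w <- window_h / (2 * step)
  n <- length(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (abs(w - round(w)) < 1e-9) {
      lo <- i - round(w); hi <- i + round(w)
      wt <- rep(1, hi - lo + 1); wt[1] <- 0.5; wt[length(wt)] <- 0.5
    } else {
      lo <- i - floor(w); hi <- i + floor(w)
      wt <- rep(1, hi - lo + 1)
    }
    keep <- seq(lo, hi) >= 1 & seq(lo, hi) <= n
    idx <- seq(lo, hi)[keep]
    out[i] <- sum(values[idx] * wt[keep]) / sum(wt[keep])
  }
  out
}
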