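test_that("noiseless limit cycle at 35 degC oscillates at the programmed period", {
  osc <- default_oscillator_params("Ca")
  osc$Ca$period_h <- function(T) rep(24, length(T))
  rep_ <- default_reporter_params("Ca")
  rep_$Ca$noise_sd <- 0
  rep_$Ca$drift_rate <- 0
  prot <- build_protocol(0, 35, 0, 240)
  tr <- simulate_network(osc, rep_, prot, seed = 1)
  dt <- detrend_running_average(compute_dff(tr$Ca), tr$time_h)
  pk <- detect_peaks(dt)
  expect_true(all(abs(diff(pk$time_h) - 24) <= 1))   # within one sample
})

test_that("below the Hopf point the oscillation dies at the displaced fixed point", {
  osc <- default_oscillator_params("Ca")
  rep_ <- default_reporter_params("Ca")
  rep_$Ca$noise_sd <- 0
  rep_$Ca$drift_rate <- 0
  prot <- build_protocol(0, 15, 480, 0)
  tr <- simulate_network(osc, rep_, prot, seed = 1)
  # oscillation envelope decays: spread over successive 48-h blocks shrinks
  spread <- vapply(split(tr$Ca, (tr$time_h %/% 48)),
                   function(x) diff(range(x)), numeric(1))
  expect_true(all(diff(spread[1:5]) < 0))
  # terminal level = fp_gain(15) * (baseline + amp * parked state)
  mu <- osc$Ca$mu(15)
  zstar <- uniroot(function(z) (mu - z^2) * z + (-mu) * osc$Ca$park,
                   c(0, 1))$root
  expected <- rep_$Ca$fp_gain(15) *
    (osc$Ca$baseline_level(15) + osc$Ca$amp_scale * zstar)
  expect_equal(tail(tr$Ca, 1), expected, tolerance = 1e-4)
})

test_that("steady-state amplitude follows sqrt(mu) Hopf scaling within 2 %", {
  osc <- default_oscillator_params("Ca")
  rep_ <- default_reporter_params("Ca")
  rep_$Ca$noise_sd <- 0
  rep_$Ca$drift_rate <- 0
  amp_at <- function(temp) {
    prot <- build_protocol(0, temp, 480, 0)
    tr <- simulate_network(osc, rep_, prot, seed = 1)
    f <- tr$Ca / rep_$Ca$fp_gain(temp)
    z_re <- (f - osc$Ca$baseline_level(temp)) / osc$Ca$amp_scale
    tail_ <- z_re[tr$time_h > 400]
    (max(tail_) - min(tail_)) / 2
  }
  for (temp in c(35, 30, 26, 23, 22)) {
    mu <- osc$Ca$mu(temp)
    expect_equal(amp_at(temp), sqrt(mu), tolerance = 0.02)
  }
  # amplitude is monotone in temperature (22 < 28 < 35)
  amps <- vapply(c(22, 28, 35), amp_at, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("simulation is bit-reproducible and noise-free runs are smooth", {
  prot <- build_protocol(96, 15, 48, 96)
  osc <- default_oscillator_params()
  rep_ <- default_reporter_params()
  a <- simulate_network(osc, rep_, prot, seed = 7)
  b <- simulate_network(osc, rep_, prot, seed = 7)
  expect_identical(a$Ca, b$Ca)
  expect_identical(a$Bmal1, b$Bmal1)
  c_ <- simulate_network(osc, rep_, prot, seed = 8)
  expect_false(identical(a$Ca, c_$Ca))

  # with noise_sd = 0 no stochastic term leaks in: second differences away
  # from temperature steps are tiny and two runs with different seeds agree
  for (ch in names(rep_)) rep_[[ch]]$noise_sd <- 0
  n1 <- simulate_network(osc, rep_, prot, seed = 1)
  n2 <- simulate_network(osc, rep_, prot, seed = 99)
  expect_identical(n1$Ca, n2$Ca)
  # second differences of the smooth warm-segment signal stay near the
  # curvature of the underlying 23.2-h cycle (A * omega^2 ~ 0.022/h^2)
  seg <- n1$Ca[n1$time_h >= 12 & n1$time_h <= 84]
  expect_lt(max(abs(diff(diff(seg)))), 0.05)
})

test_that("phase-randomised cohorts vary only in phase and noise", {
  osc <- default_oscillator_params("Ca")
  rep_ <- default_reporter_params("Ca")
  prot <- build_protocol(0, 35, 0, 288)
  co <- phase_randomized_cohort(osc, rep_, prot, n = 6, seed = 5)
  expect_equal(dplyr::n_distinct(co$slice), 6L)
  per_slice <- co |>
    dplyr::group_by(slice) |>
    dplyr::group_map(function(df, key) {
      dt <- detrend_running_average(compute_dff(df$Ca), df$time_h)
      pk <- detect_peaks(dt)
      c(period = estimate_period(pk), first = pk$time_h[1])
    })
  periods <- vapply(per_slice, `[[`, numeric(1), "period")
  expect_true(all(abs(periods - 23.2) < 0.2))
  firsts <- vapply(per_slice, `[[`, numeric(1), "first") %% 24
  expect_gt(diff(range(firsts)), 6)   # phases spread out, not aligned
  # reproducibility of the whole cohort
  co2 <- phase_randomized_cohort(osc, rep_, prot, n = 6, seed = 5)
  expect_identical(co$Ca, co2$Ca)
  expect_error(phase_randomized_cohort(osc, rep_, prot, n = 0, seed = 1),
               "positive")
})

test_that("unknown coupling sources and bad steps are rejected", {
  osc <- default_oscillator_params("Ca")
  osc$Ca$coupling <- list(list(source = "Vip", gain = 0.1, phase_lag_h = 0))
  prot <- build_protocol(0, 35, 0, 48)
  rep_ <- default_reporter_params("Ca")
  expect_error(simulate_network(osc, rep_, prot, seed = 1), "Vip")
  osc2 <- default_oscillator_params("Ca")
  expect_error(simulate_network(osc2, rep_, prot, step_h = 0.3, seed = 1),
               "divide")
})
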