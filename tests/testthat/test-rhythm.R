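test_that("dF/F0 uses the recording minimum and is scale-invariant", {
  expect_equal(compute_dff(c(100, 150, 100)), c(0, 50, 0))
  expect_equal(compute_dff(rep(7, 10)), rep(0, 10))
  x <- c(2, 3, 5, 4, 2.5)
  expect_equal(compute_dff(x), compute_dff(13 * x))
  expect_equal(min(compute_dff(x)), 0)
  expect_error(compute_dff(c(1, 0, 2)), "strictly positive")
  expect_error(compute_dff(c(1, -3, 2)), "strictly positive")
})

test_that("running-average detrend matches a brute-force window loop", {
  set.seed(42)
  tr <- cosine_trace(120, period_h = 24)
  y <- tr$values + 0.05 * tr$time_h + rnorm(nrow(tr), 0, 0.2)
  dt <- detrend_running_average(y, tr$time_h, 24)
  expect_equal(dt$trend, brute_running_mean(y, tr$time_h, 24),
               tolerance = 1e-9)
  expect_equal(dt$detrended, y - brute_running_mean(y, tr$time_h, 24),
               tolerance = 1e-9)
})

test_that("detrending removes ramps, preserves 24-h cosines and is idempotent", {
  tr <- cosine_trace(120, period_h = 24)
  # linear ramp: interior (full-window) points detrend to exactly zero
  ramp <- 3 * tr$time_h
  dt <- detrend_running_average(ramp, tr$time_h, 24)
  interior <- tr$time_h >= 12 & tr$time_h <= 108
  expect_equal(dt$detrended[interior], rep(0, sum(interior)), tolerance = 1e-9)
  # pure 24-h cosine at 1-h sampling: moving mean ~ 0 on the interior
  dtc <- detrend_running_average(tr$values, tr$time_h, 24)
  expect_equal(dtc$detrended[interior], tr$values[interior], tolerance = 1e-6)
  # cosine + ramp recovers the cosine on the interior
  dtm <- detrend_running_average(tr$values + ramp, tr$time_h, 24)
  expect_equal(dtm$detrended[interior], tr$values[interior], tolerance = 1e-6)
  # idempotence on the interior
  dd <- detrend_running_average(dtm$detrended, tr$time_h, 24)
  core <- tr$time_h >= 24 & tr$time_h <= 96
  expect_equal(dd$detrended[core], dtm$detrended[core], tolerance = 1e-9)
  expect_error(detrend_running_average(1:5, 0:4, 240), "longer")
})

test_that("peak detection finds circadian peaks and honours its contracts", {
  tr <- cosine_trace(96, period_h = 24, phase_h = 0)
  dt <- tibble::tibble(time_h = tr$time_h, detrended = tr$values)
  pk <- detect_peaks(dt)
  # peaks at 24/48/72 h (edge-excluded boundary peaks at 0 and 96 dropped)
  expect_equal(pk$time_h, c(24, 48, 72), tolerance = 1e-6)
  expect_true(all(diff(pk$time_h) >= 16))

  flat <- tibble::tibble(time_h = 0:96, detrended = rep(0, 97))
  expect_equal(nrow(detect_peaks(flat)), 0L)

  # cross-check against an exhaustive scan of local maxima on a simulated
  # trace: every reported peak must sit within one sample of some raw
  # local maximum of the smoothed series
  tr2 <- sim_ca(35, 0, seed = 3, cold_h = 0, pre_h = 0, post_h = 288)
  dt2 <- detrend_running_average(compute_dff(tr2$Ca), tr2$time_h)
  pk2 <- detect_peaks(dt2)
  expect_gte(nrow(pk2), 10L)
  expect_lte(nrow(pk2), 12L)
  sm <- brute_running_mean(dt2$detrended, dt2$time_h, 3)
  raw_max <- which(diff(sign(diff(sm))) < 0) + 1L
  nearest <- vapply(pk2$time_h,
                    function(t) min(abs(dt2$time_h[raw_max] - t)), numeric(1))
  expect_true(all(nearest <= 1))
  expect_true(all(abs(diff(pk2$time_h) - 23.2) < 0.5))
})

test_that("period estimation averages successive intervals within the window", {
  pk <- structure(tibble::tibble(time_h = c(2, 26, 50), value = c(1, 1, 1)),
                  class = c("peak_set", class(tibble::tibble())))
  expect_equal(estimate_period(pk), 24)
  expect_equal(estimate_period(pk, c(0, 20)), NA_real_)   # single peak inside
  one <- tibble::tibble(time_h = 0, value = 1)
  expect_true(is.na(estimate_period(one)))
})

test_that("amplitude estimation is linear and exact on cosines", {
  tr <- cosine_trace(120, period_h = 24, amplitude = 5)
  dt <- tibble::tibble(time_h = tr$time_h, detrended = tr$values)
  a1 <- estimate_amplitude(dt, c(12, 108))
  expect_equal(a1, 5, tolerance = 0.01)
  dt2 <- dt
  dt2$detrended <- 3 * dt$detrended
  expect_equal(estimate_amplitude(dt2, c(12, 108)), 3 * a1, tolerance = 1e-9)
  expect_equal(normalize_amplitude(15, 30), 0.5)
  expect_error(normalize_amplitude(15, 0), "positive")
  flat <- tibble::tibble(time_h = 0:120, detrended = rep(0, 121))
  expect_true(is.na(estimate_amplitude(flat)))
})

test_that("baseline level reports the trend mean of dF/F0", {
  t <- 0:120
  expect_equal(baseline_level(rep(50, 121), t), 50)
  cosine <- 10 * cos(2 * pi * t / 24)
  expect_lt(abs(baseline_level(cosine, t, c(24, 96))), 0.2)
})

test_that("rhythmicity calls cosines rhythmic and white noise not", {
  tr <- cosine_trace(96, period_h = 24)
  dt <- tibble::tibble(time_h = tr$time_h, detrended = tr$values)
  verdict <- is_rhythmic(dt)
  expect_true(verdict$rhythmic)
  # acf normalisation caps the score near (n - lag)/n for a perfect rhythm
  expect_gt(verdict$rhythm_score, 0.7)

  # false-positive rate on white noise < 5 % over 100 seeds
  fp <- vapply(1:100, function(s) {
    set.seed(s)
    noise <- tibble::tibble(time_h = 0:96, detrended = rnorm(97))
    is_rhythmic(noise)$rhythmic
  }, logical(1))
  expect_lt(mean(fp), 0.05)
  expect_error(is_rhythmic(dt, c(0, 40)), "48")
})

test_that("restart phase follows the first/second-peak convention", {
  mk <- function(times) tibble::tibble(time_h = times, value = 1)
  expect_equal(restart_phase(mk(c(192 + 14, 192 + 37)), 192), 14)
  expect_equal(restart_phase(mk(c(192 + 5, 192 + 28.8)), 192,
                             skip_first = TRUE), 4.8)
  expect_error(restart_phase(mk(192 + 5), 192, skip_first = TRUE),
               "insufficient")
  expect_error(restart_phase(mk(c(10, 20)), 192), "insufficient")
})

test_that("quantify_trace summarises windows consistently", {
  tr <- sim_ca(15, 96, seed = 4)
  q <- quantify_trace(tr)
  expect_setequal(unique(q$channel), "Ca")
  expect_equal(nrow(q), 3L)                 # three 96-h windows
  expect_equal(q$amplitude_norm[1], 1)
  expect_true(q$rhythmic[1])                # warm pre-segment
  expect_false(q$rhythmic[2])               # 15 degC segment
  expect_true(all(q$baseline_pct >= 0))
  expect_equal(q$temp_C, c(35, 15, 35))
})
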