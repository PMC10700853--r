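#' Fluorescence change relative to the recording minimum
#'
#' `dF/F0 = 100 * (F(t) - F0) / F0` with `F0` the minimum fluorescence of
#' the whole recording (ties broken by first occurrence). The minimum of
#' the output is therefore exactly 0 %.
#'
#' @param trace_values Strictly positive fluorescence values.
#' @return Numeric vector of dF/F0 values in percent.
#' @examples
#' compute_dff(c(100, 150, 100))  # 0, 50, 0
#' @export
compute_dff <- function(trace_values) {
  if (!is.numeric(trace_values) || !length(trace_values)) {
    stop("trace_values must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(trace_values))) stop("non-finite fluorescence", call. = FALSE)
  f0 <- min(trace_values)
  if (f0 <= 0) stop("fluorescence must be strictly positive (F0 would be <= 0)",
                    call. = FALSE)
  100 * (trace_values - f0) / f0
}

#' 24-h running-average detrending
#'
#' Subtracts a centred moving mean over `window_h` from the series. The
#' window is the classical even-order centred average (endpoints
#' half-weighted, as in seasonal decomposition), which removes a cosine of
#' period `window_h` exactly at uniform sampling. Edges use shrinking
#' (truncated) centred windows so the output has the same length as the
#' input.
#'
#' @param values Numeric series, uniformly sampled.
#' @param time_h Sampling times in hours (uniform grid).
#' @param window_h Averaging window, hours; must be a multiple of the
#'   sampling step. Default 24.
#' @return A tibble (class `detrended_trace`) with columns `time_h`,
#'   `detrended` and `trend`.
#' @export
detrend_running_average <- function(values, time_h, window_h = 24) {
  n <- length(values)
  stopifnot(length(time_h) == n, n >= 2L)
  step <- time_h[2L] - time_h[1L]
  if (max(abs(diff(time_h) - step)) > 1e-6) {
    stop("time grid is not uniform", call. = FALSE)
  }
  if (abs(window_h / step - round(window_h / step)) > 1e-9) {
    stop("window_h must be a multiple of the sampling step", call. = FALSE)
  }
  if (window_h > time_h[n] - time_h[1L]) {
    stop("window longer than the series", call. = FALSE)
  }
  trend <- running_mean(values, window_h / (2 * step))
  structure(tibble::tibble(time_h = time_h, detrended = values - trend,
                           trend = trend),
            window_h = window_h,
            class = c("detrended_trace", class(tibble::tibble())))
}

# centred moving mean with half-width w samples, shrinking (truncated) at
# the edges. Integer w gives the classical even-order centred average with
# half-weighted endpoints (a 2w-point window symmetrised over 2w+1 samples,
# as in seasonal decomposition), which annihilates a discrete cosine of
# period 2w exactly; half-integer w gives the plain odd-point window.
running_mean <- function(values, w) {
  n <- length(values)
  if (abs(w - round(w)) < 1e-9) {
    w <- round(w)
    offs <- seq.int(-w, w)
    wts <- c(0.5, rep(1, max(2 * w - 1, 0)), 0.5)
    if (w == 0) { offs <- 0L; wts <- 1 }
  } else {
    m <- floor(w)
    offs <- seq.int(-m, m)
    wts <- rep(1, 2 * m + 1)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- i + offs
    ok <- idx >= 1L & idx <= n
    out[i] <- sum(values[idx[ok]] * wts[ok]) / sum(wts[ok])
  }
  out
}

#' Detect circadian peaks
#'
#' Smooths the series with a centred moving mean over `smooth_h`, finds
#' local maxima, keeps them greedily in decreasing order of height subject
#' to a minimum separation, and refines each kept peak to sub-sample
#' resolution by a quadratic through the three smoothed points around it.
#'
#' @param detrended A [detrend_running_average()] result, or a tibble with
#'   `time_h` and `detrended` columns.
#' @param min_separation_h Minimum distance between accepted peaks, hours.
#' @param smooth_h Smoothing span, hours.
#' @param channel Optional channel label carried into the result.
#' @param edge_exclusion_h Candidate peaks closer than this to the ends
#'   of the series are discarded (default 12 h, half the standard
#'   detrending window, where the truncated running mean distorts peak
#'   positions). A length-2 vector gives separate exclusions for the
#'   start and end of the series.
#' @return A tibble (class `peak_set`) with columns `time_h` and `value`,
#'   ordered by time; empty when the series has no interior local maxima.
#' @export
detect_peaks <- function(detrended, min_separation_h = 16, smooth_h = 3,
                         channel = NA_character_, edge_exclusion_h = 12) {
  stopifnot(all(c("time_h", "detrended") %in% names(detrended)))
  tt <- detrended$time_h
  y <- detrended$detrended
  n <- length(y)
  step <- if (n > 1) tt[2L] - tt[1L] else 1
  ys <- running_mean(y, smooth_h / (2 * step))

  empty <- structure(
    tibble::tibble(time_h = numeric(0), value = numeric(0)),
    channel = channel, min_separation_h = min_separation_h,
    smooth_h = smooth_h, class = c("peak_set", class(tibble::tibble())))
  if (n < 3L) return(empty)

  mid <- 2:(n - 1L)
  is_max <- ys[mid] > ys[mid - 1L] & ys[mid] >= ys[mid + 1L]
  cand <- mid[is_max]
  excl <- rep_len(edge_exclusion_h, 2L)
  cand <- cand[tt[cand] - tt[1L] >= excl[1L] & tt[n] - tt[cand] >= excl[2L]]
  if (!length(cand)) return(empty)

  cand <- cand[order(ys[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(tt[i] - tt[kept]) >= min_separation_h)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)

  # sub-sample refinement: position from a quadratic through the three
  # smoothed points; value from the parabola through the unsmoothed points
  # at that position (the smoothed apex is attenuated by the smoothing
  # window, which would bias amplitude estimates low)
  refine <- function(i) {
    y1 <- ys[i - 1L]; y2 <- ys[i]; y3 <- ys[i + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y1 - y3) / denom
    delta <- max(min(delta, 0.5), -0.5)
    r1 <- y[i - 1L]; r2 <- y[i]; r3 <- y[i + 1L]
    val <- r2 + 0.5 * (r3 - r1) * delta + 0.5 * (r1 - 2 * r2 + r3) * delta^2
    c(tt[i] + delta * step, val)
  }
  ref <- vapply(kept, refine, numeric(2))
  structure(
    tibble::tibble(time_h = ref[1, ], value = ref[2, ]),
    channel = channel, min_separation_h = min_separation_h,
    smooth_h = smooth_h, class = c("peak_set", class(tibble::tibble())))
}

peaks_in_window <- function(peaks, window) {
  peaks$time_h[peaks$time_h >= window[1] & peaks$time_h <= window[2]]
}

#' Period from successive peak intervals
#'
#' Mean of successive peak-time differences among the peaks falling inside
#' the window.
#'
#' @param peaks A [detect_peaks()] result.
#' @param window Numeric `(start_h, end_h)`; default spans all peaks.
#' @return Period in hours, or `NA` when fewer than two peaks fall inside
#'   the window (undefined period, distinct from zero).
#' @export
estimate_period <- function(peaks, window = c(-Inf, Inf)) {
  pt <- peaks_in_window(peaks, window)
  if (length(pt) < 2L) return(NA_real_)
  mean(diff(pt))
}

#' Rhythm amplitude from detrended peaks and troughs
#'
#' Amplitude is the mean over cycles of (peak - trough)/2 of the detrended
#' series within the window, computed as (mean peak value - mean trough
#' value)/2 with troughs detected as peaks of the negated series.
#'
#' @inheritParams detect_peaks
#' @param window Numeric `(start_h, end_h)` evaluation window.
#' @return Amplitude in the units of the detrended input (percent dF/F0 in
#'   the standard pipeline), or `NA` when no full cycle lies in the window.
#' @export
estimate_amplitude <- function(detrended, window = c(-Inf, Inf),
                               min_separation_h = 16, smooth_h = 3) {
  pk <- detect_peaks(detrended, min_separation_h, smooth_h)
  neg <- detrended
  neg$detrended <- -neg$detrended
  tr <- detect_peaks(neg, min_separation_h, smooth_h)
  pv <- pk$value[pk$time_h >= window[1] & pk$time_h <= window[2]]
  tv <- -tr$value[tr$time_h >= window[1] & tr$time_h <= window[2]]
  if (!length(pv) || !length(tv)) return(NA_real_)
  (mean(pv) - mean(tv)) / 2
}

#' Normalise an amplitude by its pre-condition value
#'
#' @param amp Amplitude in the condition of interest.
#' @param amp_pre Amplitude before the temperature change.
#' @return Dimensionless ratio `amp / amp_pre`.
#' @export
normalize_amplitude <- function(amp, amp_pre) {
  if (any(amp_pre <= 0, na.rm = TRUE)) {
    stop("pre-condition amplitude must be positive", call. = FALSE)
  }
  amp / amp_pre
}

#' Baseline level of a dF/F0 series
#'
#' Mean of the 24-h running average (the slow trend, oscillation removed)
#' of the dF/F0 series over the window.
#'
#' @param dff_values dF/F0 series in percent.
#' @param time_h Sampling times, hours.
#' @param window Numeric `(start_h, end_h)`.
#' @param window_h Running-average span for the trend, hours.
#' @return Baseline level in percent.
#' @export
baseline_level <- function(dff_values, time_h, window = range(time_h),
                           window_h = 24) {
  dt <- detrend_running_average(dff_values, time_h, window_h)
  sel <- dt$time_h >= window[1] & dt$time_h <= window[2]
  if (!any(sel)) stop("window contains no samples", call. = FALSE)
  mean(dt$trend[sel])
}

#' Rhythmicity verdict
#'
#' Scores rhythmicity as the maximum autocorrelation of the detrended
#' series at circadian lags (20--28 h) within the window; the series is
#' called rhythmic when the score is at least `score_min` (default 0.3,
#' calibrated to keep the false-positive rate on white noise under 5 %)
#' and at least two peaks are detected in the window.
#'
#' @inheritParams estimate_amplitude
#' @param score_min Minimum circadian autocorrelation to call rhythmicity.
#' @return A one-row tibble with `rhythmic` (logical) and `rhythm_score`.
#' @export
is_rhythmic <- function(detrended, window = c(-Inf, Inf), score_min = 0.3,
                        min_separation_h = 16, smooth_h = 3) {
  sel <- detrended$time_h >= window[1] & detrended$time_h <= window[2]
  y <- detrended$detrended[sel]
  tt <- detrended$time_h[sel]
  if (length(y) < 2L || (tt[length(tt)] - tt[1L]) < 48) {
    stop("rhythmicity window must span at least 48 h", call. = FALSE)
  }
  step <- tt[2L] - tt[1L]
  lags <- seq(ceiling(20 / step), floor(28 / step))
  ac <- stats::acf(y, lag.max = max(lags), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  score <- max(ac[lags + 1L])
  pk <- detect_peaks(detrended[sel, , drop = FALSE], min_separation_h, smooth_h)
  tibble::tibble(rhythmic = score >= score_min && nrow(pk) >= 2L,
                 rhythm_score = score)
}

#' Phase of the rhythm restart after rewarming
#'
#' Phase (in hours on the 24-h circle) of the first -- or, for
#' transcription reporters whose first post-rewarming peak can reflect an
#' acute brightness response, the second -- detected peak after the
#' rewarming time.
#'
#' @param peaks A [detect_peaks()] result.
#' @param rewarm_time_h Time of rewarming, hours.
#' @param skip_first Use the second peak after rewarming instead of the
#'   first (convention: `TRUE` for transcription channels, `FALSE` for Ca).
#' @return Phase in `[0, 24)` hours relative to `rewarm_time_h`.
#' @export
restart_phase <- function(peaks, rewarm_time_h, skip_first = FALSE) {
  after <- sort(peaks$time_h[peaks$time_h > rewarm_time_h])
  need <- if (skip_first) 2L else 1L
  if (length(after) < need) {
    stop("insufficient peaks after rewarming (need ", need, ", found ",
         length(after), ")", call. = FALSE)
  }
  (after[need] - rewarm_time_h) %% 24
}

#' Quantify one recording
#'
#' Full per-trace pipeline: dF/F0 per channel, 24-h running-average
#' detrending, peak detection, then per-window period, amplitude
#' (normalised to the first window), baseline level and rhythmicity.
#' Windows default to the protocol's temperature segments split into
#' 4-day (96-h) blocks, mirroring the standard chilling schedule.
#'
#' @param trace An `scn_trace` or tibble with `time_h`, `temp_C` and one
#'   column per channel.
#' @param channels Channels to analyse; defaults to every non-time,
#'   non-temperature column.
#' @param windows Optional list of `(start_h, end_h)` windows.
#' @param min_separation_h,smooth_h Peak-detection settings.
#' @return A tibble with one row per (channel, window): `channel`,
#'   `window_start_h`, `window_end_h`, `temp_C`, `period_h`,
#'   `amplitude_pct`, `amplitude_norm`, `baseline_pct`, `rhythmic`,
#'   `rhythm_score`.
#' @export
quantify_trace <- function(trace, channels = NULL, windows = NULL,
                           min_separation_h = 16, smooth_h = 3) {
  stopifnot(all(c("time_h", "temp_C") %in% names(trace)))
  if (is.null(channels)) {
    channels <- setdiff(names(trace), c("time_h", "temp_C", "slice"))
  }
  if (is.null(windows)) windows <- default_windows(trace)

  purrr::map_dfr(channels, function(ch) {
    dff <- compute_dff(trace[[ch]])
    dt <- detrend_running_average(dff, trace$time_h)
    pk <- detect_peaks(dt, min_separation_h, smooth_h, channel = ch)
    rows <- purrr::map_dfr(windows, function(w) {
      rhy <- is_rhythmic(dt, w, min_separation_h = min_separation_h,
                         smooth_h = smooth_h)
      tibble::tibble(
        channel = ch,
        window_start_h = w[1],
        window_end_h = w[2],
        temp_C = stats::median(trace$temp_C[trace$time_h >= w[1] &
                                              trace$time_h <= w[2]]),
        period_h = estimate_period(pk, w),
        amplitude_pct = estimate_amplitude(dt, w, min_separation_h, smooth_h),
        baseline_pct = baseline_level(dff, trace$time_h, w),
        rhythmic = rhy$rhythmic,
        rhythm_score = rhy$rhythm_score)
    })
    dplyr::mutate(rows,
                  amplitude_norm = .data$amplitude_pct / .data$amplitude_pct[1L],
                  .after = "amplitude_pct")
  })
}

# split each constant-temperature segment into 96-h blocks
default_windows <- function(trace) {
  bounds <- c(trace$time_h[1L],
              trace$time_h[which(diff(trace$temp_C) != 0) + 1L],
              trace$time_h[nrow(trace)])
  windows <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    starts <- seq(bounds[i], bounds[i + 1L] - 48, by = 96)
    for (s in starts) windows <- c(windows, list(c(s, min(s + 96, bounds[i + 1L]))))
  }
  windows
}

#' Quantify a cohort of recordings
#'
#' Applies [quantify_trace()] per slice of a long cohort tibble (as
#' produced by [phase_randomized_cohort()]).
#'
#' @param cohort Tibble with a `slice` column plus trace columns.
#' @inheritParams quantify_trace
#' @return Per-slice quantification tibble with a leading `slice` column.
#' @export
quantify_cohort <- function(cohort, channels = NULL, windows = NULL, ...) {
  stopifnot("slice" %in% names(cohort))
  cohort |>
    dplyr::group_by(.data$slice) |>
    dplyr::group_modify(function(df, key) {
      quantify_trace(df, channels = channels, windows = windows, ...)
    }) |>
    dplyr::ungroup()
}

#' Post-rewarming restart phases across a cohort
#'
#' @param cohort Long cohort tibble (see [phase_randomized_cohort()]).
#' @param channel Channel to analyse.
#' @param rewarm_time_h Rewarming time, hours.
#' @param skip_first Use the second post-rewarming peak (default `TRUE`
#'   for channels other than `"Ca"`).
#' @param guard_h Hours after rewarming excluded from peak search: the
#'   step in reporter brightness and the relaxing baseline produce an
#'   acute non-circadian transient right at the temperature step, which
#'   must not be mistaken for (or suppress, via the minimum-separation
#'   rule) a genuine circadian peak. Default 3 h, just above the baseline
#'   relaxation time.
#' @return Tibble with `slice` and `phase_h`.
#' @export
cohort_restart_phases <- function(cohort, channel, rewarm_time_h,
                                  skip_first = !identical(channel, "Ca"),
                                  guard_h = 3) {
  stopifnot(all(c("slice", "time_h", channel) %in% names(cohort)))
  cohort |>
    dplyr::group_by(.data$slice) |>
    dplyr::group_modify(function(df, key) {
      # quantify the rewarmed segment on its own: a running mean spanning
      # the temperature step would be contaminated by the cold-segment
      # brightness change for half a window on either side
      post <- df[df$time_h >= rewarm_time_h + guard_h, , drop = FALSE]
      dt <- detrend_running_average(compute_dff(post[[channel]]), post$time_h)
      pk <- detect_peaks(dt, channel = channel, edge_exclusion_h = c(0, 12))
      tibble::tibble(phase_h = restart_phase(pk, rewarm_time_h, skip_first))
    }) |>
    dplyr::ungroup()
}
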