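# Circular statistics on the 24-h circle. Phases are handled in hours;
# internally they are mapped to angles via theta = 2*pi*phase/24.

hours_to_rad <- function(h) 2 * pi * (h %% 24) / 24
rad_to_hours <- function(theta) {
  h <- (theta * 24 / (2 * pi)) %% 24
  # guard against 24 - eps artefacts from the modulo of tiny negatives
  ifelse(24 - h < 1e-9, 0, h)
}

#' Circular mean and resultant length of 24-h phases
#'
#' Computes the mean resultant vector of the phases on the 24-h circle:
#' `R` is its length and the circular mean phase its direction. When
#' `R` is numerically zero the mean direction is undefined and reported
#' as `NA`.
#'
#' @param phases_h Phases in hours (any real values; reduced mod 24).
#' @return A one-row tibble (class `circular_summary`) with `n`,
#'   `mean_phase_h`, `resultant_r`, `circ_sd_h`, `rayleigh_z`,
#'   `rayleigh_p` and `mean_defined`.
#' @examples
#' circular_mean(c(23, 1))   # mean 0 h, R = cos(pi/12)
#' @export
circular_mean <- function(phases_h) {
  n <- length(phases_h)
  if (n < 1L) stop("need at least one phase", call. = FALSE)
  theta <- hours_to_rad(phases_h)
  C <- mean(cos(theta)); S <- mean(sin(theta))
  R <- sqrt(C^2 + S^2)
  defined <- R > sqrt(.Machine$double.eps)
  mean_h <- if (defined) rad_to_hours(atan2(S, C)) else NA_real_
  sd_h <- if (R > 0) sqrt(-2 * log(R)) * 24 / (2 * pi) else Inf
  z <- n * R^2
  p <- rayleigh_p_value(n, R)
  structure(tibble::tibble(n = n, mean_phase_h = mean_h, resultant_r = R,
                           circ_sd_h = sd_h, rayleigh_z = z, rayleigh_p = p,
                           mean_defined = defined),
            class = c("circular_summary", class(tibble::tibble())))
}

#' Circular standard deviation in hours
#'
#' `sqrt(-2 ln R) * 24 / (2 pi)` where `R` is the mean resultant length.
#' Returns `Inf` (infinite dispersion) when `R` is numerically zero.
#'
#' @param phases_h Phases in hours (n >= 2).
#' @return Circular SD in hours.
#' @export
circular_sd <- function(phases_h) {
  if (length(phases_h) < 2L) stop("need at least two phases", call. = FALSE)
  cs <- circular_mean(phases_h)
  if (!cs$mean_defined) return(Inf)
  cs$circ_sd_h
}

#' Rayleigh test of circular uniformity
#'
#' Test statistic `z = n R^2`; the p value uses the standard series
#' approximation `p = exp(sqrt(1 + 4n + 4(n^2 - z^2)) - (1 + 2n))`,
#' clamped to (0, 1].
#'
#' @param phases_h Phases in hours; at least 3 for a meaningful p value.
#' @return A one-row tibble with `n`, `resultant_r`, `rayleigh_z`,
#'   `rayleigh_p`.
#' @export
rayleigh_test <- function(phases_h) {
  cs <- circular_mean(phases_h)
  if (cs$n < 3L) warning("Rayleigh p value is unreliable for n < 3")
  cs[, c("n", "resultant_r", "rayleigh_z", "rayleigh_p")]
}

rayleigh_p_value <- function(n, R) {
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - z^2)) - (1 + 2 * n))
  min(max(p, .Machine$double.xmin), 1)
}

#' Circular phase difference between two peak series
#'
#' For each peak of `peaks_a`, takes the circular difference (on the 24-h
#' circle) to a matched peak of `peaks_b`, then averages the differences
#' circularly. With `pairing = "forward"` (default) each `a` peak is
#' matched to the next `b` peak at or after it, so the result is the
#' delay of rhythm `b` after rhythm `a` -- the convention in which
#' phase relations such as an anti-phasic 13.2-h offset are reported.
#' With `pairing = "nearest"` the nearest-in-time `b` peak is used; on
#' rhythms whose period differs from 24 h the two conventions disagree.
#'
#' @param peaks_a,peaks_b [detect_peaks()] results (or tibbles with a
#'   `time_h` column).
#' @param window Optional `(start_h, end_h)` evaluation window applied to
#'   `peaks_a`.
#' @param pairing `"forward"` or `"nearest"` peak matching.
#' @return Mean difference `b - a` in hours, in `[0, 24)`.
#' @export
phase_difference <- function(peaks_a, peaks_b, window = c(-Inf, Inf),
                             pairing = c("forward", "nearest")) {
  pairing <- match.arg(pairing)
  ta <- peaks_a$time_h[peaks_a$time_h >= window[1] & peaks_a$time_h <= window[2]]
  tb <- peaks_b$time_h
  if (!length(ta) || !length(tb)) stop("empty peak set", call. = FALSE)
  if (pairing == "forward") {
    ta <- ta[ta <= max(tb)]
    if (!length(ta)) stop("no a-peaks precede the last b-peak", call. = FALSE)
    d <- vapply(ta, function(t) min(tb[tb >= t]) - t, numeric(1))
  } else {
    d <- vapply(ta, function(t) tb[which.min(abs(tb - t))] - t, numeric(1))
  }
  cs <- circular_mean(d)
  if (!cs$mean_defined) {
    stop("phase differences balance out; mean difference undefined",
         call. = FALSE)
  }
  cs$mean_phase_h
}

#' Summarise phases of a cohort
#'
#' Convenience wrapper: takes a tibble with a phase column (e.g. from
#' [cohort_restart_phases()]) and returns the circular summary.
#'
#' @param data Tibble containing the phases.
#' @param phase_col Name of the phase column. Default `"phase_h"`.
#' @return A `circular_summary` tibble.
#' @export
circular_summary <- function(data, phase_col = "phase_h") {
  stopifnot(phase_col %in% names(data))
  circular_mean(data[[phase_col]])
}

#' Rayleigh plot of 24-h phases
#'
#' Polar plot on a 24-h dial with 0 h at the top and hours increasing
#' clockwise: individual phases as dots on the rim and the mean resultant
#' vector as an arrow of length `R` from the centre.
#'
#' @param phases_h Phases in hours (non-empty).
#' @param summary Optional precomputed [circular_mean()] result.
#' @return A ggplot object.
#' @export
plot_rayleigh <- function(phases_h, summary = NULL) {
  if (!length(phases_h)) stop("no phases to plot", call. = FALSE)
  if (is.null(summary)) summary <- circular_mean(phases_h)
  pts <- tibble::tibble(phase_h = phases_h %% 24, r = 1)
  arrow_df <- tibble::tibble(phase_h = summary$mean_phase_h,
                             r = summary$resultant_r)
  pl <- ggplot2::ggplot(pts, ggplot2::aes(.data$phase_h, .data$r)) +
    ggplot2::geom_point(size = 2, shape = 21, fill = "white") +
    ggplot2::coord_polar(theta = "x", start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = c(0, 6, 12, 18),
                                minor_breaks = 0:23) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = "phase (h)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (isTRUE(summary$mean_defined)) {
    pl <- pl + ggplot2::geom_segment(
      data = arrow_df,
      ggplot2::aes(x = .data$phase_h, xend = .data$phase_h, y = 0,
                   yend = .data$r),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.25, "cm")),
      linewidth = 0.8)
  }
  pl
}

#' Export a Rayleigh plot to file
#'
#' @inheritParams plot_rayleigh
#' @param path Output file (format from extension, e.g. `.svg`, `.png`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
export_rayleigh_plot <- function(phases_h, path, summary = NULL,
                                 width = 4, height = 4) {
  pl <- plot_rayleigh(phases_h, summary)
  ggplot2::ggsave(path, pl, width = width, height = height)
  invisible(path)
}

#' @export
autoplot.circular_summary <- function(object, phases_h, ...) {
  plot_rayleigh(phases_h, summary = object)
}
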