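#' Simulate a multi-channel fluorescence recording
#'
#' Integrates one Stuart-Landau oscillator per channel,
#' `dz/dt = lambda (mu(T) - |z|^2) z + i omega(T) z + lambda (forcing)`,
#' with piecewise-constant temperature from `protocol`, then passes the
#' states through the reporter model
#' `F(t) = fp_gain(T) * drift(t) * (B(t) + amp_scale * Re z) + noise`.
#'
#' Above the Hopf point (`mu > 0`) the oscillation settles on a limit
#' cycle of radius `sqrt(mu)` at the intrinsic period; below it
#' (`mu <= 0`) the angular frequency is frozen and the state relaxes
#' toward a displaced fixed point on the positive real axis (the cold
#' "parking" state), realised by a constant forcing
#' `max(-mu, 0) * park`. The slow baseline `B(t)` relaxes toward
#' `baseline_level(T)` with time constant `baseline_tau_h` after each
#' temperature step. Coupling between channels is weak additive forcing
#' of the source state rotated by `-omega * phase_lag_h`.
#'
#' Integration is fixed-step classical Runge-Kutta (RK4) at `step_h`,
#' decimated to the 1-h observation grid; additive Gaussian noise is
#' applied on the observation grid only, so a `noise_sd` of zero yields
#' a smooth deterministic trace.
#'
#' @param osc Oscillator parameters, see [default_oscillator_params()].
#' @param rep Reporter parameters, see [default_reporter_params()].
#' @param protocol A [temperature_protocol][build_protocol].
#' @param step_h Internal integration step, hours (must be <= 1 and divide
#'   the 1-h sampling interval). Default 0.1.
#' @param seed Integer seed; the trace is bit-reproducible given
#'   (parameters, protocol, seed).
#' @param slice Slice identifier stored in the trace metadata.
#' @return A tibble of class `scn_trace` with columns `time_h`, `temp_C`
#'   and one fluorescence column per channel; attributes `slice`, `seed`
#'   and `params_hash`.
#' @examples
#' prot <- build_protocol(96, 15, 96, 96)
#' tr <- simulate_network(default_oscillator_params("Ca"),
#'                        default_reporter_params("Ca"), prot, seed = 1)
#' @export
simulate_network <- function(osc, rep, protocol, step_h = 0.1, seed = 1L,
                             slice = "slice1") {
  stopifnot(inherits(protocol, "temperature_protocol"))
  channels <- names(osc)
  if (is.null(channels) || !length(channels)) stop("osc has no channels", call. = FALSE)
  if (!setequal(channels, names(rep))) {
    stop("oscillator and reporter channel sets differ", call. = FALSE)
  }
  for (ch in channels) {
    for (cp in osc[[ch]]$coupling) {
      if (!cp$source %in% channels) {
        stop("coupling source '", cp$source, "' for channel '", ch,
             "' is not a simulated channel", call. = FALSE)
      }
      if (!is.finite(cp$gain) || !is.finite(cp$phase_lag_h)) {
        stop("non-finite coupling parameters", call. = FALSE)
      }
    }
  }
  if (step_h > 1 || step_h <= 0) stop("step_h must be in (0, 1]", call. = FALSE)
  n_sub <- round(1 / step_h)
  if (abs(n_sub * step_h - 1) > 1e-9) {
    stop("step_h must divide the 1-h sampling interval", call. = FALSE)
  }

  total_h <- attr(protocol, "total_h")
  time_h <- seq(0, total_h, by = 1)
  n_out <- length(time_h)
  nc <- length(channels)

  # temperature is piecewise constant, so every temperature-dependent
  # coefficient is constant within a protocol segment: precompute them per
  # (sample, channel) from the segment covering each sample
  temp_grid <- protocol_temperature(protocol, pmin(time_h, total_h))
  # coefficients for the interval (t_i, t_{i+1}) come from the segment
  # covering its midpoint; row 1 (initial condition) uses t = 0
  temp_mid <- c(temp_grid[1L],
                protocol_temperature(protocol, utils::head(time_h, -1L) + 0.5))
  lam <- vapply(osc, `[[`, numeric(1), "relaxation_rate")
  tau_b <- vapply(rep, `[[`, numeric(1), "baseline_tau_h")
  mu_g <- vapply(seq_len(nc), function(k) osc[[k]]$mu(temp_mid), numeric(n_out))
  om_g <- vapply(seq_len(nc), function(k) {
    ifelse(mu_g[, k] <= 0, 0, 2 * pi / osc[[k]]$period_h(temp_mid))
  }, numeric(n_out))
  bt_g <- vapply(seq_len(nc), function(k) osc[[k]]$baseline_level(temp_mid),
                 numeric(n_out))
  park <- vapply(osc, `[[`, numeric(1), "park")
  # coupling as an nc x nc complex matrix per sample row would be overkill:
  # gains and sources are fixed, only the rotation e^{-i om lag} varies
  cp_src <- lapply(osc, function(p) match(vapply(p$coupling, `[[`,
                                                character(1), "source"), channels))
  cp_gain <- lapply(osc, function(p) vapply(p$coupling, `[[`, numeric(1), "gain"))
  cp_lag <- lapply(osc, function(p) vapply(p$coupling, `[[`, numeric(1),
                                           "phase_lag_h"))

  # initial conditions at T(0)
  z <- complex(length.out = nc)
  for (k in seq_len(nc)) {
    mu0 <- mu_g[1L, k]
    z[k] <- if (mu0 > 0) {
      sqrt(mu0) * exp(-1i * om_g[1L, k] * osc[[k]]$initial_phase_h)
    } else park[k] + 0i
  }
  B <- bt_g[1L, ]

  states <- matrix(0, n_out, nc)      # Re z on the output grid
  bases <- matrix(0, n_out, nc)
  states[1, ] <- Re(z)
  bases[1, ] <- B
  h <- step_h
  for (i in seq_len(n_out - 1L)) {
    # coefficients of the segment covering (t_i, t_{i+1}); sample i+1 sits
    # on the segment holding just after t_i for all substeps
    mu <- mu_g[i + 1L, ]; om <- om_g[i + 1L, ]; btarget <- bt_g[i + 1L, ]
    lin <- lam * mu + 1i * om
    forcing <- lam * pmax(-mu, 0) * park + 0i
    rot <- purrr::map(seq_len(nc), function(k) {
      lam[k] * cp_gain[[k]] * exp(-1i * om[k] * cp_lag[[k]])
    })
    dz <- function(zv) {
      f <- forcing
      for (k in seq_len(nc)) {
        if (length(cp_src[[k]])) {
          f[k] <- f[k] + sum(rot[[k]] * zv[cp_src[[k]]])
        }
      }
      (lin - lam * Mod(zv)^2) * zv + f
    }
    dB <- function(Bv) (btarget - Bv) / tau_b
    for (s in seq_len(n_sub)) {
      k1z <- dz(z);              k1b <- dB(B)
      k2z <- dz(z + h / 2 * k1z); k2b <- dB(B + h / 2 * k1b)
      k3z <- dz(z + h / 2 * k2z); k3b <- dB(B + h / 2 * k2b)
      k4z <- dz(z + h * k3z);     k4b <- dB(B + h * k3b)
      z <- z + h / 6 * (k1z + 2 * k2z + 2 * k3z + k4z)
      B <- B + h / 6 * (k1b + 2 * k2b + 2 * k3b + k4b)
    }
    states[i + 1L, ] <- Re(z)
    bases[i + 1L, ] <- B
  }

  temp_C <- temp_grid
  out <- tibble::tibble(time_h = time_h, temp_C = temp_C)
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (k in seq_len(nc)) {
    p <- osc[[k]]
    r <- rep[[k]]
    drift <- pmin(1 + r$drift_rate * time_h / 24, 2)
    f <- r$fp_gain(temp_C) * drift * (bases[, k] + p$amp_scale * states[, k])
    if (r$noise_sd > 0) {
      f <- f + stats::rnorm(n_out, 0, r$noise_sd * 2 * p$amp_scale)
    }
    if (any(f <= 0)) stop("simulated fluorescence not strictly positive; ",
                          "check baseline/noise parameters", call. = FALSE)
    out[[channels[k]]] <- f
  }
  new_scn_trace(out, slice = slice, seed = seed,
                params_hash = rlang::hash(list(osc, rep, protocol, step_h)))
}

new_scn_trace <- function(df, slice, seed, params_hash = NULL) {
  structure(df, slice = slice, seed = seed, params_hash = params_hash,
            class = c("scn_trace", class(tibble::tibble())))
}

#' Simulate a cohort of slices with randomised initial phases
#'
#' Generates `n` recordings that differ only in the Ca initial phase
#' (uniform on [0, 24) h; the other channels keep their default offsets
#' from Ca) and in the observation noise stream. This stands in for
#' independent SCN slices entering a temperature protocol at unrelated
#' circadian phases, as needed for phase-resetting analyses.
#'
#' @inheritParams simulate_network
#' @param n Number of slices (>= 1).
#' @return A tibble in long cohort form: columns `slice`, `time_h`,
#'   `temp_C` and one column per channel.
#' @export
phase_randomized_cohort <- function(osc, rep, protocol, n, seed = 1L,
                                    step_h = 0.1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  set.seed(as.integer(seed %% .Machine$integer.max))
  phases <- stats::runif(n, 0, 24)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ref_phase <- osc[[1L]]$initial_phase_h
  traces <- purrr::map(seq_len(n), function(i) {
    osc_i <- osc
    for (ch in names(osc_i)) {
      offset <- (osc[[ch]]$initial_phase_h - ref_phase) %% 24
      osc_i[[ch]]$initial_phase_h <- (phases[i] + offset) %% 24
    }
    tr <- simulate_network(osc_i, rep, protocol, step_h = step_h,
                           seed = seeds[i], slice = sprintf("slice%02d", i))
    dplyr::mutate(tibble::as_tibble(tr), slice = attr(tr, "slice"),
                  .before = 1L)
  })
  dplyr::bind_rows(traces)
}

#' @export
print.scn_trace <- function(x, ...) {
  cat("<scn_trace> slice ", attr(x, "slice"), ", seed ", attr(x, "seed"),
      "\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Plot a simulated or imported trace
#'
#' Line plot of each fluorescence channel over time with the temperature
#' protocol shaded underneath.
#'
#' @param object An `scn_trace` (or any tibble with `time_h`, `temp_C` and
#'   channel columns).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scn_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = -dplyr::any_of(c("time_h", "temp_C", "slice")),
                            names_to = "channel", values_to = "fluorescence")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$fluorescence)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::geom_line(ggplot2::aes(y = .data$temp_C / max(.data$temp_C) *
                                      max(.data$fluorescence)),
                       colour = "steelblue", linetype = 2, alpha = 0.5) +
    ggplot2::labs(x = "time (h)", y = "fluorescence (a.u.)",
                  caption = "dashed: temperature protocol (scaled)")
}
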