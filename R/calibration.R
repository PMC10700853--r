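# Calcium-probe calibration maths: free Ca in EGTA-buffered solutions
# with pH and temperature corrections, log-log Hill linearisation of the
# indicator response, fluorescent-protein brightness correction, and
# absolute Ca estimation.

#' EGTA equilibrium constants
#'
#' Reference association constants for EGTA at 20 degC: proton
#' association constants `logK1`, `logK2`, the primary Ca association
#' constant `logKCa` (all log10 of M^-1), the corresponding reaction
#' enthalpies (kcal/mol), the gas constant (kcal K^-1 mol^-1) and the
#' reference temperature in kelvin.
#'
#' @param logK1,logK2,logKCa,dH_K1,dH_K2,dH_KCa,R,T_ref_K Overrides for
#'   the defaults.
#' @return Named list of constants.
#' @export
egta_constants <- function(logK1 = 9.58, logK2 = 8.96, logKCa = 10.97,
                           dH_K1 = -5.8, dH_K2 = -5.8, dH_KCa = -8.0,
                           R = 1.9872e-3, T_ref_K = 293.15) {
  list(logK1 = logK1, logK2 = logK2, logKCa = logKCa,
       dH_K1 = dH_K1, dH_K2 = dH_K2, dH_KCa = dH_KCa,
       R = R, T_ref_K = T_ref_K)
}

#' Van't Hoff temperature correction of an equilibrium constant
#'
#' Standard isochore:
#' `logK' = logK - (dH / (2.303 R)) * (1/T - 1/T_ref)`,
#' with temperatures in kelvin, so that `logK' = logK` at the reference
#' temperature and, for exothermic binding (`dH < 0`), the constant
#' increases on cooling. `literal_printed = TRUE` instead evaluates the
#' variant form `logK' = logK + dH * (1/T - 1/T_ref) / (2.303 R T)`
#' sometimes seen in print (dimensionally inconsistent; provided only for
#' comparison).
#'
#' @param logK Reference log10 association constant.
#' @param dH Reaction enthalpy, kcal/mol.
#' @param temp_C Target temperature, degC (0--40).
#' @param const Constants from [egta_constants()] (supplies `R`, `T_ref_K`).
#' @param literal_printed Evaluate the non-standard printed form instead.
#' @return Corrected log10 association constant.
#' @examples
#' vant_hoff_correct(10.97, -8.0, 20)  # reference temperature: unchanged
#' vant_hoff_correct(10.97, -8.0, 15)  # larger: exothermic binding, colder
#' @export
vant_hoff_correct <- function(logK, dH, temp_C, const = egta_constants(),
                              literal_printed = FALSE) {
  if (any(temp_C < 0 | temp_C > 40)) {
    stop("temp_C must be within [0, 40]", call. = FALSE)
  }
  T <- temp_C + 273.15
  inv_diff <- 1 / T - 1 / const$T_ref_K
  if (literal_printed) {
    logK + dH * inv_diff / (2.303 * const$R * T)
  } else {
    logK - dH / (2.303 * const$R) * inv_diff
  }
}

#' Effective Kd of EGTA for Ca, corrected for pH and temperature
#'
#' `Kd_EGTA = (1 + 10^(logK1 - pH) + 10^(logK1 + logK2 - 2 pH)) / KCa`,
#' with `K1`, `K2` and `KCa` first Van't-Hoff-corrected to `temp_C`.
#'
#' @param pH Solution pH (6--9).
#' @param temp_C Temperature, degC.
#' @param const Constants from [egta_constants()].
#' @return Effective dissociation constant in molar.
#' @export
egta_kd <- function(pH, temp_C = 20, const = egta_constants()) {
  if (any(pH < 6 | pH > 9)) stop("pH must be within [6, 9]", call. = FALSE)
  k1 <- vant_hoff_correct(const$logK1, const$dH_K1, temp_C, const)
  k2 <- vant_hoff_correct(const$logK2, const$dH_K2, temp_C, const)
  kca <- vant_hoff_correct(const$logKCa, const$dH_KCa, temp_C, const)
  (1 + 10^(k1 - pH) + 10^(k1 + k2 - 2 * pH)) / 10^kca
}

#' Free Ca concentration in an EGTA-buffered solution
#'
#' `[Ca]free = Kd_EGTA(pH, T) * [CaEGTA] / [EGTA]free`, with the bound
#' and free chelator concentrations in any common unit (the ratio is
#' dimensionless).
#'
#' @param ca_egta_mM Ca-bound EGTA concentration, mM.
#' @param egta_free_mM Ca-free EGTA concentration, mM (> 0).
#' @param pH Solution pH.
#' @param temp_C Temperature, degC.
#' @param const Constants from [egta_constants()].
#' @return Free Ca concentration in molar.
#' @export
free_ca <- function(ca_egta_mM, egta_free_mM, pH = 7.2, temp_C = 20,
                    const = egta_constants()) {
  if (any(ca_egta_mM < 0)) stop("ca_egta_mM must be >= 0", call. = FALSE)
  if (any(egta_free_mM <= 0)) {
    stop("egta_free_mM must be strictly positive", call. = FALSE)
  }
  egta_kd(pH, temp_C, const) * ca_egta_mM / egta_free_mM
}

#' Hill fit of an indicator titration by log-log linearisation
#'
#' Plots `log10 {(F - Fmin) / (Fmax - F)}` against `log10 [Ca]free` and
#' fits a least-squares line: the slope is the Hill coefficient and the
#' x-intercept, back-transformed, the apparent Kd. `Fmin`/`Fmax` are the
#' endpoint measurements in Ca-free and Ca-saturating buffer; points with
#' `F` outside `(Fmin, Fmax)` are dropped with a warning.
#'
#' @param ca_free_M Free Ca concentrations, molar (> 0).
#' @param F Fluorescence values, same length.
#' @param f_min,f_max Endpoint fluorescence; default the observed extremes.
#' @return An object of class `hill_fit`: list with `kd_nM`, `hill_n`,
#'   `f_min`, `f_max`, `fit_r2`, `n_points` and the underlying `lm` fit.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' ca <- 10^seq(-8, -6, length.out = 9)
#' f <- 1 + 9 * ca^1.9 / (ca^1.9 + (150e-9)^1.9)
#' hill_fit(ca, f, f_min = 1, f_max = 10)
#' @export
hill_fit <- function(ca_free_M, F, f_min = min(F), f_max = max(F)) {
  stopifnot(length(ca_free_M) == length(F))
  if (f_min >= f_max) stop("f_min must be below f_max", call. = FALSE)
  usable <- F > f_min & F < f_max & ca_free_M > 0
  if (any(!usable)) {
    warning(sum(!usable), " point(s) outside (f_min, f_max) dropped")
  }
  if (sum(usable) < 3L) {
    stop("need at least 3 usable points strictly between f_min and f_max",
         call. = FALSE)
  }
  x <- log10(ca_free_M[usable])
  y <- log10((F[usable] - f_min) / (f_max - F[usable]))
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope <= 0) stop("non-positive Hill slope; data are not sigmoidal",
                       call. = FALSE)
  kd_M <- 10^(-intercept / slope)
  # summary.lm warns on exact fits (noiseless round trips are legitimate)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(kd_nM = kd_M * 1e9, hill_n = slope, f_min = f_min,
                 f_max = f_max, fit_r2 = r2,
                 n_points = sum(usable), lm_fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> Kd = %.4g nM, Hill n = %.3f (R^2 = %.4f, %d points)\n",
              x$kd_nM, x$hill_n, x$fit_r2, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(term = c("kd_nM", "hill_n"),
                 estimate = c(x$kd_nM, x$hill_n))
}

#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$fit_r2, n_points = x$n_points,
                 f_min = x$f_min, f_max = x$f_max)
}

#' Fluorescent-protein-corrected fold change
#'
#' Expresses a cold-induced dF/F0 baseline increase as a multiple of the
#' circadian rhythm amplitude after removing the intrinsic brightness gain
#' of the reporter's fluorescent protein at low temperature:
#' `(dff_cold_pct - fp_gain_increase_pct) / rhythm_amplitude_pct`.
#'
#' @param dff_cold_pct Measured baseline dF/F0 increase in the cold, percent.
#' @param fp_gain_increase_pct Brightness increase of the bare fluorescent
#'   protein at the same temperature, percent.
#' @param rhythm_amplitude_pct Circadian rhythm amplitude, percent (> 0).
#' @return Dimensionless corrected fold change.
#' @examples
#' fp_corrected_fold(196.7, 67.1, 30)  # about 4.3
#' @export
fp_corrected_fold <- function(dff_cold_pct, fp_gain_increase_pct,
                              rhythm_amplitude_pct) {
  if (any(rhythm_amplitude_pct <= 0)) {
    stop("rhythm amplitude must be positive", call. = FALSE)
  }
  (dff_cold_pct - fp_gain_increase_pct) / rhythm_amplitude_pct
}

#' Absolute Ca estimate from a corrected fold change
#'
#' Anchors the corrected fold change to literature basal and peak Ca
#' levels: `estimated = basal + fold * (peak - basal)`.
#'
#' @param corrected_fold Corrected fold change (multiples of the rhythm
#'   amplitude above basal).
#' @param basal_nM,peak_nM Literature basal and peak Ca, nM (`peak > basal`).
#' @return A one-row tibble with `corrected_fold`, `basal_nM`, `peak_nM`
#'   and `estimated_nM`.
#' @examples
#' estimate_absolute_ca(fp_corrected_fold(196.7, 67.1, 30), 172, 218)
#' @export
estimate_absolute_ca <- function(corrected_fold, basal_nM, peak_nM) {
  if (any(peak_nM <= basal_nM)) {
    stop("peak_nM must exceed basal_nM", call. = FALSE)
  }
  tibble::tibble(corrected_fold = corrected_fold, basal_nM = basal_nM,
                 peak_nM = peak_nM,
                 estimated_nM = basal_nM + corrected_fold * (peak_nM - basal_nM))
}
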