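---
title: "Models and methods behind coldclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coldclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldclock)
```

`coldclock` packages three things: a generative model of circadian
fluorescence recordings from SCN slice cultures under temperature
protocols, the estimators used to quantify such recordings, and the
calibration arithmetic that turns indicator fluorescence into Ca²⁺
concentrations. This vignette explains each model, its assumptions, the
defaults and why they were chosen, and what the synthetic data can and
cannot tell you about real recordings.

## The oscillator model

Each reporter channel (cytosolic Ca²⁺ via a jRGECO1a-like indicator,
*Per2* and *Bmal1* transcription via Venus reporters) is modelled as a
Stuart–Landau oscillator — the normal form of a supercritical Hopf
bifurcation:

$$\frac{dz}{dt} = \lambda\,(\mu(T) - |z|^2)\,z + i\,\omega(T)\,z
  + \lambda\,F(z, T), \qquad z \in \mathbb{C}.$$

This is the minimal dynamical system with the observed phenomenology: a
stable limit cycle of radius $\sqrt{\mu}$ whose amplitude shrinks
continuously with the bifurcation parameter, oscillation death when
$\mu$ crosses zero, and damped relaxation toward a fixed point below
the bifurcation. Whether the real cellular oscillator is super- or
subcritical cannot be decided from rhythm recordings alone; we assume
the supercritical form because the observed amplitude decline with
cooling is gradual, and make no claim beyond that.

**Temperature maps.** $\mu(T)$ is piecewise linear through
$(35, 1.0)$, $(22, 0.15)$, $(18.5, 0)$, $(15, -0.3)$ (°C,
dimensionless), placing the Hopf point between 22 °C and 15 °C, where
rhythm suspension is observed. The intrinsic period lengthens with
cooling (Ca²⁺: 23.2 h at 35 °C, 23.9 h at 28 °C, 25.3 h at 22 °C;
*Bmal1* lengthens more steeply to 28.4 h at 22 °C, reflecting the
stronger temperature sensitivity of the transcriptional loop). These
anchors are calibration choices consistent with reported window
estimates, not measured curves. Below the Hopf point the angular
frequency is frozen ($\omega = 0$): the phase holds while the amplitude
decays, which is what "the clock stops" means in this model.

**The cold parking state.** A plain Stuart–Landau oscillator below the
bifurcation decays to the origin, which has no phase — rewarming from it
would restart at an arbitrary, noise-selected phase. The biology says
otherwise: cold drives cytosolic Ca²⁺ *up* to a stable elevated level,
i.e. the system parks at a displaced point in state space, and long-cold
slices restart from a common phase. We therefore add a constant forcing
$\lambda \max(-\mu, 0)\,p$ (default parking displacement $p = 0.5$ on
the positive real axis), giving a sub-Hopf fixed point at
$z^\* \approx 0.35$ for the default Ca²⁺ parameters. Phase resetting by
cold then *emerges from the dynamics*: trajectories converge to $z^\*$
at a rate set by $\lambda$ and $|\mu(T)|$, so short exposures retain
memory of the entry phase while long exposures erase it.

**Relaxation rate.** $\lambda = 0.08\,\mathrm{h^{-1}}$ for all
channels. This single rate was calibrated against the resetting
phenomenology: with the default $\mu(15\,°C) = -0.3$, a 6-h cold pulse
leaves post-rewarming first-peak phases widely dispersed over a
phase-randomised cohort (circular SD > 4 h), a 48-h pulse clusters them
(resultant length > 0.9) and a 96-h pulse resets them almost completely
(circular SD ≈ 0.2 h). *Bmal1* damps much more slowly below the
bifurcation ($\mu(15\,°C) = -0.03$), so its post-rewarming phases stay
dispersed on the first day and re-entrain through the network coupling
over the following cycles — the qualitative signature that
distinguishes the two transcriptional reporters.

**Coupling.** The network is the directed cycle Ca²⁺ → *Per2* →
*Bmal1* → Ca²⁺, realised as weak additive forcing of the source state
rotated by $-\omega\,\ell$ for phase lag $\ell$ (gains 0.05; lags 7.9 h,
5.3 h and 10.0 h). Two deliberate choices here:

* All channels share the 23.2-h pacemaker frequency at 35 °C. Stable
  phase relations maintained over 12 days — as observed — require phase
  locking, which is impossible with persistently different frequencies;
  the slightly different printed per-channel periods lie within the
  cross-window spread of the peak-interval estimator.
* The three lags sum to the 23.2-h period, so the loop carries no net
  rotation and the locked configuration sits exactly at the programmed
  offsets (*Per2* 7.9 h and *Bmal1* 13.2 h after Ca²⁺).

## The reporter (observation) model

Fluorescence is generated as

$$F(t) = g(T)\,\cdot d(t) \cdot \left(B(t) + a\,\mathrm{Re}\,z(t)\right)
  + \varepsilon(t),$$

with $g(T)$ the intrinsic fluorescent-protein brightness gain at low
temperature (linear from 1 at 35 °C to 1.277 for Venus-like and 1.671
for mApple-like proteins at 15 °C — the +27.7 % / +67.1 % gains measured
for the bare proteins), $d(t)$ a slow multiplicative expression drift,
$B(t)$ a baseline relaxing toward its temperature target with a 2-h
time constant, $a$ the oscillation amplitude scale, and $\varepsilon$
additive Gaussian noise (sd 2 % of the 35 °C dynamic range, applied on
the 1-h observation grid only).

Drift defaults to 2 %/day (capped at ×2). A steeper drift would be
indistinguishable from a baseline change over a 12-day recording and
would force the "true" cold baselines to absurd values once composed
with the brightness gain, so the default is kept at the low end of what
long AAV-reporter recordings show.

The channel scales encode the observed signal magnitudes: the Ca²⁺
channel runs at ~30 % ΔF/F₀ amplitude, the Venus transcription channels
at ~1.5 %. The 15 °C baseline anchors were calibrated so that the
*measured* Day-1 cold baseline — after ΔF/F₀ against the recording
minimum, trend extraction, brightness gain and drift — averages ≈196.7 %
for Ca²⁺ (and ≈55.7 % / ≈25.4 % for *Per2* / *Bmal1*) over cohorts with
randomised initial phases. Phase averaging matters: below the Hopf
point the frozen-phase oscillation decays without oscillating, so a
single slice's Day-1 mean carries an entry-phase-dependent offset of up
to ±25 percentage points; only the cohort mean is a stable calibration
target. The 22–28 °C anchors deliberately attribute most of the
apparent baseline rise at moderate cold to the brightness artifact,
mirroring the control comparisons against bare Venus/mApple.

## Quantification pipeline

* **ΔF/F₀** = 100·(F − F₀)/F₀ with F₀ the minimum of the whole
  recording (ties → first occurrence). Positive input is enforced.
* **Detrending** subtracts a centred 24-h running mean. At 1-h sampling
  a naive 25-point window does *not* annihilate a 24-h cosine (Dirichlet
  leakage of 1/25); we use the classical even-order centred average with
  half-weighted endpoints (as in seasonal decomposition), which removes
  a cosine at exactly the window period and linear trends on interior
  points. Edges use shrinking truncated windows so the trace length is
  preserved.
* **Peak detection** smooths over 3 h, takes local maxima, keeps them
  greedily by height with ≥16-h separation, and refines positions with
  a quadratic through the three smoothed points. Peak *values* come
  from the parabola through the unsmoothed points (the smoothed apex is
  attenuated ~2–5 %, which would bias amplitudes). Candidates within
  12 h of a series end are discarded: the truncated detrending windows
  there distort peak positions by up to ~0.8 h, enough to corrupt
  period estimates.
* **Period** = mean successive peak interval in a window (undefined,
  `NA`, with fewer than two peaks — deliberately distinct from zero).
  **Amplitude** = (mean peak − mean trough)/2 of the detrended series.
  **Baseline** = mean of the running-average trend of ΔF/F₀.
* **Rhythmicity** = maximum autocorrelation of the detrended series at
  circadian lags (20–28 h) ≥ 0.3, plus ≥2 detected peaks. The 0.3
  threshold keeps the false-positive rate on white noise below 5 %
  (checked over 100 seeds); note the acf normalisation caps the score
  near (n − lag)/n even for a perfect rhythm, so scores of ~0.75 on a
  4-day window are "as rhythmic as it gets".
* **Restart phases** after rewarming are computed on the rewarmed
  segment only — a running mean spanning the temperature step is
  contaminated by the brightness discontinuity for half a window on
  either side — with the first 3 h excluded (acute reporter transient:
  the brightness step and the relaxing baseline are not circadian
  peaks), and the second peak used for transcription reporters, whose
  first post-rewarming peak can reflect an acute response.
* **Phase differences** between channels pair each reference peak with
  the *next* peak of the other channel, reporting the forward delay on
  the 24-h circle. Nearest-in-time pairing is available but disagrees
  with the forward convention whenever the period differs from 24 h
  (a 13.2-h forward delay on a 23.2-h rhythm has its nearest partner
  10.0 h *earlier*), and phase relations are conventionally reported as
  forward delays.

## Circular statistics

Phases live on a 24-h circle; all statistics go through the mean
resultant vector (length $R$, direction = circular mean). Circular SD
is $\sqrt{-2 \ln R}\cdot 24/2\pi$ hours, infinite at $R = 0$ where the
mean direction is flagged undefined. The Rayleigh test uses $z = nR^2$
with the standard series approximation
$p = \exp\!\left(\sqrt{1 + 4n + 4(n^2 - z^2)} - (1 + 2n)\right)$,
clamped to (0, 1]; Monte-Carlo checks in the test suite hold its type-I
error at nominal 5 % below 7 % for n of 6–20. Note that the circular
and arithmetic means of phases in a tight arc agree only to second
order in the dispersion (≈0.01 h at a 5-h spread), not exactly.

## Probe calibration

Free Ca²⁺ in EGTA-buffered solutions follows
$[\mathrm{Ca}]_{free} = K_d^{EGTA} \cdot [\mathrm{CaEGTA}]/[\mathrm{EGTA}]_{free}$
with
$K_d^{EGTA} = (1 + 10^{\log K_1 - pH} + 10^{\log K_1 + \log K_2 - 2pH})/K_{Ca}$
and the association constants ($\log K_1 = 9.58$, $\log K_2 = 8.96$,
$\log K_{Ca} = 10.97$ at 20 °C) corrected to temperature by the
standard Van't Hoff isochore
$\log K' = \log K - \frac{\Delta H}{2.303 R}(1/T - 1/T')$. A variant
form with an extra $1/T$ factor circulates in print; it is dimensionally
inconsistent and inverts the temperature dependence for exothermic
binding, so the standard isochore is the default and the variant is
available only behind an explicit `literal_printed` flag. One
consequence worth knowing: because the proton-association enthalpies
(−5.8 kcal/mol each) outweigh the Ca-association enthalpy
(−8.0 kcal/mol) jointly, the *effective* $K_d$ at fixed pH rises as
temperature falls even though every individual constant strengthens.

The Hill fit follows the kit convention: endpoints $F_{min}/F_{max}$
are taken from the Ca-free and Ca-saturating buffer measurements (not
free parameters; co-fitting is possible but not default), the response
is linearised as $\log\{(F - F_{min})/(F_{max} - F)\}$ against
$\log[\mathrm{Ca}]_{free}$, the slope is the Hill coefficient and the
back-transformed x-intercept the $K_D$. Points outside
$(F_{min}, F_{max})$ are dropped with a warning — the linearisation is
undefined there, and its noise amplification grows without bound toward
the saturation extremes, which is why the recovery tests use titration
points spanning mid-saturation.

The reporter correction composes the printed facts: a cold increase of
196.7 % ΔF/F₀, of which 67.1 percentage points are bare-mApple
brightness, against a 30 % rhythm amplitude gives
$(196.7 - 67.1)/30 = 4.3$ amplitudes; anchored to a 172–218 nM
basal-to-peak range this estimates $172 + 4.32\,(218 - 172) \approx
371$ nM under deep cold.

## Numerical choices

Integration is fixed-step classical RK4 at 0.1 h with decimation to the
1-h observation grid — the system is smooth and non-stiff, and a fixed
step makes runs bit-reproducible across platforms, which adaptive
steppers do not guarantee. Temperature is piecewise constant, so the
coefficients are resolved per output interval from the segment covering
its midpoint. Noise enters only on the observation grid; a zero
`noise_sd` therefore yields an exactly smooth deterministic trace, and
identical (parameters, protocol, seed) yield bit-identical output.
Cohorts derive per-slice seeds and uniform initial phases from a single
master seed.

Default problem sizes follow the canonical experiment: 12-day
recordings (96 h per condition window), 1-h sampling, cohorts of 6–9
slices, with sub-day simulations only in unit tests.

## What the synthetic data do and do not show

The generator reproduces the *structure* of the real recordings:
periods and phase relations, amplitude decline toward the Hopf point,
oscillation death with elevated baseline in deep cold, brightness and
drift confounds, duration-dependent phase resetting. It does not
attempt mechanistic transcription–translation kinetics, spatial
structure or cell-to-cell heterogeneity within a slice (traces are
ROI means), non-Gaussian imaging noise, or acute temperature-step
artifacts beyond a first-order baseline relaxation. Passing the
recovery tests therefore shows that the estimators are unbiased on
signals with this structure at realistic noise levels — not that any
particular biological parameter value is correct. Conversely, the
quantification and circular-statistics halves of the package make no
assumptions about the generator and apply to imported CSV traces
as-is.

## Known limitations

* Windows that straddle a temperature step mix regimes: the running
  mean smears the brightness discontinuity across ±12 h, which biases
  the rhythmicity score low there. Restart-phase analysis avoids this
  by construction; window summaries near steps should be read with
  care.
* The rhythmicity score's acf normalisation makes it length-dependent;
  the 0.3 threshold was calibrated for ≥4-day windows at 1-h sampling.
* The parking displacement direction (positive real axis) fixes the
  common restart phase; its value is a convention, so absolute restart
  phases are comparable within simulations but not meaningful in
  themselves.
* Sub-Hopf behaviour of the *Bmal1* channel (slow damping vs
  channel-specific noise) is underdetermined by rhythm data; the slow
  damping realisation was chosen, and its damping constant is a
  qualitative calibration.
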