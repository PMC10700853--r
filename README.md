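# coldclock

Circadian Ca²⁺ and clock-gene reporter rhythms in SCN slice cultures
survive moderate cooling, die below a critical temperature, and restart
after rewarming — from a reset phase if the cold exposure was long
enough. `coldclock` is an R package for studying exactly this class of
experiment. It provides, in one tidyverse-native toolbox:

* **A synthetic-recording generator.** One Stuart–Landau (Hopf normal
  form) oscillator per reporter channel,

  dz/dt = λ (μ(T) − |z|²) z + i ω(T) z + λ·(forcing),

  with a temperature-dependent bifurcation parameter μ(T) that crosses
  zero between 22 °C and 15 °C (so the limit cycle of radius √μ shrinks
  with cooling and oscillations die below the Hopf point), frozen phase
  and a displaced "parking" fixed point in the cold, weak phase-lagged
  coupling around the cycle Ca²⁺ → *Per2* → *Bmal1* → Ca²⁺, and a
  reporter model adding fluorescent-protein brightness gain at low
  temperature, slow expression drift, and Gaussian noise.
* **A rhythm-quantification pipeline.** ΔF/F₀ with F₀ the recording
  minimum, 24-h running-average detrending, peak detection with
  sub-sample refinement, period as the mean successive peak interval,
  amplitude, baseline level, and an autocorrelation-based rhythmicity
  verdict.
* **Circular statistics on the 24-h circle.** Circular mean and
  resultant length R, circular SD √(−2 ln R)·24/2π, the Rayleigh
  uniformity test (z = nR²), phase differences between peak series, and
  Rayleigh dial plots.
* **Ca²⁺-probe calibration maths.** Free Ca²⁺ in EGTA-buffered
  solutions with pH correction, Van't Hoff temperature correction of
  the binding constants, log–log Hill linearisation (K_D and Hill
  coefficient from a straight-line fit), fluorescent-protein brightness
  correction of cold-induced signal increases, and absolute Ca²⁺
  estimation from literature anchors.

## Worked example

Simulate the standard chilling experiment (4 days at 35 °C, 4 days at
15 °C, 4 days rewarmed) and quantify the Ca²⁺ channel per 4-day window:

```r
library(coldclock)

prot <- build_protocol(pre_h = 96, cold_temp_C = 15, cold_h = 96, post_h = 96)
tr <- simulate_network(default_oscillator_params(),
                       default_reporter_params(), prot, seed = 1)
quantify_trace(tr, channels = "Ca")
#> # A tibble: 3 × 10
#>   channel window_start_h window_end_h temp_C period_h amplitude_pct
#>   <chr>            <dbl>        <dbl>  <dbl>    <dbl>         <dbl>
#> 1 Ca                   0           96     35     23.2          36.1
#> 2 Ca                  96          192     15     22.7          15.6
#> 3 Ca                 192          288     35     23.6          38.2
#> # i 4 more variables: amplitude_norm <dbl>, baseline_pct <dbl>,
#> #   rhythmic <lgl>, rhythm_score <dbl>
```

The warm windows are rhythmic with a ~23.2-h period and ~35 % ΔF/F₀
amplitude; the 15 °C window is scored non-rhythmic (the oscillator sits
below the Hopf point) while its baseline jumps to ~230 % — the compound
of a real Ca²⁺ elevation and the intrinsic brightness gain of the
mApple-based indicator in the cold.

Correcting a measured cold increase for that brightness artifact and
anchoring it to literature Ca²⁺ levels:

```r
fold <- fp_corrected_fold(dff_cold_pct = 196.7, fp_gain_increase_pct = 67.1,
                          rhythm_amplitude_pct = 30)
fold
#> [1] 4.32
estimate_absolute_ca(fold, basal_nM = 172, peak_nM = 218)
#> # A tibble: 1 × 4
#>   corrected_fold basal_nM peak_nM estimated_nM
#>            <dbl>    <dbl>   <dbl>        <dbl>
#> 1           4.32      172     218         371.
```

That is: after removing the reporter's own 67.1 % brightness gain, the
cold Ca²⁺ signal increase equals 4.3 rhythm amplitudes, which maps the
172–218 nM basal-to-peak range onto roughly 370 nM under deep cold.

Cohort-level phase-resetting analyses use `phase_randomized_cohort()`
plus `cohort_restart_phases()` and `circular_summary()`; `run_experiment()`
drives the whole simulate → quantify → phase-analysis chain from a JSON
config and writes traces, summary tables and circular statistics as CSV.
A thin command-line wrapper with the same subcommands lives at
`inst/cli/coldclock`.

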