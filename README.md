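# hopfcochlea

Tools for testing whether cochlear-segment recordings behave like a
dynamical system poised near a Hopf bifurcation. The package is aimed at
auditory biophysicists and methodologists who want to (a) simulate
microphonic-like recordings from a forced Hopf oscillator with a passive
pathway and realistic measurement noise, and (b) run the statistical
pipeline that detects criticality signatures in level series — so that the
pipeline can be validated on data with known ground truth, and contrasted
against passive and saturating-nonlinearity nulls.

## The model and its signatures

A cochlear segment tuned to characteristic frequency CF is modeled by the
Hopf normal form for a complex state *z*:

    dz/dt = (ε + i ω_c) z − β |z|² z + F₀ e^{i(ωt + φ)},   ω_c = 2π·CF

with control parameter ε ≤ 0 (quiescent side), stabilizing cubic
coefficient β (Re β > 0). The steady-state amplitude *A* solves

    F₀² = (β_re A³ − ε A)² + (A(ω − ω_c) + β_im A³)².

Near criticality (ε → 0) this predicts, and the package measures:

* **1/3 power law at CF** — response grows as F₀^(1/3) in log–log axes;
* **−2/3 sensitivity** — S = A/F₀ declines as F₀^(−2/3);
* **linearity off CF** — slope → 1 for |ω − ω_c| large;
* **level-independent cubic distortion products** — two primaries f₁ < f₂
  produce combination tones at 2f₁−f₂ and 2f₂−f₁ holding a fixed ratio
  (~15%) to the primaries, whereas a memoryless saturating transducer
  (`sigmoid_transducer()`, the null model) produces distortion that grows
  superlinearly with level.

The analysis side implements the full detection pipeline: FFT phasor
extraction with a Rayleigh phase-locking gate (p < 0.001), local log–log
slopes from overlapping triplets/quadruplets with an SE ≤ 0.15 filter,
per-segment minimum slopes (500 Hz moving window, 10 Hz steps), the cohort
trend of minima versus frequency, piecewise sensitivity fits with
inflection-point alignment and averaging, nonlinearity classification
(any slope < 0.5), sublinear-run detection, and distortion-product level
scaling. Multitone ("zwuis") stimuli with guaranteed combination-tone
avoidance are available for simultaneous multi-frequency characterization.

## Worked example

Steady-state responses at criticality follow the cube-root law exactly:

```r
library(hopfcochlea)
p <- hopf_params(epsilon = 0, omega_c = 2 * pi * 1000)
steady_state_amplitude(p, F0 = c(1, 8, 27), omega = p$omega_c)
#> [1] 1 2 3
```

A synthetic cohort of 20 near-critical segments (CFs on 1–2.5 kHz, at-CF
level series 10–90 dB SPL, 20 repetitions each) run through the
compression pipeline:

```r
cohort <- generate_cohort(cohort_spec(n_segments = 20, master_seed = 1))
trend  <- cohort_trend(min_slope(local_slopes(cohort$curves)))
trend
#> <cohort_trend>
#>   n segments: 20
#>   trend: y = m x + q, m = -1.46e-06 [-3.76e-05, 3.47e-05] /Hz, q = 0.337 [0.269, 0.405]
#>   mean minimum slope: 0.334 +/- 0.007 (95% CI 0.320-0.349)
```

Read: each segment's level curve contributed many local log–log slopes;
the per-segment *minimum* retained slope clusters tightly near 1/3 (mean
0.334), the frequency trend of those minima is indistinguishable from
flat (the CI on m spans zero), and the intercept q sits near 1/3 — the
cohort-level fingerprint of cube-root compression. A passive cohort
(`cohort_spec(ep_on = FALSE)`) run through the same pipeline yields no
retained slope below 0.5. `glance(trend)`, `tidy(trend)` and
`autoplot(trend)` give tabular and graphical views.

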