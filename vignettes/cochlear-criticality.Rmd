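---
title: "Detecting criticality signatures in cochlear-segment recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting criticality signatures in cochlear-segment recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopfcochlea)
```

## The model

The active process of the cochlea — amplification, sharp frequency tuning,
and compressive nonlinearity — can be interpreted as the behavior of a
dynamical system poised near a Hopf bifurcation. `hopfcochlea` models a
cochlear segment as the Hopf normal form for a complex state $z(t)$,

$$\dot z = (\epsilon + i\omega_c)\,z - \beta |z|^2 z + F(t),$$

where $\epsilon$ (1/s) is the control parameter ($\epsilon \le 0$:
quiescent; $\epsilon > 0$: spontaneous oscillation at the limit-cycle
radius $\sqrt{\epsilon/\beta_{re}}$), $\omega_c = 2\pi \cdot \mathrm{CF}$ is
the natural angular frequency, and $\beta = \beta_{re} + i\beta_{im}$ with
$\beta_{re} > 0$ is the stabilizing cubic coefficient. A pure tone exerts a
rotating force $F(t) = F_0 e^{i(\omega t + \phi)}$. Seeking a steady state
$z = A e^{i(\omega t + \phi + \varphi)}$ gives the amplitude relation

$$F_0^2 = (\beta_{re} A^3 - \epsilon A)^2 +
  \big(A(\omega - \omega_c) + \beta_{im} A^3\big)^2 ,$$

which `steady_state_amplitude()` solves by bracketed root finding (the root
is unique for $\epsilon \le 0$; relative tolerance $10^{-10}$). Four
testable signatures follow at criticality ($\epsilon = 0$):

1. at resonance, $A = (F_0/|\beta|)^{1/3}$ — a 1/3 slope in log-log
   coordinates;
2. the sensitivity $S = A/F_0$ falls as $F_0^{-2/3}$;
3. far from resonance the response is linear, $A = F_0/|\omega - \omega_c|$;
4. two nearby primaries generate cubic combination tones at
   $2f_1 - f_2$ and $2f_2 - f_1$ whose magnitude keeps a fixed ratio to the
   primaries as level grows.

The contrasting null is a *stationary* saturating nonlinearity — a
sigmoidal transducer curve, implemented as
`sigmoid_transducer(x, x_half) = tanh(x / x_half)`. It imposes no power-law
floor on response growth, and its cubic distortion products grow
superlinearly (as the cube of the input for weak drive), so the
distortion-to-primary ratio *rises* with level. tanh was chosen among
sigmoids because its Taylor expansion makes the cubic-distortion oracle
exact in tests; any odd saturating function gives the same qualitative
contrast.

```{r steady-state}
p <- hopf_params(epsilon = 0, omega_c = 2 * pi * 1000)
response_curve_theory(p, omega = p$omega_c, F0_grid = c(1, 8, 27))
```

## Time-domain integration

`integrate_oscillator()` integrates the forced normal form with a
fixed-step classical Runge–Kutta scheme, switching to Euler–Maruyama at the
same step when state noise is requested. Fixed stepping was preferred over
adaptive integration for bit-level reproducibility given a seed. Because
the sampling rates used for recordings (16 kHz) put $\omega_c \Delta t$
near 1 for high-CF segments, the integrator internally oversamples so that
$\omega_c \Delta t \le 0.15$ and records on the requested grid; this keeps
steady-state amplitudes within the 1% agreement the test suite demands of
the analytic solution. A divergence guard aborts if $|z|$ exceeds a
configurable bound. Onset transients are discarded before analysis; the
default settling time is $\max(10/\mathrm{CF}, \min(5/|\epsilon|, 1))$
seconds for $\epsilon < 0$ and 50 cycles at criticality.

## What the synthetic experiment emulates

`segment_config()` + `simulate_recording()` generate
cochlear-microphonic-like recordings with the statistical structure the
analysis assumes:

$$v(t) = g_{obs}\,\mathrm{Re}\,z(t)\,[\mathrm{EP\ on}]
  + g_{pass}\,p(t - \textstyle\frac{\pi/2}{\omega}) + \eta(t),$$

an active near-critical pathway driven by $F_k = c\,P_k$ (forcing units per
pascal), a passive linear pathway, and white measurement noise. Repeated
presentations share the underlying response and differ only in the noise
realization, emulating phase-locked stimulus repetitions. "EP off"
(abolishing the endocochlear potential) removes the active pathway
entirely rather than shifting $\epsilon$, because recordings without EP are
purely passive and linear.

Defaults (all overridable) and why:

* `coupling = 1.25e4` forcing-units/Pa and `passive_gain = 50`
  observable-units/Pa place the crossover where the passive pathway
  overtakes the active one near 84 dB SPL, inside the default 10–90 dB
  series, so at-CF curves traverse noise floor, cube-root region, and
  linear high-level growth.
* `passive_phase = pi/2`: with $\beta$ real the active response is in phase
  with the forcing at resonance, and in-phase summation of a cube-root and
  a linear component smears the compressive-to-linear transition over tens
  of dB. The two generation mechanisms are not phase aligned in real
  recordings, and quadrature summation reproduces the sharp kink those
  curves show.
* `noise_rms = 100` observable units per sample makes responses below
  roughly 25 dB SPL fail the Rayleigh gate with 20 repetitions — a noise
  floor at the bottom of the series, as in real level series.
* healthy control parameters are drawn log-uniformly with
  $|\epsilon|/\omega_c \in [10^{-5}, 10^{-4}]$ (negative sign): quiescent
  but close enough to criticality that the cube-root region spans tens of
  dB. Larger detunings (e.g. $10^{-2}\omega_c$) leave no visible power-law
  region within a 10–90 dB series.
* `cohort_spec()` defaults to 20 segments with CFs uniform on 1–2.5 kHz,
  17 levels (10–90 dB SPL, 5 dB steps), 20 repetitions of 0.5 s windows at
  16 kHz. These are deliberately scaled-down problem sizes — the emulated
  study ran 78 experiments with 200 repetitions — chosen so the full
  cohort pipeline runs in well under a minute; the suite verifies that 20
  repetitions retain detection power at mid levels.

What the generator does **not** emulate: transduction biophysics (hair-cell
populations, channel kinetics), spatially extended traveling-wave
mechanics, middle-ear filtering, absolute microphonic scale (all cohort
statistics are scale-free slopes and ratios), and level calibration —
dB SPL values are nominal. Passing tests therefore demonstrate that the
*statistical pipeline* recovers the dynamical signatures from data with
this structure, not that real cochleae are critical.

## The stimulus module

Tones are synthesized with raised-cosine on/off ramps (default 10 ms; the
source only requires "tapered" onsets). `design_zwuis()` builds multitone
complexes by seeded rejection sampling on a `delta_f` grid, enforcing that
no combination tone with total coefficient weight $\le$ `order` (2 or 3)
lands on a primary; an exhaustive enumeration oracle re-checks accepted
designs in the tests. With `delta_f` = 1/window, every primary and
combination tone falls exactly on an FFT bin, so rectangular windows leak
nothing. The construction method of the original zwuis stimuli is not
specified in detail anywhere; rejection sampling with the explicit
no-collision constraint implements precisely the property that matters.

## The analysis pipeline

* `extract_response()`: per-repetition FFT phasor at one grid-locked bin;
  coherent (complex) averaging across repetitions — valid because stimuli
  are phase locked to acquisition, and equivalent to FFT-after-averaging
  for grid-locked signals; Rayleigh test on per-repetition phases with the
  second-order-corrected p-value $e^{-Z}(1 + (2Z - Z^2)/(4n))$, accurate at
  small repetition counts (the crude $e^{-Z}$ is biased there). Gates:
  $p < 0.001$ for microphonic-style series, $p \le 0.01$ for
  vibrometry-style series. Off-grid frequencies are refused rather than
  interpolated.
* `local_slopes()`: ordinary least squares on every run of 3 and of 4
  consecutive gate-passing points in log-log coordinates (both window
  sizes pooled, as in the source procedure), with the classical OLS slope
  standard error; estimates with SE > 0.15 are dropped.
* `min_slope()`: per-segment minimum retained slope; multi-frequency
  protocols are scanned with a 500 Hz moving window stepped by 10 Hz. The
  moving window is applied within segments; the alternative cohort-display
  reading would apply it across segments and is not implemented.
* `cohort_trend()`: OLS of minima against frequency (Hz) with 95% CIs,
  plus the mean of minima with SE and CI. Near-critical cohorts cluster at
  1/3 with a flat trend; passive or saturating cohorts scatter without a
  floor.
* `piecewise_fit()`: continuous hinge (negative slope, then flat) fitted
  in log-log space by exhaustive search over breakpoints at observed
  levels and their midpoints — globally optimal on that grid; curves with
  no negative-slope breakpoint are flagged non-compressive rather than
  force-fitted.
* `align_and_average()`: curves translated so inflection points coincide,
  pooled, running-averaged in 0.1-decade bins (the source states no bin
  width; 0.1 decade resolves the 5 dB level grid), then 4-point sliding
  OLS slopes with 95% CIs from $t_{2}$ (OLS residual degrees of freedom).
* `classify_nonlinear()`: any retained slope < 0.5 (strict).
* `sublinear_run_mask()`: at least three consecutive point-to-point
  log-log increments below a threshold, default 0.9 — the source says only
  "sublinear", so the 10% linearity margin is exposed as a parameter.

Triplet and quadruplet slopes are pooled before taking minima (whether the
original procedure pooled them is not stated; pooling matches "each
experiment contributed many slope values").

```{r pipeline, eval = FALSE}
cohort <- generate_cohort(cohort_spec(n_segments = 20, master_seed = 1))
trend <- cohort_trend(min_slope(local_slopes(cohort$curves)))
trend
autoplot(trend)
```

## Distortion products

`measure_dps()` extracts gated phasors at the primaries and at the
odd-order combination tones $n f_1 - (n-1) f_2$ (and mirrored) and reports,
per level, the mean gate-passing cubic-product magnitude divided by the
mean primary magnitude. For near-critical two-tone simulations this ratio
stays near 15% with a coefficient of variation well below 0.2 across a
30 dB sweep, while the tanh transducer's ratio grows monotonically — the
dynamical-versus-stationary discriminator. The default two-tone geometry
mirrors the classic protocol ($f_1 = 1230$, $f_2 = 1236$ Hz, products at
1224/1242 and 1218/1248 Hz, all on the 2 Hz grid of 0.5 s windows).

## Degenerate inputs and numerical conventions

Level series must be strictly increasing; off-grid analysis frequencies
are errors, not interpolations; curves with fewer than 3 gate-passing
points are insufficient for slopes (5 for piecewise fits, 4 for sublinear
runs); segments whose estimates are all SE-filtered return an explicitly
flagged empty minimum. All randomness flows from explicit integer seeds
(cohorts from a single `master_seed`), and every simulation is
reproducible byte for byte. Serialization uses plain CSV/JSON with 17
significant digits so numeric round trips are exact; a legacy curve
dialect without Rayleigh columns is read with the gate marked
"not evaluated".

## Known limitations

* `steady_state_amplitude()` is restricted to $\epsilon \le 0$; driven
  responses on the spontaneous side (entrainment) are available only
  through time integration.
* Coherent averaging assumes repetition-locked acquisition; asynchronous
  data would need per-repetition windowing before averaging.
* The intercept of the cohort trend extrapolates to 0 Hz from CFs on
  1–2.5 kHz; at 20 segments its sampling variability is several times
  larger than in the 78-experiment study, so it is the least stable of the
  cohort statistics.
* The forcing-to-pascal coupling and observable gain are arbitrary
  constants: only scale-free statistics (slopes, ratios, trends) are
  meaningful.
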