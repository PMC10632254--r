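---
title: "Pressure-only aortic wave separation with flow surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-only aortic wave separation with flow surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavesep)
```

## The problem

Wave separation analysis decomposes a central arterial pressure waveform
$P(t)$ into a forward-running component generated by ventricular ejection
and a backward-running component produced by reflection in the arterial
network. With a simultaneous aortic flow waveform $Q(t)$ and the
characteristic impedance $Z_c$,

$$P_f = \tfrac{1}{2}\left(P - P_{ud} + Z_c Q\right), \qquad
  P_b = \tfrac{1}{2}\left(P - P_{ud} - Z_c Q\right),$$

where $P_{ud}$ is the undisturbed pressure (taken as zero by default).
Two summary indices are derived: the reflection magnitude
$RM = \Delta P_b / \Delta P_f$ (component amplitudes, max minus min over
the beat) and the reflected-wave return time $T_r$, computed as the delay
between the time-axis centroids of $P_b$ and the input pressure
$P_{f,in} = Z_c Q$ — the pressure that would exist without any
reflection. Central pressure is easy to obtain non-invasively; aortic
flow is not. Because $RM$ and $T_r$ depend only on the *shape* of the
flow waveform, an uncalibrated surrogate flow waveform suffices, and
this package provides the three families of surrogates in practical use:

* a **representative flow waveform**: a population average of
  amplitude- and time-normalized measured flow waveforms,
  de-normalized onto the individual beat;
* a **triangular flow waveform** spanning onset to end-systole with a
  parameterized apex;
* **Doppler-like velocity traces** (envelope, sample-volume mean,
  whole-lumen peak), which the package can also *generate* from a known
  cross-sectional velocity field, isolating the errors introduced by
  sample-volume coverage and velocity-profile skew.

Everything is validated against a built-in tube-load generator with
exact ground truth, since suitable clinical recordings cannot be bundled.

## Characteristic impedance

$Z_c$ is the slope of the early-systolic pressure–flow relation, fitted
by least squares from the flow upstroke's onset until flow first reaches
95% of its peak (`upstroke_fraction`, configurable). The early upstroke
is used because reflected waves have not yet returned there, so
$P \approx Z_c Q$ up to an additive constant that the fit absorbs. On
noiseless tube-load beats the estimate is within 0.4% of truth across
reflection coefficients 0.1–0.7 and delays 60–200 ms, because the
fitting window closes before the reflected wave arrives.

## Beat landmarks

All surrogates are anchored on beat landmarks detected from a flow (or
velocity) waveform:

* `t_peak`: grid argmax;
* `t_50up`: the last upward crossing of 50% of peak before the peak
  (sub-sample, linear interpolation) — used as the first normalization
  anchor because it is insensitive to small variations in the foot;
* `t_onset`: the last time before `t_50up` at which the signal is at or
  below 5% of peak (`onset_frac`, configurable). A relative threshold is
  robust to baseline noise and matches the near-zero diastolic flow of
  aortic waveforms;
* `t_es` (end-systole): the first local minimum after the peak — the
  valve-closure notch — searched within 0.6 of the cycle length after
  the peak (`es_window_frac`; systole occupies less than 60% of the
  cycle at physiological heart rates). A local minimum is a sample lower
  than its left neighbour and no higher than its right neighbour, ties
  resolved to the earliest time; strict minima are refined to sub-sample
  precision by a parabolic fit;
* `t_zero`: the first return to zero at or after `t_es`, absent when the
  signal stays positive.

For pressure-only deployments, `pressure_landmarks()` applies the same
logic to a baseline-subtracted pressure or area waveform, so end-systole
is its first post-peak local minimum (the dicrotic notch). On the
synthetic beats below, the sharp onset of the forcing wave places that
minimum at the reflected-wave arrival rather than at valve closure, so
the pressure-anchored mode carries a documented accuracy cost there;
with measured pressure waveforms the notch is the usual anchor.

## The representative flow waveform

Construction, given a cohort of measured flow beats:

1. **Normalize** each beat: divide by its peak (peak becomes 1.0, and
   the 50%-upstroke anchor is 0.5 by construction) and map time affinely
   so that `t_50up` sits at $\tau = 0$ and `t_es` at $\tau = 1$. Beats
   are resampled onto a common grid of 1000 points spanning
   $\tau \in [-0.3, 2.5]$, which covers pre-foot through late diastole
   at all physiological heart rates; outside its own range a beat is
   extended with its boundary values (diastolic flow is near zero).
2. **Average** pointwise and **smooth** with a Savitzky–Golay filter
   spanning 0.125 normalized time units (polynomial order 3, window
   forced to the nearest odd sample count). Order 3 reproduces cubic
   segments exactly, so the systolic peak is not flattened.
3. **Enforce zero late-diastolic flow** with a three-segment weighting
   function: 1.0 until the smoothed mean first returns to zero after its
   end-systolic minimum, a linear ramp from 1.0 to 0.0 over 0.6
   normalized time units, and 0.0 thereafter. The ramp is applied to the
   averaged waveform, not per subject. Values beyond the ramp are exact
   zeros; the small negative end-systolic backflow before the zero
   return is retained.
4. The 5th/95th percentile envelopes are computed from the unsmoothed,
   unramped inputs, so they bracket the ensemble mean.

De-normalization inverts the affine time map using the individual's own
anchors (from measured flow where available, from the pressure waveform
otherwise) and leaves the amplitude at the normalized scale — the
separation indices do not need it.

```{r repflow}
co <- simulate_cohort(n = 8, seed = 1)
norms <- lapply(co$subjects, function(s) normalize_beat(s$q))
rep <- build_representative(norms)
rep
```

`loo_cross_validate()` evaluates the representative waveform the way it
must be evaluated — each subject's surrogate is built from everyone
else's beats — and reports signed and absolute percent errors of $RM$
and $T_r$ plus component RMSEs against the measured-flow separation.
For any two separations sharing the same pressure waveform, the forward
and backward RMSEs are identical algebraically (the difference is
$\pm\frac{1}{2}\,\Delta(Z_cQ)$ in both components), and the package
reports both as a cross-check.

## The synthetic generator and what it does (not) emulate

`sim_truth()`/`simulate_beat()` implement a single-reflection
transmission line: a compact forward wave $F(t)$ (a skewed half-sine of
300 ms duration peaking at 25% of ejection — close to the average timing
of peak aortic flow), a reflected copy $\Gamma F(t - \Delta)$, and

$$P = F + \Gamma F(t-\Delta) + P_{dia}, \qquad
  Q = \left(F - \Gamma F(t-\Delta)\right) / Z_c.$$

Defaults are chosen once on physiology: heart rate 70 bpm, forward
amplitude 40 mmHg, diastolic baseline 70 mmHg, $Z_c$ = 0.1 mmHg·s/mL
(so peak flow is a realistic 400 mL/s), area surrogate
$A = 450 + 2(P - P_{dia})$ mm², 128 samples per cycle (the temporal
resolution of segmented phase-contrast imaging). Cohorts draw
$\Gamma \in [0.3, 0.6]$, $\Delta \in [80, 160]$ ms, heart rate
$[55, 90]$ bpm, ejection $[270, 330]$ ms and rise fraction
$[0.22, 0.28]$ uniformly under one seeded stream.

Because there is no re-reflection, ground truth is closed-form:
separation with the true $Z_c$ recovers $P_b = \Gamma F(t-\Delta)$ to
machine precision and $RM = \Gamma$ exactly. Two deliberate
idealizations matter when interpreting validation results:

* **No aortic valve.** The model's flow carries the reflected lobe at
  full amplitude, including a deep negative diastolic lobe that real
  aortic flow (valve closed) does not show. A direct consequence is
  that the flow-shaped input pressure $P_{f,in} = Z_c Q$ is *not* a
  shifted copy of the forward wave: its centroid sits early by
  $\Gamma\Delta/(1-\Gamma)$, so the centroid return time on these beats
  obeys the exact law $T_r = \Delta/(1-\Gamma)$ rather than
  $T_r = \Delta$. The package's tests assert that law to within one
  sample; on measured data, where ventricular outflow is only weakly
  affected by reflection, the method's own assumption
  ($P_{f,in} \approx$ reflection-free input) is far closer to true.
  The same idealization makes surrogate-flow return times on synthetic
  cohorts much more variable than on real cohorts: the estimated
  backward wave $\frac{1}{2}(P - \hat Z_c \hat Q)$ inherits the
  *cohort-average* reflected lobe of the representative waveform at
  half weight, which is exactly the distortion real flows do not carry.
* **Static linear pressure–area map**, no wall viscoelasticity: the
  area surrogate is an affine copy of pressure, so calibration
  invariances can be asserted at machine precision.

The jittered cohort does reproduce the qualitative morphology finding
that motivates the representative-waveform approach: normalized flow
waveforms are nearly identical during the systolic upstroke (before the
earliest reflections return) and vary mostly during the downstroke.

## Centroid return time: conventions

Centroids are $\int t\,s(t)\,dt / \int s(t)\,dt$ by trapezoidal
quadrature over the whole beat (exact for piecewise-linear signals,
robust on coarse grids). Following the originating description of the
method, only $P_b$ is offset to a minimum of zero before integration;
$P_{f,in}$ enters as-is. Offsetting $P_{f,in}$ as well would add a
constant pedestal across the whole beat whenever the flow surrogate has
a negative lobe, dragging its centroid toward mid-beat and destroying
the translation property that makes the method work (a shifted, scaled
copy must shift the centroid by exactly the delay — the package asserts
this recovery across random shifts to within one sample). Integrating
over the whole beat rather than systole only uses all of the reflected
wave's energy and keeps that translation property exact.

## Virtual Doppler ultrasound

From a cross-sectional velocity field with a lumen mask:

* the square **sample volume** covers 50% of the minimum effective
  diameter $D(t) = 2\sqrt{A(t)/\pi}$ over the beat and sits at the
  time-averaged lumen centroid, fixed in space;
* per frame, **DopEnv** is the 95th percentile of velocity over pixels
  whose centres fall inside the square (intersected with the lumen),
  **DopMean** the mean over the same pixels, **PeakU** the 95th
  percentile over the whole lumen, and the **true mean** the lumen
  average — the velocity equivalent of volumetric flow. Percentiles
  interpolate linearly between order statistics; pixel membership is by
  pixel centre. Both rules are stated here because acquisition software
  does not report them.
* traces are post-processed the way Doppler traces are prepared for
  analysis: the end-diastolic level at beat onset is subtracted, and
  the trace is zeroed from its post-systolic zero return onward. The
  cut is grid-level, which makes the operation idempotent; any
  flow-reversal lobe beyond the zero return is dropped with the
  diastole, mirroring the envelope's inability to capture reversal.

The simulated field uses a power-law profile
$u \propto 1 - (r'/R)^n$ (parabolic at $n = 2$, flat as
$n \to \infty$) with the profile centre displaced along one axis by
$\text{skew} \cdot R \cdot q(t)/\max q$. The displacement follows the
instantaneous velocity because secondary flows that skew the profile
scale with it; a time-constant displacement would leave every trace
exactly proportional to the true mean and hence could not produce any
separation error, which is contrary to the error mechanism the
simulator exists to exhibit. Each frame is renormalized so the lumen
mean equals $q(t)/A$ exactly. With a flat profile all four traces are
identical and Doppler-based separation is exact; with skew, the
envelope's separation error grows monotonically, and the whole-lumen
95th percentile can fall below the sample-volume envelope (both
percentiles cut their own pixel populations).

## Numerical choices

* **Interpolation** is the classical C² cubic spline everywhere
  (exact on polynomials up to degree 3; resampling a 20-point half-sine
  to 1000 points errs below $10^{-4}$ of amplitude). A shape-preserving
  piecewise-cubic Hermite alternative (`method = "pchip"`) is exposed
  for waveforms where overshoot at the dicrotic notch matters more than
  asymptotic accuracy.
* Landmark crossing times are sub-sample; the diastolic cut in trace
  post-processing is deliberately grid-level (idempotence).
* Degenerate inputs fail with classed conditions (`ws_invalid_input`,
  `ws_landmark_error`, `ws_degenerate_input`, ...) naming the failing
  quantity.
* Reflection-free beats have no backward wave to time; `separate_waves`
  reports `tr = NA` there instead of a meaningless centroid.

## Problem sizes used in the validation suite

The test suite and the results script run entirely on the synthetic
generator: 200 random beats for the conservation property, a 35-point
$(\Gamma, \Delta)$ recovery grid, a 20-subject cohort for leave-one-out
evaluation, 41–61 pixel grids with 128 frames for the Doppler checks,
and 50 random shifts for the centroid oracle. These sizes make the full
suite run in well under a minute while keeping every property
non-trivial.

## Known limitations

* The generator has no valve, no re-reflection and no nonlinearity; see
  above for the two validation consequences. It demonstrates that the
  algorithms are implemented correctly, not that surrogate flows work
  on any particular patient population.
* The representative waveform built here comes from synthetic cohorts;
  users analysing real data should build one from their own measured
  flows (`build_representative`) or supply a published normalized
  waveform via `load_external_normalized`, asserting its anchor
  convention themselves.
* Group-level inferential statistics are out of scope; the evaluation
  harness reports descriptive mean ± SD only.
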