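---
title: "Peri-saccadic LFP asymmetries: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-saccadic LFP asymmetries: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periLFP)
```

## The scientific question

The primate superior colliculus (SC) holds a retinotopic map in which the
upper and lower visual fields are treated differently: visual bursts of SC
neurons are stronger for upper-field stimuli, while the motor bursts emitted
around saccade onset are *weaker* for upper-field movement endpoints. Local
field potentials (LFPs) recorded at the same electrodes index aggregate
synaptic activity of the surrounding network rather than local spiking
output. The analysis this package implements asks: around the time of a
saccade, does the LFP follow the spiking asymmetry (weaker upper-field motor
bursts) or the sensory asymmetry (stronger upper-field visual drive)?

The study conditions encoded in the package's generator reflect the
published answer: the peri-saccadic LFP negativity is larger — by a factor
of about 2.7 in magnitude — at upper-field sites, even though motor bursts
there are weaker, and the change across the horizontal meridian is a step,
not a gradient. Stimulus-evoked LFP deflections carry a similar asymmetry
(about 2.5x). During the delay period of memory-guided saccades the LFP
turns positive, and the upper field then shows the *larger positivity*;
visually-guided delays keep the upper field more negative.

## Pipeline

A session is one electrode track with a known retinotopic site
(`siteGeometry(eccentricityDeg, directionDeg)`; positive direction = upper
field), a table of trial events, spike times, and continuous wideband
voltage at 40 kHz. The analysis chain is:

1. **Conditioning** (`preprocessChain()`): zero-phase IIR notch filters at
   50/100/150 Hz (Q = 35), a zero-phase 4th-order Butterworth low-pass at
   300 Hz, then phase-0 decimation to 1 kHz. Forward–backward application
   makes the chain lag-free, so peak latencies are preserved exactly.
   Firing rates come from `spikeDensity()`: every spike contributes a
   Gaussian density (SD 10 ms) in spikes/s on the same 1 kHz grid.
2. **Epoching** (`buildEpochMatrix()`): half-open windows \[a, b) ms around
   a named event, rounded half-up to the 1 kHz grid, one row per trial;
   `sessionMean()` averages trials, `groupAverage()` averages sessions and
   attaches the across-session SEM (n−1 denominator).
3. **Measurement** (`windowMeasure()`): one scalar per session — the mean
   over 0–50 ms after saccade onset (`PERISACC`), the mean over −50 to 0 ms
   (`PRESACC`), the mean over −50 to +25 ms around the go signal (`GO`), or
   the most negative sample 30–100 ms after target onset (`STIMPEAK`).
   `baselineShift()` subtracts the −300 to −200 ms pre-saccadic mean, which
   matters for memory-guided saccades where working memory shifts the
   pre-saccadic LFP level.
4. **Topography** (`directionBins()`, `eccentricityBins()`): direction bins
   are 20 deg wide in 10 deg steps of |direction| per field — overlapping,
   so a typical session joins two bins and bin membership counts exceed the
   session count — with a minimum of 10 members per retained bin; bins never
   straddle the horizon. Eccentricity bins are non-overlapping with edges
   0, 2, 5, 10, 30 deg.
5. **Statistics** (`twoSampleT()`, `oneWayAnova()`,
   `twoWayAnovaMainEffects()`): implemented from the defining sums of
   squares, with p-values through the regularized incomplete beta function.

## The synthetic session generator

No public recordings accompany the analysis, so the generator *is* the test
bed: it emulates the two tasks and the asymmetry structure with full seed
control, and every claim the test suite makes about the pipeline is a
parameter-recovery claim against this generator.

Trial timelines follow the task design: fixation 300–1000 ms; the target
stays on in the visual task but is flashed for exactly 50 ms in the memory
task; target-to-go delay 500–1000 ms (visual) or 300–1000 ms (memory);
saccade latency 150–200 ms after the go signal; saccade duration fixed at
40 ms (a typical macaque value; it touches no measurement window).

The LFP of a trial is a sum of three event-locked components plus noise:

* a **stimulus-evoked** negative Gaussian deflection (peak 60 ms after
  target onset, SD 15 ms, unit peak 60 uV) — the 30–100 ms measurement
  window brackets its peak;
* a **peri-saccadic** negative Gaussian deflection (peak 25 ms after
  saccade onset, SD 20 ms, unit peak 80 uV) — the 0–50 ms window brackets
  its peak;
* a **delay-period plateau** (logistic rise from 150 ms after target onset,
  released 100 ms after go, time constant 30 ms, unit magnitude 30 uV),
  negative in the visual task and positive in the memory task.

The waveform shapes are parametric stand-ins — the source figures show but
do not parameterize them — chosen for analytic tractability: Gaussian bumps
and a logistic plateau make window means available in closed form for the
tests. Field gains multiply each component: by default upper/lower = 2.7/1.0
(peri-saccadic), 2.5/1.0 (stimulus), 1.5/1.0 (delay), switching as a step at
the horizontal meridian (`fieldModel = "step"`). The `"linear"` control
model interpolates the gain continuously across direction and exists so the
topography stage can demonstrate it distinguishes a genuine step from a
gradient.

Spike trains are inhomogeneous Poisson, simulated by thinning against a
1 ms-grid bound: baseline 10 sp/s, a visual burst (peak 100 sp/s, gains
1.5/1.0 — stronger upper), a field-independent delay rate (20 sp/s), and a
motor burst (peak 200 sp/s 20 ms after saccade onset, gains 0.7/1.0 —
*weaker* upper, the dissociation at the heart of the analysis).

Noise has three parts: pink (1/f) noise at 15 uV per-sample SD, white noise
at 5 uV, and mains sinusoids of 20/10/5 uV at 50/100/150 Hz with random
phases. Pink noise is synthesized by filtering white Gaussian noise through
a cascade of first-order pole/zero sections spaced two per decade (the
classical pinking-filter construction); the scale is set analytically from
the cascade's impulse-response energy, keeping the generator linear and
Gaussian. Noise amplitudes are round values of the order seen in
extracellular recordings; they were fixed once, before any recovery test
was run, and give a per-session measurement SEM of roughly 1–2 uV at
30–50 trials.

What the generator does *not* emulate: biophysical LFP generation, volume
conduction and electrode impedance, eye-position signals, microsaccades,
behavioral errors, session-to-session gain variability, and non-stationary
line noise. Passing the recovery suite therefore shows the *pipeline* is
correct and calibrated under realistic noise — not that real SC recordings
would yield these exact numbers.

## Numerical choices

* **Zero-phase filtering** pads with an odd (point-reflected) extension of
  length three times the filter's effective impulse-response length (time
  to decay to 1%, capped at 1e5 samples) and uses steady-state initial
  conditions scaled to the first padded sample. Narrowband notches still
  ring near recording edges; sessions carry a 0.5 s lead-in and tail so all
  analysis epochs are interior.
* **Notch bandwidth** is unstated in the source analysis; Q = 35 (−3 dB
  width 1.4 Hz at 50 Hz) is the default and configurable. The low-pass
  family/order is likewise unstated; a 4th-order Butterworth applied
  forward–backward (flattest passband) is used. Because zero-phase
  application squares the magnitude response, the designed response is not
  perfectly flat to 200 Hz: roll-off reaches 1.7% at 180 Hz and 3.8% at
  200 Hz, and each constant-Q notch carries a transition band that widens
  with frequency (about ±10/±20/±30 Hz around 50/100/150 Hz at the 1%
  level). The tests therefore assert sub-1% flatness wherever the designed
  response promises it and, separately, that the implemented chain matches
  the designed closed-form response within 1% over all of 1–200 Hz.
* **Decimation** keeps every 40th sample from phase 0 — safe because the
  300 Hz cut-off is well below the 500 Hz output Nyquist.
* **Event-to-sample rounding** is round-half-up at 1 kHz; windows are
  half-open so "0–50 ms" is exactly 50 samples and adjacent windows tile.
* **Spike-density truncation** at ±5 SD, no edge renormalization: epochs of
  interest are interior, where truncation error is below 1e-6 of a spike.
* **Trials whose window exceeds the recording** are dropped and counted in
  a message, never padded.
* **Degenerate inputs**: horizon sites (direction 0) are rejected; zero
  pooled variance with unequal means, zero within-group sums of squares
  with unequal means, and factors collapsing to one level all raise errors
  rather than returning numbers.

## Statistics design

The field comparison is a two-sided pooled-variance two-sample t test
(upper group first, so "upper more negative" appears as t < 0); a Welch
variant is available. The one-way ANOVA across direction bins inherits the
overlap of the sliding bins — sessions appear in up to two groups, so group
counts exceed session counts and independence across groups is violated;
this is replicated deliberately because the published df accounting
(n = 351 memberships from 198 sessions; 12 retained bins giving
F(11, 339)) is only consistent with exactly this overlap.

The two-way field-by-bin ANOVA uses Type II sums of squares on an additive
main-effects model by default (each factor adjusted for the other;
invariant to level ordering). The published error dfs (185 with N = 193,
166 with N = 172, 117 with N = 123) all equal N minus the number of cells,
implying the original software kept the field-by-bin interaction in the
error term even though only main effects were reported;
`errorModel = "full"` reproduces that accounting, and both variants are
verified against an independent Type II implementation. Empty field-by-bin
cells are excluded together with their counterpart field's sessions for
that bin. No multiple-testing correction is applied (none was reported).

Very small p-values are reported exactly (via the incomplete beta), so
lines that were originally printed as "p = 0" are not bit-reproducible.

## Scale of the verification runs

The recovery suite simulates 60 + 60 sessions of 50 trials at the full
40 kHz bandwidth for the main parameter-recovery check, 20 + 20 sessions
per task for the sign-structure checks, 1 kHz-bandwidth datasets of
60 + 60 sessions for the step-versus-gradient contrast, and 1000 replicate
null datasets (20 sessions per field, 20 trials) for Type-I error
calibration — sizes chosen so that each check's statistical resolution
comfortably exceeds the tolerance it asserts. The Type-I calibration
simulates trials at the epoch level in the conditioned (1 kHz,
line-noise-free) domain, which is the regime the t test actually consumes;
its null distribution is unaffected by the wideband front end, which is
exercised separately.

## Known limitations

* Every session of a field shares the same ground-truth gains; real data
  have site-to-site amplitude variability, which would widen the
  between-session variance the t tests see.
* The exact direction-bin edge set (lower edges 0..70 deg) is a
  reconstruction constrained by the published retained-bin count and
  membership total, not printed anywhere.
* The generator resolves "~50 ms" flash duration to exactly 50 ms, and the
  published session-count discrepancy (103 vs 102 lower-field tracks) is
  left to the caller: session counts are parameters.
* The hardware acquisition band-pass (0.7 Hz – 6 kHz) is emulated only on
  request (`hardwareBandpass = TRUE`); at analysis bandwidth the software
  chain dominates.

## A small worked run

```{r example}
cfg <- generatorConfig(fsHz = 2000)   # reduced bandwidth for the vignette
ds <- generateDataset(4, 4, 6, "visual", cfg, masterSeed = 11)
sessions <- lapply(ds$sessions, preprocessSession)
m <- sessionMeasurements(sessions, "lfp", "PERISACC")
asymmetryRatio(m$value[m$field == "upper"], m$value[m$field == "lower"])
fieldTTest(m)
```

The ratio recovers the injected 2.7 up to noise, and the t statistic is
negative: the upper-field LFP is the more negative one.
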