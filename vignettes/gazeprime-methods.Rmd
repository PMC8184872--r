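---
title: "Methods: from raw gaze samples to repeated-measures inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw gaze samples to repeated-measures inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeprime)
```

`gazeprime` implements an analysis chain for 300 Hz gaze recordings from a
saccadic precueing experiment, together with a synthetic-data generator
that emulates the experiment closely enough that every stage of the chain
can be verified against known ground truth. This vignette explains the
models and the choices behind them; it states no empirical result that the
package's tests and acceptance script do not themselves compute.

## The experimental design

A session is 10 blocks of 84 trials. Each trial is 2000 ms: 500 ms central
fixation, a background image shown for 1000 ms, and a 500 ms return phase.
The go-cue — a color change of the fixation dot — appears at an SOA of 100,
200, 400 or 600 ms after image onset; blue cues a leftward and green a
rightward 12° saccade, red (always at SOA 400) cues none. Per session
there are 320 head-congruent, 320 handle-congruent, 160 control and 40 red
trials. A printed "40 repetitions per tool-end × SOA cell" cannot be
reconciled with those totals over four SOAs, so the per-condition totals
are treated as authoritative: head and handle cells hold 40 trials per SOA
per direction, control cells 20. Left/right cues are balanced exactly
within every non-red cell; head/handle trials are split 50/50 between
horizontal and oblique orientations (configurable via `oblique_frac`),
control items are horizontal only. Randomisation is a uniform shuffle of
the whole session; a `block_balanced` flag stratifies conditions across
blocks instead, since blocks otherwise act only as rest units.

## The synthetic gaze generator

The generator's role is to produce traces whose statistical structure
matches what the analysis assumes, with every quantity of interest known
exactly.

**Kinematics.** Saccades follow the oculomotor main sequence with
conventional constants: duration `d0 + d1·A` (defaults 21 ms + 2.2 ms/deg)
and peak velocity `vmax·(1 − e^{−A/a0})` (defaults 500 deg/s, 14°). The
velocity profile is Gaussian in time, scaled so that its discrete integral
equals the requested amplitude exactly and its peak equals the
main-sequence peak velocity; the profile width therefore follows as
`σ = A/(V_p·√(2π))` and its support is truncated at ±2.2σ and
renormalised. Two consequences are worth stating plainly. First, the
*effective* movement duration (≈ 4.4σ, about 73 ms for a 12° saccade)
exceeds the main-sequence duration law, because a Gaussian cannot satisfy
the amplitude integral, the peak-velocity law, and the duration law
simultaneously; peak velocity and amplitude were chosen as the binding
constraints since threshold-based detection depends on them and the
duration law is still reported by `main_sequence()` for analysis use.
Second, ground-truth saccade onset is defined *operationally* as the time
the noise-free velocity profile first reaches the 50 deg/s detection
threshold. This gives the generator and the detector one shared onset
convention, which is what makes sample-exact recovery a meaningful
contract; the quantity the pipeline calls SRT is latency from cue onset to
that threshold crossing.

**Latencies.** Trial latencies are ex-Gaussian — a Gaussian trial
component (`trial_sd`, default 40 ms) plus a mean-centred exponential tail
(`exgauss_tau`, default 30 ms) — on top of an additive structure: a
condition mean (defaults 393/402/402 ms for head/handle/control), an SOA
shift (+33.75/+8.75/−16.25/−26.25 ms, the published SOA means expressed as
deviations from their grand mean), and a Gaussian between-subject offset
(`subject_sd`, default 54 ms ≈ 10.6·√26, matching between-subject SEMs of
~10.6 ms over 26 subjects). Latencies are floored at 80 ms. No random
subject-by-condition interaction is modelled: the calibration targets are
per-condition means and SEMs, from which such a term is not identifiable.
Draws whose saccade could not complete before trial end are recorded as
ground-truth omissions rather than errors.

**Artifacts.** Position noise is white Gaussian (default 0.1° RMS per
axis). Blinks arrive as a Poisson process (default 3/min) with uniform
durations of 100–250 ms — always at least the 10 samples the blink rule
needs — simulated as signal loss with an optional eyelid deflection on the
flanking samples to exercise the padding rule. Isolated dropouts occur at
a small per-sample rate, and a damped post-saccadic oscillation (default
0.15°, 35 Hz, 20 ms decay) exercises the 9-sample landing average. A
return saccade to the screen centre is generated in the return phase.

**What the generator does not emulate:** pupil dynamics, binocular
vergence, smooth pursuit, microsaccade statistics, drift, calibration
error, or any dependence of saccade endpoints on image content. Passing
recovery tests on these traces shows the pipeline is correct under its own
assumptions; it does not certify behaviour on pathologies the generator
does not produce.

## Preprocessing

The position filter is a Chebyshev type II low-pass of order 8 with its
stopband edge at 0.3·π rad/sample and 60 dB stopband attenuation — the
family that places its specification exactly at those two numbers — applied
forward and backward for zero phase. "0.3 radians·π/sample" is read as the
stopband edge (the frequency where 60 dB is first attained). Zero-phase
application preserves event latencies, at the price of Gibbs-like ringing
around sharp transients; the landing-point average exists to cancel
exactly that. Numerically, each pass runs on a signal padded by 64 samples
of odd end-point reflection and detrended to its endpoint line, so the
zero-state transients of the IIR passes act on a signal that starts and
ends at zero; constants therefore pass through bit-nearly unchanged and
edge transients are controlled without initial-condition matching.

Blinks are detected on the *raw* validity flags as runs of ≥10
continuously lost samples, extended by 20 samples on each side (clipped at
segment edges), and set to missing; shorter gaps stay missing but
unpadded. Masking runs **before** filtering — the source description lists
filtering first, but an IIR filter cannot cross NaNs, so each contiguous
finite segment is filtered independently and nothing is interpolated
through a blink. Segments shorter than `3·(order + 1)` samples are left
unfiltered rather than risking a transient longer than the data.

## Saccade detection and trial metrics

Velocity is computed from x and y together: central differences in the
interior of each finite segment (no phase lag), one-sided differences at
segment edges, undefined wherever a contributing sample is missing. An
event opens at the first sample of a run of ≥3 samples at or above
50 deg/s and closes at the last above-threshold sample before a run of ≥3
below it, a missing sample, or the end of the trace. Sub-persistence dips
inside an event do not close it, which keeps ringing from splitting one
saccade in two. The 100 deg/s threshold *classifies* events by peak
velocity rather than gating detection — this keeps a single onset
definition for all events — and an `onset_at_big` switch restores the
two-threshold detection reading for sensitivity analyses. The landing
point is the mean of up to 9 finite samples after the offset, with the
count actually used recorded.

The response saccade is the first large event with onset after the cue and
before trial end, latency ≥80 ms, and (by default) direction matching the
cue. Trials without one receive exactly one status — `anticipatory`,
`wrong_direction`, `blink_contaminated`, or `no_saccade` — and red trials
are `red_excluded` before any aggregation. The original analysis does not
state trial-level exclusion rules; this taxonomy is the package's own,
with every exclusion logged and the direction check toggleable. Saccadic
error is the Euclidean distance from the landing point to the target cross
at (±12°, 0°) — targets stay on the horizontal axis for oblique stimuli —
and is rounded only at the subject-average level, to the nearest multiple
of 0.03° (one pixel's worth), ties upward. Subject exclusion for "poor
data quality" is operationalised as an overall missing-sample fraction
above 0.3 (configurable).

## Inference

The repeated-measures ANOVA performs the full balanced within-subject SS
decomposition (every effect, the subject main term, and each
effect-by-subject error stratum) on the subject × cell table, testing each
effect against its own error stratum. Greenhouse–Geisser ε is estimated
per effect by projecting the per-subject cell vectors onto the effect's
orthonormal contrast space (Kronecker products across factors) and
applying the trace formula to the projected covariance, clipped to
`[1/df1, 1]`; the correction is applied uniformly to every effect with
more than one numerator df, with no sphericity pretest, and corrected
p-values come from the F distribution at `(ε·df1, ε·df2)`. Generalized eta
squared divides the effect SS by itself plus *all* subject-related SS —
the all-manipulated-factors convention, since every design factor here is
manipulated. The three-way SRT analysis (tool end × SOA × orientation)
excludes control items, which have no oblique orientation. Paired t-tests
report raw p-values as the primary (historically matching) column with
Holm-adjusted values alongside; a zero-variance difference yields a capped
statistic with an explicit `degenerate` flag instead of a numerical
infinity. The implementation is cross-checked in the test suite against
`stats::aov` multistratum fits and against textbook summation formulas.

## Geometry and I/O

Pixel-to-degree conversion uses the exact per-axis tangent about the
screen centre — at 12° eccentricity the small-angle error is visible in
the tests — with a `linear` flag restoring the linearisation. The
published equivalence 0.03° ≈ 1 px is not derivable from typical panel
dimensions at 670 mm, so geometry is fully configurable and 0.03° is
treated as a rounding constant, not a derived quantity. Raw gaze tables
are delimited text with remappable column names; invalid or non-finite
samples become missing flags, timestamps are normalised to ms from
recording start, non-monotonicity is a hard error and sampling jitter
beyond 1% warns. Binocular averaging is out of scope of the table reader;
traces are assumed cyclopean.

## Problem sizes and reproducibility

The package-level recovery runs (acceptance script and end-to-end test)
simulate 26 subjects × 840 trials at 300 Hz — the full design — which
takes on the order of a minute per cohort. The null-calibration check
runs 1000 replications at 8 subjects and 40 trials per cell, generated at
the latency level: a separate sample-precision test shows the trace stage
adds only a condition-independent threshold-crossing constant plus
sub-sample quantisation to each SRT, so repeating the trace stage 1000
times would add cost but no information. Detector-oracle equivalence uses
1000 short random velocity traces against an independent state-machine
enumeration. All randomness flows from explicit seeds: cohorts derive
per-subject child seeds deterministically from the master seed, so
subjects can be regenerated independently and in any order.

## Known limitations

- The generator's endpoint scatter is condition-independent; saccadic
  error analyses run, but the published error *differences* between
  conditions are not targets of the simulation.
- Trial-level exclusion rules and the latency distribution shape are
  modelling choices, not reproductions; only condition means and SEMs are
  calibrated.
- The ANOVA requires a complete balanced table (one value per subject per
  cell) and rejects anything else rather than imputing.
- Event detection assumes uniform sampling; recordings with real jitter
  beyond 1% must be resampled upstream.
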