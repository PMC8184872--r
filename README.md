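# gazeprime

Saccade detection and reaction-time analysis for high-speed eye-tracking
cueing experiments, with a fully verifiable synthetic-data path.

## The problem

In implicit precueing paradigms a participant fixates a central dot that
changes color after a variable stimulus onset asynchrony (SOA); the color
cues a 12° leftward or rightward saccade (or withholds it) while a
task-irrelevant image — here, a hand-held tool whose *head* or *handle* lies
on the cued side — appears in the background. The question is whether the
tool's structure primes the oculomotor system: are saccadic reaction times
(SRTs) shorter toward the functional end? Answering it requires a chain of
signal-processing and inference steps on 300 Hz gaze recordings, each with
parameters that materially affect the result. `gazeprime` packages that
chain as composable, tested tibble-in/tibble-out functions for researchers
in oculomotor psychophysics:

1. **Design** — balanced 3 × 4 within-subject schedules (tool end ∈
   {head, handle, control} × SOA ∈ {100, 200, 400, 600} ms), 10 × 84 trials
   with 320/320/160 analysed trials plus 40 red catch trials.
2. **Synthetic gaze** — a generator with main-sequence kinematics
   (duration `d0 + d1·A`; peak velocity `vmax·(1 − e^{−A/a0})`), ex-Gaussian
   latencies, position noise, blinks and signal dropouts, emitting traces
   with known ground truth so every downstream stage is verifiable.
3. **Preprocessing** — blink masking (≥10 continuous lost samples, padded
   by 20 samples on each side) and zero-phase Chebyshev-II low-pass
   filtering (stopband edge 0.3·π rad/sample, 60 dB attenuation) that
   leaves event latencies unshifted.
4. **Saccade detection** — combined-axis velocity with dual thresholds
   (50 deg/s detects all saccades, 100 deg/s classifies the large response
   saccades) and 3-consecutive-sample persistence for onsets and offsets;
   landing points averaged over 9 post-offset samples to cancel
   filter-induced ringing.
5. **Metrics** — response-saccade selection, SRT (cue onset → saccade
   onset), saccadic error (Euclidean landing-to-target distance, subject
   averages rounded to 0.03° ≈ 1 px), trial-status taxonomy and
   missing-data subject exclusions.
6. **Inference** — repeated-measures ANOVA with full within-subject SS
   decomposition, per-effect Greenhouse–Geisser ε (df correction
   `(df1, df2) → (ε·df1, ε·df2)`), generalized eta squared
   `η²G = SS_effect / (SS_effect + ΣSS_subject-related)`, and paired
   t-tests with optional Holm adjustment.

## Worked example

Simulate and analyse a small cohort end-to-end (8 subjects, full 840-trial
sessions; ~20 s):

```r
library(gazeprime)
library(dplyr)

res <- process_cohort(n_subjects = 8, master_seed = 42)

res$summaries |>
  group_by(subject_id, tool_end) |>
  summarise(srt = mean(mean_srt_ms), .groups = "drop") |>
  group_by(tool_end) |>
  summarise(mean = mean(srt), sem = sd(srt) / sqrt(n()))
#>   tool_end  mean   sem
#> 1 control   393.  25.5
#> 2 handle    393.  24.3
#> 3 head      384.  24.8

fit <- rm_anova(filter(res$summaries, tool_end != "red"),
                "mean_srt_ms", within = c("tool_end", "soa_ms"))
fit
#> Repeated-measures ANOVA on 'mean_srt_ms' (8 subjects)
#>   tool_end         F(1.61, 11.27) = 25.405, p = 0.0001122 (G-G), eps = 0.805, eta_G2 = 0.0038
#>   soa_ms           F(2.24, 15.70) = 406.602, p = 1.696e-14 (G-G), eps = 0.748, eta_G2 = 0.0995
#>   tool_end:soa_ms  F(2.92, 20.42) = 0.554, p = 0.6465 (G-G), eps = 0.486, eta_G2 = 0.0003
```

Head-congruent saccades come out ~9 ms faster than handle-congruent ones —
the priming effect injected by the calibrated latency generator — while the
huge SOA main effect reflects the built-in foreperiod gradient
(433/408/383/373 ms across the four SOAs). A paired test on the condition
means:

```r
paired_t(res$summaries |> group_by(subject_id, tool_end) |>
           summarise(srt = mean(mean_srt_ms), .groups = "drop"),
         "srt", "tool_end", "handle", "head")
#>   pair              t    df mean_diff        p degenerate
#> 1 handle - head  7.55     7      8.95 0.000132 FALSE
```

`tidy(fit)` and `glance(fit)` return the effect table and model summary as
tibbles; `autoplot(fit)`, `plot_gaze_trace()` and `plot_condition_means()`
provide quick visual checks.

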