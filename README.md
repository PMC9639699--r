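# ambientfocal

An R pipeline for analysing free-viewing scene-perception eye-tracking
experiments that manipulate the visual field with gaze-contingent masks:
a **central** condition (a 5° window around gaze is visible), a
**peripheral** condition (a 5° scotoma hides the fovea/parafovea), and an
unmasked **control** condition.

The package is aimed at researchers who record raw gaze samples (1000 Hz
EyeLink-style streams) during 20-s scene viewing and want a fully
accounted, reproducible path from samples to the quantities this
literature reports:

- **Event detection** — blinks from missing pupil signal; saccades by an
  EyeLink-style parser (speed > 30°/s *or* |acceleration| > 8000°/s²,
  sustained ≥ 4 ms, deflection > 0.1°); fixations as the complement, so
  fixations + saccades + blinks partition each trial.
- **Cleaning cascade** — four ordered rules with exact per-stage
  accounting: events starting before scene onset; events within 100 ms
  of a blink; fixations shorter than 80 ms or longer than 1000 ms
  (bounds kept); trials with ≥ 4 s total blink time. Removed events are
  quarantined with reasons, never silently dropped.
- **Time-course model** — fixation durations and saccade amplitudes are
  binned into 500-ms viewing-time intervals (participant means first,
  then across-participant means with t-based 95% CIs) and fitted with
  the nonlinear asymptote model

  ```
  fd(t) = b · exp(a / t)
  ```

  where `b` is the asymptote and `a` the signed acceleration rate
  (negative `a`: the curve rises toward `b`, the fixation-duration case;
  positive `a`: it falls, the saccade-amplitude case, fitted with the
  first two bins excluded). *Time-to-asymptote* is the first bin whose
  95% CI contains the fitted `b`.
- **Ambient/focal classification** — a fixation preceded by a saccade
  larger than 5° is *ambient* (exploratory); at or below 5°, *focal*
  (scrutinising); fixations with no abutting preceding saccade stay
  *unclassified*.
- **Tidy exports** — per-participant summary tables by condition, scene
  type, early (0–2 s) / late (6–8 s) interval and fixation type, ready
  for any standard repeated-measures ANOVA tooling.
- **Synthetic scanpath simulator** — generates gaze streams and
  ground-truth event logs with condition-specific time-course curves,
  mask-consistent saccade targeting, Poisson blinks and Gaussian gaze
  noise, so every stage of the pipeline is testable without recorded
  data.

## Worked example

Simulate a small experiment (6 participants × 90 trials, event-level
output), run the full pipeline and inspect the fits:

```r
library(ambientfocal)

cfg <- sim_config(n_participants = 6, trials_per_condition = 10, seed = 42)
d   <- simulate_dataset(cfg)
res <- run_pipeline(events = d$truth, manifest = d$manifest)
res$fits
#> # A tibble: 8 × 8
#>   measure               group           b      a b_ci_lo b_ci_hi converged reach_time_s
#>   <chr>                 <chr>       <dbl>  <dbl>   <dbl>   <dbl> <lgl>            <dbl>
#> 1 fixation_duration_ms  pooled     305.   -0.280  299.    311.   TRUE               3
#> 2 fixation_duration_ms  central    283.   -0.196  276.    289.   TRUE               2
#> 3 fixation_duration_ms  control    327.   -0.316  318.    336.   TRUE               2.5
#> 4 fixation_duration_ms  peripheral 314.   -0.332  307.    322.   TRUE               2
#> 5 saccade_amplitude_deg pooled       5.83  0.431    5.77    5.89 TRUE               4
#> 6 saccade_amplitude_deg central      3.25  0.203    3.21    3.30 TRUE               3
#> 7 saccade_amplitude_deg control      5.68  0.531    5.57    5.79 TRUE               4
#> 8 saccade_amplitude_deg peripheral   8.93  0.462    8.76    9.10 TRUE               4
```

Each row is one asymptote fit: the fixation-duration asymptote `b` (ms)
rises from the central (283 ms) through the peripheral (314 ms) to the
control condition (327 ms, here with a pooled fit of 305 ms), while the
saccade-amplitude asymptote `b` (degrees) orders central (3.3°) <
control (5.7°) < peripheral (8.9°) — the masks force short saccades
inside a 5° window and long ones across a 5° scotoma. `reach_time_s` is
the first 500-ms bin whose confidence interval contains `b`.

Condition-level grand means (participant means first, then unweighted
means across participants):

```r
grand_means(res$summaries$condition)
#> # A tibble: 3 × 4
#>   condition  mean_fd_ms mean_sa_deg n_participants
#>   <chr>           <dbl>       <dbl>          <int>
#> 1 central          268.        3.45              6
#> 2 control          301.        6.71              6
#> 3 peripheral       289.       10.0               6
```

Raw gaze streams go through the same front door: `read_gaze_samples()`
(CSV or a minimal EyeLink-ASC-like subset), then
`run_pipeline(samples = ...)` runs detection first; `res$cleaning$report`
shows what each cleaning rule removed and `res$summaries` the tidy
per-participant tables.

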