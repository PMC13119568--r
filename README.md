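# hrrhythm

Trend analysis of stress-related heart-rate rhythm from wearable data.

Consumer smartwatches record heart rate at 1 Hz as a rolling one-minute
average, together with timestamped self-reports of stress. Because this
signal is too smooth for beat-to-beat heart-rate-variability metrics,
`hrrhythm` characterises the *temporal structure* of the signal around
stress reports instead, and asks whether that structure differs from
ordinary wear time. For each participant it:

1. removes physiologically implausible samples (below 60 bpm or above the
   age-predicted maximum `220 − age`);
2. extracts 20-minute **stress windows** (±10 min around each report) and an
   equal number of randomly placed, disjoint **normal windows**;
3. tests each window for stationarity (Augmented Dickey–Fuller, constant
   term, AIC lag selection, MacKinnon p-values) and applies first-order
   differencing uniformly;
4. extracts rhythm features per window:
   * **significant-lag count** — lags whose autocorrelation exceeds the
     95% band (`1.96/√n` or Bartlett);
   * **peak count** — strict local maxima of the autocorrelation sequence;
   * **scaling exponent α** — from-scratch detrended fluctuation analysis
     (profile integration, both-ends segmentation, order-1 detrending,
     log–log OLS fit), where α ≈ 0.5 is white noise, α ≈ 1.0 pink noise,
     α ≈ 1.5 Brownian persistence;
5. averages features per participant and compares stress against normal
   with paired t-tests (`t = mean(d)/(sd(d)/√n)` on the per-participant
   differences), plus Mann–Kendall tests (tie-corrected, continuity
   correction) for event-frequency trends by hour and weekday.

A synthetic cohort generator (spectral synthesis of `1/f^β` noise with
`β = 2α − 1`, circadian baseline, spliced stress episodes, artifact
contamination) makes the full pipeline testable without device data.

## Worked example

```r
library(hrrhythm)

sim <- sim_config(n_participants = 10, duration = 43200,
                  events_per_participant = 5,
                  normal_alpha = 0.7, stress_alpha = 1.0,
                  stress_mean_shift = 8, noise_sd = 5,
                  artifact_rate = 0.062, seed = 42)
res <- run_pipeline(pipeline_config(sim = sim, seed = 42))
print(res)
```

```
<pipeline_result>
<cohort_summary> 50 events from 10 participants (mean 5.0, sd 0.00, median 5)
  weekday/weekend events per day: 10.0 / 0.0
  stress-window HR: mean 89.5, sd 5.31, median 89.45 bpm
  comparison over 10 participant pairs:
           parameter   transform mean_normal mean_stress difference t_statistic
1 n_significant_lags      actual     39.3800    394.7800   355.4000      22.793
2 n_significant_lags differenced     29.0600     22.3000    -6.7600      -5.241
3            n_peaks      actual    179.3200    131.4400   -47.8800     -27.787
4            n_peaks differenced    223.3800    210.0200   -13.3600     -11.905
5              alpha      actual      0.7123      0.9835     0.2711      31.601
    p_value n_pairs
1 2.858e-09      10
2 5.342e-04      10
3 4.917e-10      10
4 8.239e-07      10
5 1.562e-10      10
```

This cohort was simulated with stress episodes that are both elevated
(+8 bpm) and more persistent (α 1.0 vs 0.7), and the report recovers
exactly that signature: the stress windows carry far more significant
autocorrelation lags, *fewer* ACF peaks (smoother, more self-similar
correlograms), and a scaling exponent near the injected 1.0 against 0.71
for normal windows — each contrast significant in the paired test across
the 10 participants. The differenced rows show the same comparison after
first-order differencing.

Single components work standalone:

```r
x <- generate_long_range_noise(2^14, alpha = 1.0, seed = 1)  # pink noise
dfa_alpha(x)
#> <dfa_result> alpha = 1.039 (R^2 = 0.999), 15 scales [4..4096], n = 16384
```

A thin CLI wraps the same functions
(`Rscript inst/cli/hrrhythm-cli.R simulate|run-all --config cfg.yaml ...`).

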