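---
title: "Methods: stress-related heart-rate rhythm analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-related heart-rate rhythm analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrrhythm)
```

## The problem

Consumer smartwatches record a temporally smoothed heart rate — each 1 Hz
sample is the average over the preceding minute — alongside user-initiated
stress reports. The question this package addresses is whether the *rhythm*
of that signal, not just its level, differs between the 20 minutes
surrounding a stress report and ordinary wear time. Classical
heart-rate-variability metrics need beat-to-beat (RR) intervals, which this
signal cannot provide; instead we characterise temporal structure directly:

* **Autocorrelation (ACF) features** — how many lags carry significant
  serial correlation, and how rough the correlogram is (its count of local
  maxima);
* **Detrended fluctuation analysis (DFA)** — the scaling exponent
  $\alpha$ of long-range correlation ($\alpha \approx 0.5$ white noise,
  $\approx 1.0$ pink noise, $\approx 1.5$ Brownian persistence);
* **Trend tests** — the Mann–Kendall test for monotone trends in event
  frequency, and paired t-tests for stress-versus-normal contrasts of
  per-participant feature averages.

## Preprocessing

Samples below 60 bpm or above the age-predicted maximum $220 - \text{age}$
are treated as sensor artifacts and removed; both bounds are read strictly
(60 itself survives). Each stress report anchors a window of
$\pm$ `half_width` seconds (default 600 s, i.e. a 20-minute window at 1 Hz
containing a nominal 1201 samples). Filtering precedes windowing, so windows
may contain gaps: a window is retained only if it keeps at least
`min_coverage` (default 80%) of its nominal samples. Windows overlapping a
recording boundary are dropped with a warning. Reports closer together than
the window length yield overlapping stress windows; both are kept, since
nothing in the study design deduplicates reports.

Per participant, the same number of *normal* windows as retained stress
windows is drawn. Placement is uniform at random under a recorded seed,
subject to the normal spans being disjoint from every stress span and from
each other; a deterministic rule (e.g. fixed offsets) would risk aliasing
with circadian structure. If the recording cannot host the requested number
of disjoint windows, as many as possible are returned with a warning and the
participant's pairing uses what exists.

## Stationarity handling

Each window is tested with an Augmented Dickey–Fuller regression containing
a constant and no deterministic trend term — heart-rate windows have a
nonzero mean but no prescribed linear drift. The augmentation lag is chosen
by AIC below the Schwert bound $\lfloor 12 (n/100)^{1/4} \rfloor$, with all
candidate models compared on a common trimmed sample; p-values use the
MacKinnon approximate response-surface for the constant-only case. A
constant window admits no unit-root regression and is flagged degenerate.

Following the study design the pipeline then applies first-order
differencing to *every* window uniformly — ADF outcomes are recorded for
reporting, not used as a gate — and ACF features are extracted from both the
actual and the differenced series, since both carry interpretable (and
different) information.

## ACF features

The estimator is the standard biased one (lag-$k$ cross-products normalised
by $n$ and the overall variance), so $\hat\rho_0 = 1$ and
$|\hat\rho_k| \le 1$. Two 95% significance bands are offered: the constant
white-noise band $1.96/\sqrt{n}$ (default) and Bartlett's cumulative
large-lag band. The **significant-lag count** is the number of lags
$k \ge 1$ with $|\hat\rho_k|$ above the band. The **peak count** is the
number of strict interior local maxima of the ACF sequence; ties break
toward non-peak so the count is conservative and deterministic. Whether
peaks should additionally be restricted to significant lags is ambiguous in
the source methodology; both readings are implemented
(`peak_mode = "all"` default, `"significant"` optional).

`max_lag` defaults to 600, half the nominal window length. Counts scale
with `max_lag`, so reported magnitudes are only comparable within one
configuration; the pipeline therefore fixes it per run and records it in the
manifest.

## DFA

The series is integrated into a profile of cumulative deviations from the
mean, the profile is cut into $\lfloor n/s \rfloor$ segments of length $s$
from the start *and* the same number from the end (so the remainder is
covered at both ends rather than discarded), each segment is detrended by an
order-1 least-squares polynomial, and $F(s)$ is the RMS of the pooled
residuals. $\alpha$ is the OLS slope of $\log_{10} F(s)$ on $\log_{10} s$
over ~15 log-spaced scales in $[4, n/4]$; the fit's $R^2$ is reported.
Degenerate scales (zero fluctuation, e.g. an exactly linear profile) are
dropped with a warning, and fewer than four usable scales is an error.

Two choices deserve emphasis:

* **Span**: by default DFA consumes the 300 samples following the window
  centre (the five minutes after the report), the span on which the
  source analysis displays its DFA comparison; `dfa_span = "full"` uses
  all 1201 samples instead. At 300 samples the per-window $\alpha$ is
  noisy (SE roughly 0.1), which is why inference runs on per-participant
  averages.
* **Transform**: DFA always uses the undifferenced window. DFA does not
  require stationarity, and differencing would lower the exponent by
  construction (integration raises $\alpha$ by exactly 1, a property the
  tests verify), destroying comparability.

## Trend tests and comparison

Mann–Kendall uses $S = \sum_{i<j} \mathrm{sign}(x_j - x_i)$, the tie-corrected
variance, and a $\pm 1$ continuity correction; p-values are two-sided, and a
direction label is attached only when $p < 0.05$. The stress-versus-normal
comparison averages each feature per participant within label and applies a
paired t-test to the per-participant (stress, normal) pairs — participants,
not windows, are the unit of inference, so unequal window counts do not
bias the pairing. Differences are reported as stress minus normal. Three
uncorrected p-values per transform are reported, mirroring the
compared-metrics table layout; no multiplicity correction is applied by
default.

## The synthetic cohort generator

Real device data is not redistributable, so the generator emulates the
statistical features the analysis consumes:

* **Long-range-correlated noise** by spectral synthesis: a Gaussian random
  spectrum shaped to $S(f) \propto f^{-\beta}$ with $\beta = 2\alpha - 1$,
  inverse-transformed and standardised. This maps target $\alpha \in
  [0.5, 1.5]$ onto $\beta \in [0, 2]$; empirically the DFA estimate of the
  output is within ~0.01 of the target at $n = 2^{14}$. Spectral synthesis
  was chosen over Davies–Harte fractional Gaussian noise because it covers
  the nonstationary half of the range ($\alpha > 1$) in the same
  construction.
* **Circadian baseline**: a single 24-h sinusoid peaking late afternoon.
  Amplitude defaults to 5 bpm — a realistic magnitude for ambulatory HR —
  and the sinusoid is deliberately simple: the analysis operates on
  20-minute windows over which any smooth diurnal model is locally linear.
* **Stress episodes**: within `episode_half_width` (600 s) of each event,
  an independently generated noise segment with `stress_alpha` replaces the
  `normal_alpha` noise via a 30-sample linear cross-fade, and the mean is
  raised by `stress_mean_shift` with the same ramp. Splicing keeps the two
  regimes' exponents independently verifiable; the ramp avoids
  step-discontinuity artifacts at window edges. Events are placed uniformly
  with pairwise gaps above the window length so stress windows never
  overlap in simulation.
* **Artifacts**: a configured fraction of samples is replaced by values
  uniform on $[30, 59]$ or $[221 - \text{age}, 250]$ with equal
  probability — the filter bounds are known, the true artifact distribution
  is not, so the simplest distribution straddling the bounds is used.

Defaults follow the targeted study design where it states values: 1 Hz
sampling, 600 s half-width, 6.2% artifact rate, age 22, baseline 85 bpm
with an 8 bpm stress shift (stress-window level ≈ 93 bpm), and scaling
exponents 0.61/0.63 (normal/stress). The generator does *not* emulate
motion artifacts beyond the range filter, non-wear gaps, weekday/weekend
event-rate structure, or beat-to-beat variability — so green tests
demonstrate correct recovery of the modelled structure, not robustness to
everything real wearables produce.

## Reproducibility and numerical choices

Identical configuration plus seed reproduces a cohort, and a pipeline run,
byte-for-byte; per-participant streams derive deterministically from the
master seed, and all random placement is seeded. CSV/JSON outputs are
written with fixed formatting so reruns diff clean. Degenerate inputs
(constant windows, zero-variance paired differences, all-tied sequences)
are flagged rather than silently propagated.

The validation suite runs at desk scale, chosen for statistical resolution
rather than fidelity to cohort size: noise calibration at $n = 2^{14}$ over
20 seeds, test-size calibration with 2000 null replicates, and end-to-end
recovery on cohorts of 10 participants × 12 h × 5 events with a clearly
separated regime (normal $\alpha = 0.7$, stress $\alpha = 1.0$, +8 bpm).
The separation is intentionally larger than the 0.61/0.63 defaults: the
recovery check asks whether the pipeline's *direction* inference is sound
at a cohort size 20 small cohorts can resolve, not whether it reproduces
any particular empirical effect size.

## Limitations

Window features depend on configuration (`max_lag`, band type, DFA span),
so absolute feature magnitudes are not comparable across configurations.
The ADF lag policy affects borderline stationarity calls, though nothing
downstream gates on them. The generator's uniform event placement means
simulated diurnal event-frequency trends are flat by construction; the
descriptive trend machinery is instead validated on directly constructed
hourly counts.
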