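---
title: "Artifact correction in beat-to-beat heart rate variability recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact correction in beat-to-beat heart rate variability recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvclean)
```

## The problem

Consumer heart-rate monitors — a GPS watch paired with a chest strap —
record two parallel channels during exercise: the beat-to-beat (RR)
interval series in milliseconds, and an instantaneous heart-rate trace in
beats per minute, equisampled (1 Hz for the devices this package targets).
The RR channel is raw and fragile: strap movement and transmission glitches
produce *peaks* (one recorded interval spanning two or more true beats,
typically exceeding the surrounding level by well over 300 ms) and *gaps*
(runs of empty samples). The HR channel, by contrast, is smoothed by the
device firmware and arrives clean.

HRV measures are highly sensitive to these artifacts, and classical filters
repair them at the cost of distorting the very measures being studied — a
width-7 median filter can cut RMSSD several-fold on low-variability
exercise data. The two algorithms implemented here are designed around the
opposite goal: repair every artifact while changing the eight standard
measures as little as possible, with no manual tuning.

A structural fact ties the two channels together: the sum of all
beat-to-beat durations approximately equals the duration of the heart-rate
trace,

$$\sum_{i=1}^{N} \mathrm{RR}_i \;\cong\; T,$$

and the misalignment does not accumulate with recording length.
`check_alignment()` reports the exact mismatch; `beat_time()` and
`hr_at_time()` translate between beat index and trace time using this
correspondence.

## Peak correction

`correct_peaks()` operates on the events found by `detect_peaks()`. A
sample is flagged when it exceeds the local baseline (median of the
defined samples in a centred window, excluding the sample itself) both by
a ratio (default 1.5) and by an absolute excess (default 300 ms, the
empirical magnitude of missed-beat spikes on chest-strap data; the guard
keeps slow beats at low heart rates from being flagged). The number of
true beats hidden in the spike, `est_beats`, is the rounded ratio of the
peak value to the baseline, floored at 2. Adjacent flagged samples — the
double artifacts that occur when two beats in a row are missed — are
merged into one event whose magnitude is their sum.

For each event, in order, with output indices shifted as the series grows:

* if `est_beats` is at most `max_multiple` (default 3), the sample is
  replaced by `est_beats` draws from
  $\mathcal{N}(\hat\mu, \hat\sigma)$, where $\hat\mu$ is the mean of the
  defined samples in windows of `2 * est_beats` beats on each side and
  $\hat\sigma$ is the mean of the per-side sample standard deviations
  (`surrounding_stats()`);
* otherwise the sample is converted into a gap of `est_beats` missing
  markers and left to the gap filler, which can exploit the heart-rate
  trace over the longer span.

Either way the series grows by `est_beats - width` samples, accumulated in
`total_new`.

### Numerical choices

*Clamping.* Normal draws are unbounded; each generated beat is clamped to
$\hat\mu \pm 3\hat\sigma$ and to strictly positive durations
(`clamp_draws = FALSE` restores the literal unbounded draws). At the
near-zero context variance typical of strenuous exercise the clamp is
inactive; it only guards pathological contexts.

*Sum rescaling.* A genuine missed-beat artifact conserves elapsed time:
the too-long interval is exactly the sum of the beats hidden inside it.
`rescale = TRUE` therefore multiplies the replacement beats by a common
factor so their sum equals the recorded peak value, which conserves
cumulative time per event exactly and keeps the alignment identity intact
for downstream gap filling. The default is nevertheless `rescale = FALSE`,
for a reason worth spelling out: the validation protocol (and any study of
filter-induced distortion on clean data) injects *synthetic* peaks at two
or three times the global series mean. Such a peak does not conserve local
elapsed time — on a drifting series the global mean differs from the local
level by the order of SDNN — so rescaling propagates the injection's time
distortion into the replacement beats and inflates the measure error
severalfold (the evaluation harness makes the comparison easy to
reproduce: run `run_experiment()` with `rescale = TRUE` passed through to
`correct_peaks()`). Plain draws from the local statistics are the
behaviour whose measure preservation the harness quantifies; rescaling is
the right choice when correcting real missed-beat spikes in field data.

*The SD of the draws.* The two per-side SDs are computed separately
(asymmetric contexts are informative when a trend runs through the
artifact) and combined by their mean for the replacement draws; nothing in
the procedure dictates a particular combination and the mean is the
neutral one.

## Heart-rate-guided gap filling

`fill_gaps()` reconstructs each run of missing beats found by
`detect_miss()`. For a gap of width $w$ starting at index $\ell$:

1. context means and SDs come from `surrounding_stats()` with windows of
   $2w$ beats per side; a side with fewer than two defined samples borrows
   from the other side, which also covers gaps touching the series
   boundary;
2. the gap's start time and nominal end time are mapped into the HR trace
   with `beat_time()` (missing prefix beats are substituted by the mean of
   their nearest defined neighbours so the mapping stays defined
   mid-correction);
3. for the $j$-th missing beat, the fractional position $d = j/(w+1)$
   interpolates the context statistics linearly:
   $\hat\mu_j = (1-d)\,\bar x_{\mathrm{before}} + d\,\bar x_{\mathrm{after}}$,
   and likewise $\hat\sigma_j$;
4. the beat's provisional end time locates a measured heart rate in the
   trace; the **corrective scale factor** is the ratio of the heart rate
   expected under a linear change between the gap endpoints to the
   measured one, clamped to $[0.5, 2]$ (`corrective_scale_factor()`). If
   the heart rate really does change linearly across the gap the factor is
   exactly 1; a measured rate above the linear expectation shortens the
   generated beat, one below lengthens it;
5. the beat is drawn from $\mathcal{N}(\hat\mu_j, \hat\sigma_j)$, clamped
   as above, multiplied by the factor, and written into the series; the
   running time cursor advances by the *generated* duration, so subsequent
   heart-rate lookups use realised, not nominal, positions.

The output has the same length as the input and no missing markers.

`hr_at_time()` interpolates the trace linearly between bracketing samples
(nearest-sample lookup is available via `hr_lookup = "nearest"`): linear
interpolation makes the corrective factor continuous in time, which
matters because consecutive generated beats sample the trace at
sub-interval spacing.

## Reference filters

Three standard methods serve as comparison baselines, behind the same
interfaces:

* `median_filter()` — sliding median of odd width; missing samples, and
  samples whose window touches one, pass through untouched (it is a spike
  tool, not a gap filler), as do boundary samples with incomplete windows;
* `threshold_cubic()` — flags samples deviating from the local median by
  more than `threshold` robust SDs (1.4826 × MAD of the window, excluding
  the sample; when the window is degenerate a 300 ms absolute rule takes
  over) and replaces them with a cubic-spline evaluation on non-flagged
  neighbours. The threshold is read as dimensionless (in robust SDs);
  published threshold filters in HRV software are parameterised in
  seconds, but the values quoted alongside this family of filters (3, 5)
  read naturally as sigmas and a dimensionless rule is scale-equivariant.
  Missing samples are never filled and flagged runs wider than half the
  window are left alone — longer holes stay unfilled, which is exactly the
  limitation the heart-rate-guided filler addresses;
* `cubic_spline_fill()` — deterministic gap filling by a cubic spline
  fitted on $2w$ defined samples per side. End conditions follow
  Forsythe–Malcolm–Moler (an exact cubic through the four points nearest
  each end) rather than natural end conditions: natural splines force the
  second derivative to zero at the ends and therefore cannot reproduce a
  cubic trend, while the FMM interpolant is exact on polynomials of degree
  at most 3 — a property the test suite checks. Boundary gaps are
  rejected; the stochastic filler handles those.

## The eight measures

`all_measures()` returns, in order: `rmssd`, `sdnn`, `sdsd`, `tp`, `lf`,
`hf`, `sd1`, `sd2`.

Time domain: RMSSD is the root mean square of successive differences,
SDNN and SDSD are sample ($n-1$) standard deviations of the intervals and
their successive differences. The sample convention is deliberate: on
published low-variability rows RMSSD and SDSD differ in the third digit
(3.09 vs 3.10), a signature of the $n$ vs $n-1$ denominators, and the
printed Poincaré cells are reproduced to two decimals under this
convention.

Poincaré: the scattergram descriptors follow the ellipse identities

$$\mathrm{SD1} = \mathrm{SDSD}/\sqrt{2}, \qquad
  \mathrm{SD2} = \sqrt{2\,\mathrm{SDNN}^2 - \tfrac12\,\mathrm{SDSD}^2},$$

evaluated internally with the population-convention SDSD so that
$\mathrm{SD1}^2 + \mathrm{SD2}^2 = 2\,\mathrm{SDNN}^2$ holds exactly.

Frequency domain: the tachogram is resampled at 4 Hz by cubic
interpolation over cumulative beat time, linearly detrended, and its PSD
estimated by Welch's method (Hann window, segments of at most 256 samples,
50% overlap). Band powers are trapezoidal integrals over 0.0033–0.40 Hz
(total power), 0.04–0.15 Hz (LF) and 0.15–0.40 Hz (HF). No reference
estimator is being matched here — absolute spectral scales are
estimator-dependent, which is why the evaluation harness works exclusively
with *relative* errors, where the estimator choice cancels to first order.
Series shorter than 30 s are rejected and shorter than 60 s draw a warning
(LF content is meaningless below roughly one minute).

## The synthetic generator

No public dataset pairs raw chest-strap RR with the device's smoothed HR
channel in the exercise regimes of interest, so validation runs on
synthetic stand-ins. `generate_rr_hr()` builds the RR series beat by beat,

$$\mathrm{RR}_i = \mu + \beta\Big(\tfrac{t_i}{T} - \tfrac12\Big)
  + a_{\mathrm{LF}} \sin(2\pi f_{\mathrm{LF}} t_i + \varphi_1)
  + a_{\mathrm{HF}} \sin(2\pi f_{\mathrm{HF}} t_i + \varphi_2)
  + \varepsilon_i,
  \qquad \varepsilon_i \sim \mathcal{N}(0, \sigma^2),$$

with $t_i$ the cumulative start time of beat $i$ and random phases per
realisation; generation stops when $t_i$ reaches the requested duration,
so the alignment identity holds to within one beat by construction. The HR
trace is $60000$ divided by the 5-beat moving average of the RR series,
resampled at 1 Hz — emulating the automatic smoothing the monitors apply
to their HR channel.

Two presets encode the validated regimes. Their components were sized once
from the published summary statistics of the corresponding recordings and
are not tuned thereafter:

* `needed_like` (strenuous cycling, hill-descent segment): mean RR 550 ms,
  linear drift 38 ms per 5 min, LF tone 3.3 ms at 0.09 Hz, HF tone 2.1 ms
  at 0.25 Hz, beat-to-beat noise SD 2 ms. This reproduces the defining
  feature of the regime — SDNN an order of magnitude larger than RMSSD
  (realised values around 11.5 and 3.2 ms against published originals of
  13.13 and 3.09): overall variability dominated by slow drift, with tiny
  beat-to-beat noise.
* `physionet_like` (uphill treadmill walking): mean RR 800 ms, drift
  130 ms, LF 51 ms at 0.08 Hz, HF 28 ms at 0.25 Hz, noise SD 12 ms,
  anchored to the published original row (RMSSD 32.18, SDNN 57.26,
  LF 1296, HF 403 ms²); a noise SD of 20 ms — the context-window
  dispersion reported for that data — would push RMSSD to about 40 ms, so
  the preset favours the printed measure values and leaves `noise_sd_ms`
  free.

What the generator does *not* emulate: respiratory sinus arrhythmia
coupling, ectopic beats, quantisation of the device clock, and
non-stationarity beyond a linear drift. Passing tests on these signals
demonstrate that the algorithms preserve second-order structure under the
stated artifact model; they do not certify behaviour on arrhythmic or
heavily non-stationary recordings.

## The evaluation harness

`run_experiment()` mirrors the validation protocol: for each of `reps`
(default 50) repetitions, one seeded generator stream drives — in fixed
order — signal generation, injection of a single artifact (a peak of 2× or
3× the series mean, or a gap of 3, 5 or 7 beats) at a random interior
position, and any stochastic correction. Relative errors
$100\,|m_{\mathrm{corr}} - m_{\mathrm{orig}}|/m_{\mathrm{orig}}$ are
averaged over repetitions first, then over the eight measures; measures
with numerically zero originals are excluded from the mean rather than
producing infinities, and the exclusion is recorded. One artifact per
repetition is the default, matching the protocol; the across-repetition SD
of each corrected measure is reported alongside.

```{r, eval = FALSE}
prof <- hrv_profile_preset("needed_like")
reports <- run_experiment(prof, "peak:2",
                          c("algorithm1", "threshold:5", "median:3"),
                          reps = 50, base_seed = 1000)
writeLines(format_report(reports))
```

Problem sizes throughout the shipped tests and the acceptance script are
5-minute recordings (about 550 beats) and 50 repetitions — the segment
length and repetition count of the protocol itself.

## Conventions, tolerances, degenerate inputs

* Indices are 1-based, the R convention; `beat_time(rr, i)` is the time
  before the i-th beat, so `beat_time(rr, 1) = 0`.
* Missing markers: `NA`/`NaN` in memory; `NaN` or an empty line in files
  (written canonically as `NaN`).
* RR sanity bounds: values must lie in (0, 5000] ms; HR values in
  (20, 250) bpm; both configurable at the reader level.
* Alignment warnings fire beyond a 2 s mismatch — a deliberate choice, as
  no tolerance is prescribed anywhere; misalignments observed on real
  device data are fractions of a second and do not grow with time.
* With zero context variance both correction algorithms are fully
  deterministic and seed-independent; with a seed supplied, reruns are
  bit-identical. RNG state is locally scoped (`withr::with_seed`), so
  calls do not perturb the caller's stream; `seed = NULL` deliberately
  joins the caller's stream instead, which is what the harness relies on.
* Ties in the peak detector's `round()` follow R's round-half-to-even; a
  peak whose ratio estimate falls below 2 is floored at 2 (a flagged spike
  hides at least one extra beat by definition).

## Known limitations

* The gap filler's reconstruction inherits any bias in the device's HR
  smoothing; a trace smoothed over many seconds will under-correct fast
  rate changes inside a gap (the factor clamp at [0.5, 2] also bounds how
  hard it can steer).
* Only too-long intervals are treated as peaks; abnormally short beats are
  left to the threshold filter, and ectopy classification is out of scope.
* Spectral measures on series near the 30–60 s floor are fragile
  regardless of correction quality.
* FIT-file parsing is out of scope: inputs are plain text/CSV exports.
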