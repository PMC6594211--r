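---
title: "Methods: cleaning, segmentation and weekly features for continuous home oximetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cleaning, segmentation and weekly features for continuous home oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxiweek)
```

## The measurement problem

A wearable finger pulse oximeter worn during daily home routines produces a
1 Hz SpO2 stream with three kinds of contamination: device-flagged invalid
samples (the sentinel value 500), spuriously low runs surrounding those
error values (motion and contact artifacts that the device's own quality
algorithm only partially brackets), and isolated single-sample outliers.
A simultaneously worn actigraph reports, once per minute, energy
expenditure in MET and binary lying-down/sleep indications. The analysis
goal is per-period SpO2 features — mean, SD, CT90 (percentage of measured
time below 90%) — per night, day, and day-in-rest, their weekly averages
and ranges, and the nocturnal-desaturator classification.

## Segmentation

Bed intervals are the maximal runs of consecutive lying minutes that
contain the night's first sleep minute; runs shorter than
`min_bed_minutes` (default 180 min) are ignored so afternoon naps do not
become nights. Nights are delimited noon-to-noon. All intervals are
half-open `[start, end)`, which guarantees that no sample is counted twice
at a boundary: a sample exactly at the bed start belongs to the night.
Samples during in-bed wake belong to the night segment — segmentation is
by bed interval, not sleep state. With no detectable bed interval the
stream is flagged unsegmentable and excluded (with a logged reason) rather
than guessed at.

Retention: a night must be covered by SpO2 samples over at least
`night_coverage_fraction` (default 0.9) of the bed interval ("full
night"); a day needs at least `min_day_seconds` (default 3600 s) of
samples. "Full night" has no canonical numeric definition, so the fraction
is a configuration parameter with a conservative default, and every
exclusion is logged with the measured quantity. A morning window is
computed but no morning contrast is reported — morning wear is too rare to
support one; the afternoon (13:00–18:00) vs evening (18:00–bed) contrast
requires at least one hour of samples in each window.

Activity labels follow MET cut-points: rest is MET ≤ 1.5 while awake, LIPA
is 1.5 < MET ≤ 3, MVPA is MET > 3; minutes scored as sleep are `asleep`.
The 1/min context is expanded to the 1 Hz grid by step assignment (each
minute's values apply to its 60 seconds, no smoothing): the simplest
alignment that cannot invent intermediate activity levels. Samples with no
covering actigraphy minute are `unaligned` and excluded from
activity-specific features.

## The four-step cleaning algorithm

Per segment, exactly once, in order:

1. **Small blocks.** Maximal runs of non-error samples that are bounded by
   an error sample on *both* sides and shorter than 20 samples are
   removed. Runs touching a segment edge or a recording gap are never
   removed by this step: removal is tied to lying *between* error values,
   and the edge rule is the conservative reading of that phrase.
2. **Deviating blocks.** Runs of 20–100 samples between error values are
   removed when their mean deviates by more than `dev_threshold` (default
   6) from the segment's context mean. The threshold is read as absolute
   percentage points of SpO2 — SpO2 is itself a percentage, and a relative
   reading (6% of ~93 ≈ 5.6 pp) is available via `dev_relative = TRUE`.
   The context mean is computed over all non-error samples of the segment
   *before* any exclusion, so the order of removals cannot change it.
3. **Median down-sampling.** Non-overlapping 20-s windows aligned to the
   segment start (segments begin at bed transitions, not round clock
   times) are reduced to the median of their valid samples; a window with
   no valid sample is missing. The median of an even count is the mean of
   the two central values. A 20-sample window tolerates up to 9 one-sided
   outliers without leaving the range of the clean samples, which is what
   makes isolated outliers harmless.
4. **Gap interpolation.** Runs of 1–3 consecutive missing 20-s bins
   strictly between valid bins are filled linearly; longer runs and runs
   touching a segment edge stay missing. The gap unit is the 20-s bin, not
   the raw second: interpolation operates on the down-sampled series, the
   last stage of the chain.

The steps run non-iteratively (no re-scan after removals merge gaps); the
run structure is computed once from the error positions, which steps 1–2
never change. Cleaning is strictly per-segment: one segment's data can
never affect another's output. A final human visual pass is deliberately
replaced by a machine-readable audit log of every removal (step, position,
length, block mean, deviation) — reproducibility over eyeballs.

The 20-s sampling time is not arbitrary: `autocorrelation_sampling_time()`
computes the gap-aware sample autocorrelation of the valid 1 Hz signal
(mean-removed; products only over pairs with both samples valid) and
returns the smallest lag at which it falls below `acf_threshold` (default
1/e). For an AR(1) signal with per-second coefficient $\phi$ the
population answer is $-1/\ln\phi$; at $\phi = e^{-1/20}$ the decorrelation
time is 20 s, i.e. the 1 Hz stream oversamples the SpO2 dynamics by about
a factor 20. Degenerate inputs (constant series, zero variance) are
refused explicitly rather than returning a pseudo-lag.

## Features, weekly aggregation, classification

Features are computed on the cleaned 20-s series. Mean and SD (sample SD,
$n-1$) run over non-missing bins; interpolated bins count as data — they
are part of the cleaned series, and excluding them would bias coverage
against artifact-adjacent periods. CT90 uses strict inequality
(SpO2 *below* 90 ⇒ value < 90) and its denominator is the valid measured
time, not the full bed interval: CT90 is computed from measurements, and
under the 0.9 full-night coverage rule the two denominators nearly
coincide. Sleep metrics come from the actigraphy: TNST is the count of
in-bed sleep minutes, WASO the count of in-bed awake minutes strictly
after the first sleep minute, Seff = 100·TNST/time-in-bed; sleep-onset
latency + TNST + WASO equals time in bed exactly, which the tests assert.

Weekly averages are unweighted means over the patient's retained periods
(features are per-period quantities first, following the
compute-then-average convention), and weekly ranges are max − min. A
patient is a consistent desaturator when *every* night has CT90 > 30
(strict, "more than 30%"), a consistent nondesaturator when none does,
and an occasional desaturator otherwise; the category needs at least two
nights. The two-night flag compares the clinical two-night rule
(desaturation in ≥ 1 of the first two nights ⇒ desaturator) against the
week category; under that rule every occasional desaturator is discordant,
so the report additionally gives the fraction of occasional desaturators
whose first two nights were *concordant* (both on the same side of the
threshold) — the patients a two-night protocol would confidently
mislabel.

Statistics are formula-level: paired $t = \bar d/(s_d/\sqrt n)$ with
$n-1$ df, Pearson $r$ from centred cross-products with the $t$ transform
on $n-2$ df; both are validated against the base-R reference
implementations to $10^{-10}$ in the tests, which keeps the implementation
and its oracle separate. Two-sided p-values are always reported raw; no
multiple-testing correction is applied, and the report says so.

## The synthetic-data generator

The generator stands in for raw patient data, which cannot be shipped. It
emulates, per patient-week:

* a circadian baseline: daytime level `baseline_day_spo2`, nocturnal level
  lower by `nocturnal_drop` (defaults 94 and 2, putting nights near the
  clinically interesting 90% region), and a 0.8 pp evening dip after
  18:00 (`evening_dip`) so the afternoon–evening machinery has signal to
  find;
* within-period fluctuation as Gaussian AR(1) with stationary SD
  `intraperiod_sd` (default 1.5 pp) and $\phi = e^{-1/20}$, giving the
  ~20 s memory the down-sampling analysis assumes. The AR(1)/Gaussian form
  is a modelling choice — nothing in the domain fixes the distributional
  family — and is stated as such;
* transient desaturation events (half-sine dips, default 1/h, depth 6 pp,
  ~2 min), part of the *clean* signal, not artifact;
* clustered artifact episodes: 1 + Poisson(1.2) error runs of geometric
  mean length 10 s, separated by depressed inter-runs (≤ 50 samples,
  depression 10–30 pp) and flanked outside by depressed runs of 1–60
  samples. Episodes start preferentially during high-MET minutes
  (weights 1/2/8 for rest/LIPA/MVPA), reproducing the strong
  activity-dependence of motion artifacts; nights use a fifth of the
  daytime episode rate (`night_artifact_burst_rate`), matching the
  observation that nocturnal data are far cleaner than daytime data;
* isolated single-sample outliers (fraction `outlier_rate`);
* bed intervals jittered ±30 min around a 23:00 bed time, ~480 min in
  bed, with onset latency and brief awakenings so WASO is nonzero; and
  daytime wear as afternoon and evening blocks with the device off in
  between — the realistic wear pattern of a finger-clip device.

Ground truth carries per-sample labels (clean/artifact/outlier/error),
true bed intervals, and per-night true mean SpO2 and CT90. The per-night
truth is defined on the artifact-free signal passed through the same ideal
20-s median binning aligned to the true bed start. This choice is
deliberate: defining truth on raw seconds would mix a structural binning
difference (the tail fraction of bin medians is not the tail fraction of
seconds, a 1–3 pp effect near the threshold for a signal with ~20 s
memory) into every comparison; with bin-level truth, estimate-minus-truth
isolates exactly what the pipeline can influence — artifact handling. With
artifacts and outliers switched off, the pipeline recovers the truth
*exactly*, which the tests use as an alignment check.

What the generator does **not** emulate: photoplethysmogram waveforms
(SpO2 is generated at the derived-value level), exacerbation dynamics,
oximeter calibration bias (the ±2% device accuracy), missing actigraphy,
daylight-saving clock shifts, or naps with sleep scoring. Passing tests
therefore demonstrate correctness of the pipeline's logic under the
assumed signal structure, not clinical validity on real recordings.

The designed cohort (`generate_cohort()`) builds 5/5/10
desaturator/nondesaturator/occasional patients by night-baseline
construction: consistent desaturators around 85.5–88, consistent
nondesaturators around 92–94, occasional patients alternating between a
low (~88.5) and a high (~91.5) nightly baseline so their weekly mean sits
near 90 — the region where nightly CT90 genuinely straddles the 30%
threshold. Sixty percent of occasional patients get concordant first two
nights. All draws flow from one global seed, and identical seeds produce
byte-identical files.

## Numerical and degenerate-input choices

* All thresholds live in `oxiweek_config()`; the defaults are the
  method's standard operating points (19/20–100/6 pp/20 s/3 bins/1/e).
* Timestamps are wall-clock local times held in a fixed UTC
  representation; clock windows (13:00, 18:00) are wall-clock by
  definition, so no timezone arithmetic is wanted or performed.
* Ties in per-bin activity labelling (a 20-s bin straddling two minutes)
  go to the modal label, broken in the order rest, LIPA, MVPA, asleep.
* Empty segments, empty masks, zero-variance series, and fewer than two
  nights are refused with explicit messages, never silently coerced.
* Feature-table numbers are written with the shortest decimal that parses
  back to the identical double, making write→read→report loops
  bit-reproducible.

## Known limitations

* **The outer-flank leak.** The cleaning rules remove depressed blocks
  *between* error values. A depressed flank on the outer side of an
  artifact episode is contiguous with clean data, is therefore never
  removed by steps 1–2, and partially survives the bin median when it
  covers more than half a window; it also anchors the interpolation of
  the adjacent removed gap. The consequence is a small negative bias in
  recovered per-night mean SpO2 (a few tenths of a percentage point at
  realistic nocturnal artifact rates) that the pipeline cannot see from
  the data alone; CT90 recovery is much less sensitive because few
  corrupted bins cross the 90% threshold in either direction. The
  acceptance script quantifies both (`nights_mean_spo2_within_0p2_pct`,
  `nights_ct90_within_2_pct`). A workflow with a human in the loop would
  close this gap with a final visual inspection; this package deliberately
  trades that for a complete audit log, and the audit log is the right
  place to look when a night's mean matters to a few tenths of a point.
* CT90's denominator is measured time; on nights with coverage just above
  the retention floor the full-bed-interval reading could differ.
* The report's correlations are limited to the SD-vs-mean relations the
  pipeline itself computes; no patient characteristics are modelled.
* Problem sizes in the test-suite simulations (a 20-patient designed week
  for recovery and classification, 1000 randomized segments for the
  cleaning oracle, $10^5$ samples for the autocorrelation check) were
  chosen as the smallest sizes at which the checked quantities are
  statistically stable.
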