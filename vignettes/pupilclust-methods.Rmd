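---
title: "Clustering pupil dynamics under cognitive load: models and methods"
author: "pupilclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering pupil dynamics under cognitive load: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pupilclust)
```

## The analysis

`pupilclust` implements an unsupervised analysis of pupillometry recorded
during a color-matching task with escalating cognitive load: three blocks of
six difficulty levels, 17 trials per level (306 trials in all), with
deliberately false ("deceptive") correctness feedback in Block 2, levels 3-6.
Each participant is reduced to a 306-element vector of trial-averaged pupil
sizes; participants are partitioned by the *shape* of that trajectory, and the
resulting clusters are then contrasted on cardiac, electrodermal, respiratory,
oculomotor and behavioral metrics.

The pipeline is fixed and logged: trial averaging, per-participant z-scoring,
uniform-kernel smoothing, isolation-forest outlier screening, Euclidean
k-means with k = 2, label alignment, metric extraction, and normality-gated
two-group statistics.

## The synthetic cohort is the test substrate

Raw recordings are not required anywhere in the package: a generator
(`generate_cohort()`) draws a cohort with known ("ground-truth") archetype
labels, and every downstream stage is validated against that truth. The
generator's defaults define the study conditions and are not tuned per
analysis:

* **Cohort**: 70 participants, 33 of archetype 0 and 37 of archetype 1,
  matching the cluster sizes the analysis is designed to recover.
* **Pupil trajectories** (archetype shape, in z-shape units, scaled by
  0.6 mm around a ~4 mm baseline): archetype 0 starts each block elevated
  (+1.3) and declines within the block (slope −1.5); archetype 1 starts low
  (−0.8), rises with difficulty (+1.2), and adds a Gaussian peak (amplitude
  1.3, SD 8 trials) centered on the first deceptive cell (Block 2, Level 3).
* **Cardiac**: RR intervals are `mean_nn + A_LF sin(2π·0.1t) +
  A_HF sin(2π·0.25t) + jitter`, with the carriers at the centers of the
  standard LF and HF bands. Archetype 0: MeanNN 850 ms, jitter for an RMSSD
  target of 45 ms, HF-dominant modulation (25 vs 15 ms); archetype 1:
  750 ms, 30 ms, LF-leaning modulation (20 vs 10 ms). The ECG is rendered as
  Gaussian QRS bumps (SD 12 ms) at the beat times at 250 Hz plus white noise
  and slow baseline wander — enough morphology to exercise the filter and
  peak detector, deliberately not a full PQRST simulation.
* **Oculomotor**: Poisson saccade/fixation/blink events (archetype 1 denser:
  2.0/2.2/0.35 Hz vs 1.6/1.8/0.25 Hz) with lognormal amplitudes, velocities
  and durations; archetype 0 has longer fixations (260 vs 210 ms median).
* **Behavior**: gamma response times (shape 8) with mean 2000 ms (archetype
  0) or 2600 ms (archetype 1) at level 1, rising 240 ms per level; error
  probability rising with level and higher for archetype 0; self-esteem
  ratings `round(5.2 − 0.45·level + bias + N(0, 0.4))` clipped to 1..5 with
  bias −0.5 / +0.3.
* **EDA / respiration** are generated with *no* archetype difference (tonic
  drift plus Poisson SCR events; ~15 bpm sinusoidal breathing with period
  jitter), reflecting that these channels are expected to show null results;
  they exercise the metric extractors, not the contrasts.

The task is self-paced and no per-trial durations are published, so the
generator sets trial duration to RT + 1.8 s stimulus/feedback overhead. That
yields ~4.2-5 s trials, blocks of roughly 7.5 minutes, and per-level spans
comfortably above 60 s, which is the minimum we require for frequency-domain
HRV. Inter-block rest breaks are metadata only; the synthetic recording
timeline is contiguous.

**What passing tests do and do not show.** The generator produces clean,
stationary, well-separated data: Gaussian trial noise, no blink artifacts
inside trials, no drift in electrode contact, no ectopy beyond what the
artifact rule simulates, and archetypes that are linearly separable after
smoothing (the package requires the between-archetype centroid distance on
processed trajectories to exceed 4x the mean within-archetype
distance-to-centroid). Tests passing on this substrate demonstrate that the
*machinery* is correct — they do not establish that two clusters exist in any
particular real cohort, nor that real pupil data meet the separability the
generator guarantees.

## Pupil preprocessing

* **Normalization** subtracts each participant's mean pupil size over the
  entire test and divides by their SD, removing absolute pupil-size
  differences. The SD uses the population (n) denominator, which makes the
  transform exactly idempotent; this is configurable in principle but fixed
  here for reproducibility.
* **Missing trials**: linear interpolation over trial index when under 5% of
  a participant's trials are missing; otherwise the participant is excluded,
  with a message. Exclusions are never silent.
* **Smoothing** is convolution with a uniform kernel whose width equals the
  number of trials per level (17), so one smoothed point summarizes about
  one difficulty level. Output keeps the input length; edges use shrinking
  windows (the mean of available neighbors), since no padding convention is
  canonical. Smoothing before clustering is the default; a `smooth = FALSE`
  toggle exists because the choice is not fully settled.
* **Outlier screening** scores trajectories with an isolation forest
  (100 trees, subsample 256, seed-deterministic) and flags the
  `ceiling(contamination x n)` highest scores (default contamination 0.05).
  Flagged participants are *reported, not dropped*; dropping requires the
  explicit `drop_outliers` switch so exclusions stay auditable.

## Clustering

k-means with Euclidean distance on the processed vectors, k fixed at 2. We
run 25 restarts of Lloyd's algorithm (tolerance 1e-6 on the centroid shift,
max 300 iterations) and keep the lowest-inertia solution. Restarts alternate
two seeding schemes: k-means++ point seeding, and random-partition seeding
(centroids of a uniformly random assignment). The second scheme is there
because Lloyd's basin of attraction of the global optimum occasionally
contains no point-pair initialization at all on small instances; alternating
seedings restores exact agreement with exhaustive search on every tiny
instance we test (400 random cases with n <= 8). Inertia is asserted
non-increasing at every iteration, and an emptied cluster is reseeded at the
point farthest from its centroid.

Cluster labels are arbitrary, so `align_labels()` fixes the reporting
convention: cluster 0 is the cluster whose centroid has the larger mean over
the Block 1, Level 1 window (the "high initial arousal" phenotype). An exact
tie falls back to ordering by inertia contribution, with a warning.

`silhouette_by_k()` reports silhouette widths across candidate k but never
auto-selects; the two-cluster structure is a design commitment of the
analysis, not a model-selection outcome. Recovery on synthetic cohorts is
scored with the adjusted Rand index against the generator's truth labels.

## Autonomic signal processing

* **ECG**: zero-phase (forward-backward) fifth-order Butterworth high-pass at
  0.5 Hz, then a zero-phase 48-52 Hz band-stop against power-line
  interference. Zero-phase filtering is used throughout so R-peak latencies
  are not shifted. R-peaks are found from gradient steepness: the detector
  isolates 5-25 Hz QRS energy, thresholds the absolute first difference at
  median + 5·MAD (estimated over 10 s windows, interpolated between window
  centers), takes the signal's local maximum within each supra-threshold
  region, and enforces a 250 ms refractory period (ties resolved toward the
  larger amplitude). On rendered 300 s recordings with 20 dB SNR the
  detector's precision and recall are at least 0.99 against generator truth.
* **NN cleaning**: intervals deviating more than 20% from the running median
  of 11 are flagged as artifacts and excluded from all metrics; a segment
  with over half its intervals flagged is refused. This rule is a
  transparent, configurable detector chosen over opaque toolkit defaults.
* **Time domain**: MeanNN (mean), SDNN (sample SD, n−1), RMSSD (root mean
  square of successive differences across adjacent non-artifact pairs).
* **Frequency domain**: the NN tachogram is cubic-spline interpolated to a
  uniform 4 Hz grid, linearly detrended, and its Welch PSD (Hann windows,
  50% overlap, segments of up to 256 samples) integrated by the trapezoid
  rule over 0.04-0.15 Hz (LF) and 0.15-0.40 Hz (HF) — the conventional band
  edges, since none are stated in the source analyses. Powers are reported
  in ms²; published HF values in this paradigm have ambiguous units, so no
  absolute spectral target is claimed anywhere — only orderings and ratios.
  Frequency metrics require a 60 s span and are otherwise missing by rule.
* **EDA**: phasic component by zero-phase 0.05 Hz high-pass (the acquisition
  band's lower edge) on the mean-centered trace, with a 2 s guard band at
  the trace edges; SCR peaks must rise at least 0.05 µS from the preceding
  trough *and* stand above the phasic baseline (half threshold), the second
  clause rejecting filter-ringing recovery bumps.
* **Respiration**: cycles from zero crossings of the detrended trace;
  inspiration is trough-to-peak, expiration peak-to-trough; rate, mean
  amplitude, mean phase durations and the inspiration/expiration ratio.

Segment metrics assign an interval or event to a (block, level) window by
the time of its terminating peak (intervals) or onset (events); windows are
mapped to recording time through the trial table.

## Group statistics

Every comparison is gated by Shapiro-Wilk normality tests on both groups at
alpha 0.05. If both pass: two-sided Student's t with pooled variance
(Welch behind a flag), Cohen's d with pooled-SD denominator and a
normal-approximation CI (`var(d) = (n0+n1)/(n0·n1) + d²/(2(n0+n1−2))`), and
the point-biserial correlation with a Fisher-z CI. Otherwise (or when a
group is constant): two-sided Mann-Whitney U, rank-biserial correlation and
common-language effect size. The normative definition of the rank effects is
pairwise enumeration with ties counted half — `CLES = [#(x1>x0) +
0.5·#ties]/(n0·n1)`, `RBC = 2·CLES − 1` — and the midrank computation is
tested to agree with that enumeration exactly. Effect signs are always
"cluster 1 relative to cluster 0", and every output row carries that note,
because published sign conventions in this literature are inconsistent.

Headline p-values are raw; Benjamini-Hochberg adjusted values are appended
per metric as a `p_bh` column but never substituted, making the multiplicity
cost visible without silently diverging from the per-level reporting style
this analysis mirrors. Binary variables (e.g. smoking) use Pearson's
chi-square without continuity correction (Yates by flag); a zero margin is
an error rather than a silent NaN. The gated machinery's type-I error is
calibrated by simulation (10,000 null replicates at n = 33 vs 37) to lie in
[0.045, 0.055].

Block-level comparisons average each participant's per-level values within
the block first, then compare participants — a participant-level summary,
not a pooled-trial one. `peak_reactions()` reports, per cluster and metric,
the (block, level) cell of the extreme cluster mean and whether it falls on
a deceptive cell; ties return the earliest segment, flagged.

## Numerical choices and degenerate inputs

* Trial indices are 0-based half-open internally; blocks and levels are
  reported 1-based. Windows are validated to partition the trial range.
* Seeds: the generator consumes a per-participant substream derived from the
  master seed, with pupil and behavioral draws preceding the continuous
  channels — so generating fewer channels never perturbs the ones kept, and
  a cohort is a pure function of (seed, parameters). Clustering and
  screening take their own seeds (offset from the master seed in the
  pipeline config); all seeds are recorded in the run manifest.
* Zero pupil SD (constant trajectory) is an error naming the participant;
  zero pooled SD makes d undefined (error); fewer than 3 clean NN intervals
  or fewer than 2 respiration cycles yield missing metrics with a message.
* The k-means monotonicity assertion (`stopifnot`) is active in production,
  not only in tests: a violation would indicate numerical corruption worth
  halting for.

## Problem sizes used by the test suite

The suite validates clustering recovery on 20 cohorts of 70 participants
(pupil channel), the k-means oracle on 200 random instances with n <= 8
against exhaustive search, the HRV time-domain oracle on 1,000 random
series, rank-effect equivalence on 1,000 random instances, type-I
calibration on 10,000 null replicates, R-peak recovery on a 300 s recording,
and the full multimodal direction pattern on one default 70-participant
cohort. These sizes were chosen to make Monte-Carlo bounds tight enough to
be meaningful while keeping the default test run comfortably reproducible on
a laptop.

## Known limitations

* The generator's archetypes are caricatures: real pupil trajectories carry
  luminance responses, blink artifacts and slow arousal drifts that the
  trial-mean abstraction removes by construction.
* The ECG model has no P/T waves, so the peak detector is not exercised
  against T-wave over-sensing; the artifact rule is likewise exercised only
  against the ectopy-like deviations it defines.
* Spectral HRV on ~60-80 s windows is at the short end of what the LF band
  supports; LF estimates on single levels are noisy and are interpreted only
  through orderings, never absolute values.
* With k fixed at 2, cohorts with more (or no) latent structure will still
  be split in two; the silhouette report is the only guard.
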