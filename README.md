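# pupilclust

Unsupervised analysis of pupil-size dynamics under escalating cognitive load
with deceptive feedback, for psychophysiologists who want to ask: *do
participants fall into distinct autonomic phenotypes, visible in the shape of
their pupil trajectory alone — and do those groups differ in heart-rate
variability, eye movements and task behavior?*

The task structure is three blocks × six difficulty levels × 17 trials
(306 trials per participant), with deliberately false correctness feedback in
Block 2, levels 3–6. Each participant is reduced to the vector
**x** ∈ ℝ³⁰⁶ of trial-averaged pupil sizes, z-scored per participant
(population SD), smoothed by convolution with a uniform kernel of width 17
(one difficulty level), screened with an isolation forest, and partitioned by
Euclidean k-means (k = 2, Lloyd's algorithm, best of 25 restarts by inertia).
Labels are aligned so **cluster 0** is the cluster whose centroid is higher
over the Block 1 Level 1 window (the "high initial arousal" phenotype).
Clusters are then contrasted per level and per block on:

* **HRV** — MeanNN, SDNN (n−1), RMSSD; LF (0.04–0.15 Hz), HF (0.15–0.40 Hz)
  and LF/HF from a Welch PSD of the 4 Hz-resampled NN tachogram, after
  Butterworth filtering (0.5 Hz high-pass + 50 Hz notch, zero-phase),
  gradient-steepness R-peak detection and running-median artifact cleaning;
* **EDA / respiration** — SCR peak count and mean amplitude; breathing rate,
  amplitude, inspiration/expiration phase durations and their ratio;
* **oculomotor and behavioral metrics** — saccade / fixation / blink counts
  and durations, response times, mistakes, self-esteem ratings.

Comparisons are gated by Shapiro–Wilk normality: Student's t (pooled
variance) with Cohen's d and point-biserial r when both groups pass, else
Mann–Whitney U with the rank-biserial correlation (RBC = 2·CLES − 1) and
common-language effect size, defined by pairwise enumeration with ties
counted half. Effect signs are always "cluster 1 relative to cluster 0".

A synthetic multimodal cohort generator with known archetype labels
(`generate_cohort()`) stands in for raw recordings, so the whole pipeline is
testable end to end; see the methods vignette
(`vignettes/pupilclust-methods.Rmd`) for the generative model and its
deliberate simplifications.

## Worked example

```r
library(pupilclust)

sched <- build_schedule()
sched
#> <task_schedule> 3 blocks x 6 levels x 17 trials = 306 trials (68 deceptive)

cohort <- generate_cohort(sched, seed = 1, channels = c("pupil", "ecg", "eye"))
cohort
#> <cohort> 70 participants (33/37 per archetype), 306 trials each,
#>          channels: pupil, ecg, eye

prep <- prepare_trajectories(cohort$trials, sched)
fit  <- align_labels(kmeans_fit(prep$trajectories, k = 2, seed = 1001),
                     sched, prep$trajectories)
glance(fit)
#> # A tibble: 1 × 7
#>       k     n inertia n_init n_iter  seed aligned
#>   <int> <int>   <dbl>  <int>  <int> <dbl> <lgl>
#> 1     2    70    318.     25      2  1001 TRUE

merged <- merge(tidy(fit), cohort$truth)
adjusted_rand(merged$cluster, merged$archetype)
#> [1] 1
```

The recovered partition matches the generator's archetypes exactly
(ARI = 1): aligned cluster 0 holds the 33 participants whose pupil
trajectories start each block elevated and decline, cluster 1 the 37 whose
trajectories rise with difficulty and peak at the onset of deceptive
feedback. Contrasting the clusters block-wise:

```r
metrics <- cohort_metrics(cohort, channels = c("hrv", "eye", "behavior"))
blocks  <- report_blocks(metrics, fit)
subset(blocks, metric %in% c("mean_nn_ms", "rmssd_ms"),
       c(metric, block, mean0, mean1, test, p_value))
#>       metric block  mean0  mean1         test    p_value
#> 1 mean_nn_ms     1 849.73 749.81    student_t 2.153e-115
#> 2 mean_nn_ms     2 849.62 749.64 mann_whitney  6.834e-13
#> 3 mean_nn_ms     3 849.90 749.94    student_t 1.132e-113
#> 4   rmssd_ms     1  49.96  32.09    student_t  2.642e-59
#> 5   rmssd_ms     2  50.18  32.33    student_t  8.793e-58
#> 6   rmssd_ms     3  51.06  31.96    student_t  2.963e-59
```

Cluster 0 shows the higher vagally-mediated HRV (longer NN intervals, larger
RMSSD) in every block — the mean NN interval recovered for each cluster
(≈850 ms vs ≈750 ms) is the value its archetype was generated with, i.e. the
full chain ECG rendering → filtering → R-peak detection → artifact cleaning
→ segmentation is faithful. `report_levels()` gives the same table per
(block, level); `peak_reactions()` locates each cluster's extreme segments
and flags whether they fall on deceptive cells; `autoplot(fit, sched)` draws
the centroid trajectories; `run_pipeline(default_config())` executes the
whole chain into a run directory with a manifest, and `validate_run()`
scores it against the generator's truth.

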