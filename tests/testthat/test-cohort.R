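arches <- default_archetypes()

test_that("pupil shapes encode the two phenotypes", {
  a0 <- pupil_trace(arches[[1]], default_sched, noise_sd = 0)
  a1 <- pupil_trace(arches[[2]], default_sched, noise_sd = 0)
  expect_length(a0, 306L)
  expect_length(a1, 306L)
  # archetype 0: block-start elevation then within-block decline
  expect_gt(a0[1], a0[102])
  expect_gt(a0[103], a0[204])
  # archetype 1: low start rising with difficulty
  expect_lt(a1[1], a1[102])
  # archetype 1: block-2 maximum falls inside the level-3 (deceptive) window
  block2 <- 103:204
  peak_trial <- block2[which.max(a1[block2])] - 1L  # 0-based
  win <- level_windows(default_sched)
  w23 <- win[win$block == 2 & win$level == 3, ]
  expect_gte(peak_trial, w23$first_trial)
  expect_lt(peak_trial, w23$last_trial)
})

test_that("cohort generation is deterministic and channel-stable", {
  c1 <- small_cohort(seed = 11)
  c2 <- small_cohort(seed = 11)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$questionnaires, c2$questionnaires)
  # dropping trailing channels must not perturb the kept channels
  c3 <- generate_cohort(default_sched, n_per_archetype = c(6L, 6L), seed = 11,
                        channels = "pupil")
  expect_identical(c1$trials$pupil_mm, c3$trials$pupil_mm)
  c4 <- small_cohort(seed = 12)
  expect_false(identical(c1$trials$pupil_mm, c4$trials$pupil_mm))
})

test_that("default cohort has the study's size and recorded truth", {
  coh <- pupil_cohort(seed = 1)
  expect_equal(nrow(coh$truth), 70L)
  expect_equal(unname(table(coh$truth$archetype)), c(33L, 37L), ignore_attr = TRUE)
  expect_equal(nrow(coh$trials), 70L * 306L)
  expect_error(generate_cohort(default_sched, n_per_archetype = c(1L, 5L)),
               ">= 2")
})

test_that("zero noise collapses within-archetype pupil variation", {
  coh <- generate_cohort(default_sched, n_per_archetype = c(3L, 3L),
                         noise_config = default_noise(0), seed = 5,
                         channels = "pupil")
  wide <- tidyr::pivot_wider(coh$trials[c("participant", "trial", "pupil_mm")],
                             names_from = "participant", values_from = "pupil_mm")
  a0 <- coh$truth$participant[coh$truth$archetype == 0]
  expect_equal(wide[[a0[1]]], wide[[a0[2]]])
  expect_equal(wide[[a0[1]]], wide[[a0[3]]])
})

test_that("archetypes are separable on processed trajectories", {
  coh <- pupil_cohort(seed = 3)
  prep <- prepare_trajectories(coh$trials, default_sched)
  v <- prep$trajectories$values
  a <- coh$truth$archetype[match(rownames(v), coh$truth$participant)]
  c0 <- colMeans(v[a == 0, ])
  c1 <- colMeans(v[a == 1, ])
  between <- sqrt(sum((c0 - c1)^2))
  within <- mean(c(
    apply(v[a == 0, ], 1, function(r) sqrt(sum((r - c0)^2))),
    apply(v[a == 1, ], 1, function(r) sqrt(sum((r - c1)^2)))
  ))
  expect_gt(between / within, 4)
})

test_that("rr_series follows its generative contract", {
  a <- arches[[1]]
  # no jitter, no modulation: all intervals equal mean_nn
  a0 <- a
  a0$lf_mod_amp <- 0
  a0$hf_mod_amp <- 0
  rr <- rr_series(a0, 120, jitter_sd = 0)
  expect_true(all(rr$rr_ms == a0$mean_nn_ms))
  # interval count ~ duration / mean
  a850 <- a0
  a850$mean_nn_ms <- 850
  rr <- rr_series(a850, 300, jitter_sd = 0)
  expect_lte(abs(nrow(rr) - 352), 1)
  # all intervals above the physiological floor
  set.seed(2)
  rrj <- rr_series(a, 120)
  expect_true(all(rrj$rr_ms > 300))
  expect_error(rr_series(a, 30), ">= 60")
  bad <- a
  bad$mean_nn_ms <- 320
  expect_error(archetype_spec(label = 0, block_start = 0, within_block_slope = 0,
                              deception_peak = 0, mean_nn_ms = 200,
                              rmssd_target_ms = 30, lf_mod_amp = 0, hf_mod_amp = 0,
                              saccade_rate_hz = 1, fixation_rate_hz = 1,
                              blink_rate_hz = 1, rt_mean_ms = 1000,
                              error_prob_by_level = rep(0, 6)),
               "300")
})

test_that("rendered ECG places QRS templates at the ground-truth beats", {
  ecg <- render_ecg(c(1000, 1000), fs = 250, qrs_amp = 1)
  # 3 beats, no noise: exactly 3 local maxima above half amplitude
  s <- ecg$signal
  locmax <- which(diff(sign(diff(s))) == -2) + 1L
  expect_equal(sum(s[locmax] > 0.5), 3L)
  # argmax within +/- 1 sample of each true R time
  for (idx in ecg$peak_idx) {
    lo <- max(1, idx - 50)
    hi <- min(length(s), idx + 50)
    expect_lte(abs((lo + which.max(s[lo:hi]) - 1L) - idx), 1L)
  }
  expect_error(render_ecg(c(1000, 1000), fs = 50), ">= 100")
})

test_that("behavioral generator matches its distributions", {
  set.seed(9)
  a <- arches[[1]]
  beh <- eye_and_behavior(a, default_sched)
  expect_true(all(beh$trials$self_esteem %in% 1:5))
  expect_equal(nrow(beh$trials), 306L)
  expect_true(!is.unsorted(beh$events$onset_s))
  # Poisson counts within 4 sigma of rate x span
  spans <- window_spans(beh$trials, default_sched)
  total_span <- sum(spans$t_end - spans$t_start)
  n_sac <- sum(beh$events$type == "saccade")
  mu <- a$saccade_rate_hz * total_span
  expect_lt(abs(n_sac - mu), 4 * sqrt(mu))
  # error_prob 0: no mistakes at all
  a_perfect <- a
  a_perfect$error_prob_by_level <- rep(0, 6)
  beh0 <- eye_and_behavior(a_perfect, default_sched, events = FALSE)
  expect_true(all(beh0$trials$correct))
})

test_that("downstream HRV ranks archetypes as configured", {
  # noise-free series: MeanNN recovers the configured value exactly
  specs <- default_archetypes()
  for (s in specs) {
    s0 <- s
    s0$lf_mod_amp <- 0
    s0$hf_mod_amp <- 0
    rr <- rr_series(s0, 120, jitter_sd = 0)
    tm <- hrv_time(nn_from_intervals(rr$rr_ms))
    expect_equal(tm$mean_nn_ms, s$mean_nn_ms, tolerance = 1e-12)
    expect_equal(tm$sdnn_ms, 0)
    expect_equal(tm$rmssd_ms, 0)
  }
  # with full modulation + jitter: archetype 0 above archetype 1
  set.seed(21)
  t0 <- hrv_time(nn_from_intervals(rr_series(specs[[1]], 300)$rr_ms))
  t1 <- hrv_time(nn_from_intervals(rr_series(specs[[2]], 300)$rr_ms))
  expect_gt(t0$mean_nn_ms, t1$mean_nn_ms)
  expect_gt(t0$rmssd_ms, t1$rmssd_ms)
})

test_that("cohort writes a tidy directory with truth kept separate", {
  dir <- withr::local_tempdir()
  coh <- small_cohort(seed = 4)
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(
    dir, c("trials.csv", "events.csv", "questionnaires.csv", "truth.csv",
           "metadata.yaml")
  ))))
  back <- read_cohort(dir)
  expect_equal(nrow(back$trials), nrow(coh$trials))
  expect_true(all(is.na(back$truth$archetype)))
  expect_equal(total_trials(back$schedule), 306L)
})
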