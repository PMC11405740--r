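test_that("ECG filtering removes DC and line noise but keeps the QRS band", {
  fs <- 250
  t <- seq(0, 60, by = 1 / fs)
  # DC offset goes to ~0 once clear of the start-up transient
  out <- filter_ecg(rep(3, length(t)), fs)
  mid <- 5000:10000
  expect_lt(max(abs(out[mid])), 1e-6)
  # 50 Hz line noise attenuated below 5% RMS
  line <- sin(2 * pi * 50 * t)
  out <- filter_ecg(line, fs)
  expect_lt(sqrt(mean(out[mid]^2)), 0.05 * sqrt(mean(line^2)))
  # 10 Hz passband preserved within 5%
  tone <- sin(2 * pi * 10 * t)
  out <- filter_ecg(tone, fs)
  expect_equal(sqrt(mean(out[mid]^2)), sqrt(mean(tone[mid]^2)),
               tolerance = 0.05)
  expect_error(filter_ecg(mid, 80), "notch")
})

test_that("R-peak detection recovers clean and noisy beats", {
  # flat signal: no peaks, with a warning
  expect_warning(nn <- detect_r_peaks(numeric(5000), 250), "no R-peaks")
  expect_length(nn$nn_ms, 0L)
  # two template beats 1 s apart -> NN = 1000 ms
  ecg <- render_ecg(1000, fs = 250, qrs_amp = 1)
  nn <- detect_r_peaks(ecg$signal, 250)
  expect_length(nn$nn_ms, 1L)
  expect_equal(nn$nn_ms, 1000, tolerance = 8)  # within 2 samples
  # noisy 300 s recording: precision and recall >= 0.99 vs generator truth
  set.seed(14)
  arch <- default_archetypes()[[1]]
  rr <- rr_series(arch, 300)
  ecg <- render_ecg(rr, fs = 250, qrs_amp = 1, baseline_noise_sd = 0.1,
                    baseline_wander_amp = 0.05)
  det <- detect_r_peaks(filter_ecg(ecg$signal, 250), 250)
  truth_t <- (ecg$peak_idx - 1) / 250
  hits <- outer(det$peak_times_s, truth_t, function(a, b) abs(a - b) < 0.05)
  recall <- sum(apply(hits, 2, any)) / length(truth_t)
  precision <- sum(apply(hits, 1, any)) / length(det$peak_times_s)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
})

test_that("artifact cleaning flags ectopic-like intervals", {
  clean <- nn_from_intervals(rep(c(800, 810, 790), 10))
  out <- clean_nn(clean)
  expect_false(any(out$artifact))
  # one 2000 ms interval amid ~800 ms: flagged
  v <- rep(800, 20)
  v[10] <- 2000
  out <- clean_nn(nn_from_intervals(v))
  expect_true(out$artifact[10])
  expect_equal(sum(out$artifact), 1L)
  # infinite tolerance: identity
  out <- clean_nn(nn_from_intervals(v), rel_tol = Inf)
  expect_false(any(out$artifact))
  # mostly-corrupt segments are refused
  expect_error(clean_nn(nn_from_intervals(rep(c(400, 1200), 10))), "unusable")
  expect_error(clean_nn(nn_from_intervals(c(800, 810))), ">= 3")
})

test_that("time-domain metrics match hand computation and a brute-force oracle", {
  tm <- hrv_time(nn_from_intervals(c(800, 810, 790, 805)))
  expect_equal(tm$mean_nn_ms, 801.25)
  expect_equal(tm$sdnn_ms, 8.539, tolerance = 1e-3)
  expect_equal(tm$rmssd_ms, 15.546, tolerance = 1e-3)
  # constant series: zero dispersion
  tm <- hrv_time(nn_from_intervals(rep(750, 10)))
  expect_equal(tm$sdnn_ms, 0)
  expect_equal(tm$rmssd_ms, 0)
  # shift invariance of SDNN and RMSSD
  set.seed(10)
  v <- stats::rnorm(50, 800, 30)
  t1 <- hrv_time(nn_from_intervals(v))
  t2 <- hrv_time(nn_from_intervals(v + 100))
  expect_equal(t1$sdnn_ms, t2$sdnn_ms, tolerance = 1e-9)
  expect_equal(t1$rmssd_ms, t2$rmssd_ms, tolerance = 1e-9)
  # random series vs independent one-line recomputation, exact
  for (i in 1:200) {
    v <- stats::runif(sample(3:50, 1), 500, 1200)
    tm <- hrv_time(nn_from_intervals(v))
    expect_identical(tm$mean_nn_ms, mean(v))
    expect_identical(tm$sdnn_ms, stats::sd(v))
    expect_identical(tm$rmssd_ms, sqrt(mean(diff(v)^2)))
  }
})

test_that("band powers reflect the modulation frequency of the tachogram", {
  arch <- default_archetypes()[[1]]
  hf_only <- arch
  hf_only$lf_mod_amp <- 0
  hf_only$hf_mod_amp <- 25
  rr <- rr_series(hf_only, 300, jitter_sd = 0)
  fr <- hrv_freq(nn_from_intervals(rr$rr_ms))
  expect_gt(fr$hf_power, 10 * fr$lf_power)
  lf_only <- arch
  lf_only$lf_mod_amp <- 25
  lf_only$hf_mod_amp <- 0
  rr <- rr_series(lf_only, 300, jitter_sd = 0)
  fr <- hrv_freq(nn_from_intervals(rr$rr_ms))
  expect_gt(fr$lf_hf_ratio, 1)
  # constant RR: both band powers negligible vs a modulated reference
  none <- arch
  none$lf_mod_amp <- 0
  none$hf_mod_amp <- 0
  rr <- rr_series(none, 300, jitter_sd = 0)
  fr0 <- hrv_freq(nn_from_intervals(rr$rr_ms))
  expect_lt(fr0$lf_power + fr0$hf_power, 1e-8 * (fr$lf_power + fr$hf_power))
})

test_that("total Welch power bounds the band powers", {
  set.seed(33)
  x <- stats::rnorm(1024)
  psd <- welch_psd(x, fs = 4)
  total <- pracma::trapz(psd$freq, psd$psd)
  lf <- psd[psd$freq >= 0.04 & psd$freq <= 0.15, ]
  hf <- psd[psd$freq >= 0.15 & psd$freq <= 0.40, ]
  expect_gte(total,
             pracma::trapz(lf$freq, lf$psd) + pracma::trapz(hf$freq, hf$psd))
})

test_that("segment metrics honour window membership and the span rule", {
  arch <- default_archetypes()[[1]]
  arch$lf_mod_amp <- 0
  arch$hf_mod_amp <- 0
  rr <- rr_series(arch, 600, jitter_sd = 0)
  nn <- nn_from_intervals(rr$rr_ms)
  spans <- tibble::tibble(
    block = 1L, level = 1:3, deceptive = FALSE,
    t_start = c(0, 90, 180), t_end = c(90, 180, 230)
  )
  out <- segment_hrv(nn, spans)
  # stationary series: equal MeanNN across segments
  expect_equal(out$mean_nn_ms, rep(arch$mean_nn_ms, 3), tolerance = 1e-9)
  # third span (50 s) too short for spectral metrics, time metrics present
  expect_true(is.na(out$lf_power[3]))
  expect_false(is.na(out$mean_nn_ms[3]))
  expect_false(anyNA(out$lf_power[1:2]))
  # empty window: missing row values
  empty <- segment_hrv(nn, tibble::tibble(block = 9L, level = 9L,
                                          deceptive = FALSE,
                                          t_start = 3000, t_end = 3100))
  expect_true(is.na(empty$mean_nn_ms))
})
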