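#' NN (normal-to-normal) interval series
#'
#' Successive R-peak times and the intervals between them, with an artifact
#' mask maintained by [clean_nn()]. Interval `i` runs from peak `i` to peak
#' `i + 1`; its "time" is the time of its terminating peak.
#'
#' @param peak_times_s Strictly increasing R-peak times in seconds.
#' @param artifact Optional logical artifact mask (length = peaks - 1).
#' @return An object of class `nn_series`.
#' @export
nn_series <- function(peak_times_s, artifact = NULL) {
  peak_times_s <- as.numeric(peak_times_s)
  if (is.unsorted(peak_times_s, strictly = TRUE)) {
    rlang::abort("peak times must be strictly increasing")
  }
  nn_ms <- diff(peak_times_s) * 1000
  if (is.null(artifact)) artifact <- rep(FALSE, length(nn_ms))
  stopifnot(length(artifact) == length(nn_ms))
  structure(
    list(peak_times_s = peak_times_s, nn_ms = nn_ms, artifact = artifact),
    class = "nn_series"
  )
}

#' @rdname nn_series
#' @param nn_ms Interval lengths in ms; peak times are their cumulative sum
#'   (first peak at 0).
#' @export
nn_from_intervals <- function(nn_ms) {
  out <- nn_series(c(0, cumsum(nn_ms) / 1000))
  out$nn_ms <- as.numeric(nn_ms)  # keep intervals exact (no time round-trip)
  out
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d intervals (%d flagged), span %.1f s\n",
              length(x$nn_ms), sum(x$artifact), diff(range(x$peak_times_s))))
  invisible(x)
}

#' Preprocess a raw ECG waveform
#'
#' Zero-phase (forward-backward) fifth-order Butterworth high-pass at
#' 0.5 Hz to remove baseline drift, followed by a zero-phase 50 Hz notch
#' (48-52 Hz band-stop) against power-line interference. Zero-phase
#' filtering avoids shifting R-peak latencies.
#'
#' @param raw Numeric waveform.
#' @param fs Sampling rate in Hz; must exceed twice the 50 Hz notch
#'   frequency.
#' @return Filtered waveform, same length.
#' @export
filter_ecg <- function(raw, fs) {
  if (fs <= 100) rlang::abort("fs must exceed twice the 50 Hz notch frequency")
  hp <- signal::butter(5, 0.5 / (fs / 2), type = "high")
  out <- signal::filtfilt(hp, raw)
  notch <- signal::butter(2, c(48, 52) / (fs / 2), type = "stop")
  signal::filtfilt(notch, out)
}

#' Detect R-peaks by gradient steepness
#'
#' Candidate QRS regions are samples where the absolute first difference of
#' the (filtered) ECG exceeds an adaptive threshold — median + `c_mad` x MAD
#' of the gradient magnitude, computed over sliding windows of
#' `window_s` seconds. Each candidate region contributes the local maximum
#' of the signal as its R-peak; peaks closer than the 250 ms refractory
#' period are resolved in favor of the larger amplitude.
#'
#' @param ecg Filtered ECG waveform.
#' @param fs Sampling rate (Hz).
#' @param c_mad MAD multiplier of the adaptive threshold.
#' @param window_s Threshold estimation window (s).
#' @param refractory_s Minimum peak-to-peak separation (s).
#' @return An `nn_series` (empty, with a warning, if nothing is found).
#' @export
detect_r_peaks <- function(ecg, fs, c_mad = 5, window_s = 10,
                           refractory_s = 0.25) {
  n <- length(ecg)
  # isolate QRS energy (5-25 Hz) before differentiating, so the gradient
  # of the narrow R upstroke stands clear of the broadband noise floor
  bp <- signal::butter(3, c(5, 25) / (fs / 2), type = "pass")
  qrs <- signal::filtfilt(bp, ecg)
  g <- abs(c(0, diff(qrs)))
  # adaptive threshold per window, linearly interpolated between window centers
  wlen <- max(round(window_s * fs), 32L)
  starts <- seq(1L, n, by = wlen)
  thr_pts <- vapply(starts, function(s) {
    seg <- g[s:min(s + wlen - 1L, n)]
    stats::median(seg) + c_mad * stats::mad(seg)
  }, numeric(1))
  centers <- pmin(starts + wlen / 2, n)
  thr <- if (length(starts) == 1L) rep(thr_pts, n) else
    stats::approx(centers, thr_pts, xout = seq_len(n), rule = 2)$y
  cand <- which(g > thr)
  if (length(cand) == 0L) {
    rlang::warn("no R-peaks found")
    return(nn_series(numeric(0)))
  }
  # group candidates into regions separated by > 50 ms
  gap <- as.integer(round(0.05 * fs))
  region_id <- cumsum(c(1L, diff(cand) > gap))
  pad <- as.integer(round(0.03 * fs))
  peaks <- vapply(split(cand, region_id), function(idx) {
    lo <- max(1L, min(idx) - pad)
    hi <- min(n, max(idx) + pad)
    as.integer(lo + which.max(ecg[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refractory resolution: keep the larger of any pair closer than 250 ms
  keep <- rep(TRUE, length(peaks))
  last <- 1L
  for (i in seq_along(peaks)[-1]) {
    if ((peaks[i] - peaks[last]) / fs < refractory_s) {
      if (ecg[peaks[i]] > ecg[peaks[last]]) {
        keep[last] <- FALSE
        last <- i
      } else {
        keep[i] <- FALSE
      }
    } else {
      last <- i
    }
  }
  peaks <- peaks[keep]
  if (length(peaks) < 2L) {
    if (length(peaks) == 0L) rlang::warn("no R-peaks found")
    return(nn_series((peaks - 1L) / fs))
  }
  nn_series((peaks - 1L) / fs)
}

#' Flag artifactual NN intervals
#'
#' Intervals deviating by more than `rel_tol` (relative) from the running
#' median of 11 neighboring intervals are flagged as artifacts and excluded
#' from all downstream metrics. This is a transparent, configurable rule
#' standing in for toolkit-specific artifact detectors.
#'
#' @param nn An `nn_series` with >= 3 intervals.
#' @param rel_tol Relative deviation tolerance (default 0.2).
#' @return The `nn_series` with an updated artifact mask.
#' @export
clean_nn <- function(nn, rel_tol = 0.2) {
  stopifnot(inherits(nn, "nn_series"))
  v <- nn$nn_ms
  if (length(v) < 3L) rlang::abort("clean_nn needs >= 3 intervals")
  if (!is.finite(rel_tol)) {
    nn$artifact <- rep(FALSE, length(v))
    return(nn)
  }
  k <- min(11L, length(v) - (1 - length(v) %% 2))  # largest odd <= min(11, n)
  ref <- stats::runmed(v, k)
  flag <- abs(v - ref) > rel_tol * ref
  if (mean(flag) > 0.5) {
    rlang::abort(sprintf("unusable segment: %.0f%% of intervals flagged as artifacts",
                         100 * mean(flag)))
  }
  nn$artifact <- flag
  nn
}

#' Time-domain HRV metrics
#'
#' MeanNN (arithmetic mean of NN intervals), SDNN (sample SD, n-1
#' denominator) and RMSSD (root mean square of successive differences,
#' computed only across pairs of adjacent non-artifact intervals).
#'
#' @param nn An `nn_series`; artifact-flagged intervals are excluded.
#' @return One-row tibble with `mean_nn_ms`, `sdnn_ms`, `rmssd_ms`, and
#'   `n_nn` (intervals used). Metrics are `NA` (with a message) when fewer
#'   than 3 clean intervals are available.
#' @export
hrv_time <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  v <- nn$nn_ms[!nn$artifact]
  if (length(v) < 3L) {
    message("hrv_time: fewer than 3 clean intervals; metrics missing")
    return(tibble::tibble(mean_nn_ms = NA_real_, sdnn_ms = NA_real_,
                          rmssd_ms = NA_real_, n_nn = length(v)))
  }
  ok <- !nn$artifact
  adj <- ok[-length(ok)] & ok[-1]
  d <- diff(nn$nn_ms)[adj]
  tibble::tibble(
    mean_nn_ms = mean(v),
    sdnn_ms = stats::sd(v),
    rmssd_ms = if (length(d) >= 2) sqrt(mean(d^2)) else NA_real_,
    n_nn = length(v)
  )
}

#' Welch power spectral density
#'
#' Segmented averaged periodogram: Hann-windowed segments with 50% overlap,
#' one-sided density scaling (power / Hz).
#'
#' @param x Uniformly sampled series.
#' @param fs Sampling rate (Hz).
#' @param nseg Segment length (default `min(256, length(x))`).
#' @return Tibble with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nseg = min(256L, length(x))) {
  n <- length(x)
  nseg <- min(nseg, n)
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  scale <- fs * sum(w^2)
  acc <- numeric(floor(nseg / 2) + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 / scale
    half <- p[seq_len(floor(nseg / 2) + 1L)]
    # one-sided: double everything except DC (and Nyquist when nseg even)
    mult <- rep(2, length(half))
    mult[1] <- 1
    if (nseg %% 2 == 0) mult[length(half)] <- 1
    acc <- acc + half * mult
  }
  tibble::tibble(
    freq = seq(0, floor(nseg / 2)) * fs / nseg,
    psd = acc / length(starts)
  )
}

band_power <- function(psd, band) {
  idx <- psd$freq >= band[1] & psd$freq <= band[2]
  if (sum(idx) < 2) return(0)
  pracma::trapz(psd$freq[idx], psd$psd[idx])
}

#' Frequency-domain HRV metrics
#'
#' The NN tachogram is interpolated to a uniform 4 Hz grid (cubic spline),
#' linearly detrended, and its Welch PSD integrated (trapezoid rule) over
#' the LF and HF bands. Band edges default to the conventional 0.04-0.15 Hz
#' (LF) and 0.15-0.40 Hz (HF); powers are in ms^2.
#'
#' @param nn An `nn_series` spanning at least `min_span_s` seconds of clean
#'   intervals.
#' @param lf_band,hf_band Band edges in Hz.
#' @param resample_fs Tachogram resampling rate (Hz).
#' @param min_span_s Minimum span; shorter segments yield missing metrics.
#' @return One-row tibble: `lf_power`, `hf_power`, `lf_hf_ratio`.
#' @export
hrv_freq <- function(nn, lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40),
                     resample_fs = 4, min_span_s = 60) {
  stopifnot(inherits(nn, "nn_series"))
  t <- nn$peak_times_s[-1][!nn$artifact]
  v <- nn$nn_ms[!nn$artifact]
  if (length(v) < 4L || diff(range(t)) < min_span_s) {
    message("hrv_freq: segment too short for spectral metrics")
    return(tibble::tibble(lf_power = NA_real_, hf_power = NA_real_,
                          lf_hf_ratio = NA_real_))
  }
  grid <- seq(min(t), max(t), by = 1 / resample_fs)
  tach <- stats::spline(t, v, xout = grid)$y
  fit <- stats::lm.fit(cbind(1, grid), tach)
  tach <- fit$residuals
  psd <- welch_psd(tach, fs = resample_fs)
  lf <- band_power(psd, lf_band)
  hf <- band_power(psd, hf_band)
  tibble::tibble(
    lf_power = lf, hf_power = hf,
    lf_hf_ratio = if (hf > 0) lf / hf else NA_real_
  )
}

#' Segment-wise HRV metrics
#'
#' Computes time- and frequency-domain HRV for every time span in `spans`
#' (typically the per-level windows of the task, from [window_spans()]).
#' An interval belongs to a span when its terminating peak falls inside
#' `[t_start, t_end)`. Spans shorter than `min_span_s` report time-domain
#' metrics only.
#'
#' @param nn An `nn_series` for the whole recording (artifacts flagged).
#' @param spans Tibble with `t_start`, `t_end` and any id columns (`block`,
#'   `level`, ...), which are carried through.
#' @param min_span_s Minimum span for frequency metrics (s).
#' @return Tibble: id columns plus `mean_nn_ms`, `sdnn_ms`, `rmssd_ms`,
#'   `n_nn`, `lf_power`, `hf_power`, `lf_hf_ratio`.
#' @export
segment_hrv <- function(nn, spans, min_span_s = 60) {
  stopifnot(inherits(nn, "nn_series"))
  id_cols <- setdiff(names(spans), c("t_start", "t_end"))
  purrr::map_dfr(seq_len(nrow(spans)), function(i) {
    t0 <- spans$t_start[i]
    t1 <- spans$t_end[i]
    term <- nn$peak_times_s[-1]
    inside <- term >= t0 & term < t1
    ids <- spans[i, id_cols, drop = FALSE]
    if (sum(inside) == 0L) {
      return(dplyr::bind_cols(
        ids,
        tibble::tibble(mean_nn_ms = NA_real_, sdnn_ms = NA_real_,
                       rmssd_ms = NA_real_, n_nn = 0L,
                       lf_power = NA_real_, hf_power = NA_real_,
                       lf_hf_ratio = NA_real_)
      ))
    }
    first_peak <- min(which(inside))        # index into intervals
    seg_peaks <- nn$peak_times_s[c(first_peak, which(inside) + 1L)]
    seg <- nn_series(seg_peaks, artifact = nn$artifact[inside])
    tm <- suppressMessages(hrv_time(seg))
    fr <- suppressMessages(hrv_freq(seg, min_span_s = min_span_s))
    dplyr::bind_cols(ids, tm, fr)
  })
}

#' Per-level time spans of a recording
#'
#' Maps the schedule's per-level trial windows onto the recording timeline
#' using the trial onset/offset times of one participant.
#'
#' @param trials One participant's trial table with `trial`, `t_on_s`,
#'   `t_off_s`.
#' @param schedule A `task_schedule`.
#' @return Tibble: `block`, `level`, `deceptive`, `t_start`, `t_end`.
#' @export
window_spans <- function(trials, schedule) {
  win <- level_windows(schedule)
  trials <- dplyr::arrange(trials, .data$trial)
  dplyr::mutate(
    win,
    t_start = trials$t_on_s[.data$first_trial + 1L],
    t_end = trials$t_off_s[.data$last_trial]
  )[c("block", "level", "deceptive", "t_start", "t_end")]
}
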