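# alternating local extrema from zero-crossing segments of a detrended trace
alternating_extrema <- function(x, fs) {
  s <- sign(x)
  s[s == 0] <- 1
  bounds <- c(0L, which(diff(s) != 0), length(x))
  out <- purrr::map_dfr(seq_len(length(bounds) - 1L), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    if (x[idx[1]] > 0) {
      tibble::tibble(kind = "peak", idx = idx[which.max(x[idx])])
    } else {
      tibble::tibble(kind = "trough", idx = idx[which.min(x[idx])])
    }
  })
  dplyr::mutate(out, t_s = (.data$idx - 1L) / fs, value = x[.data$idx])
}

#' Skin-conductance response (SCR) peak metrics
#'
#' The phasic component is extracted with a zero-phase 0.05 Hz Butterworth
#' high-pass (the lower edge of the EDA acquisition band); SCR peaks are
#' local maxima whose rise amplitude (peak minus preceding trough) reaches
#' `threshold_uS` and whose peak stands above the phasic baseline.
#'
#' @param eda EDA waveform in microsiemens.
#' @param fs Sampling rate (>= 10 Hz).
#' @param t_start,t_end Optional analysis window (s); default whole trace.
#' @param threshold_uS Minimum rise amplitude (default 0.05).
#' @return One-row tibble: `scr_peak_count`, `scr_peak_amp_mean_uS` (`NA`
#'   when no peak qualifies).
#' @export
scr_metrics <- function(eda, fs, t_start = 0, t_end = length(eda) / fs,
                        threshold_uS = 0.05) {
  if (fs < 10) rlang::abort("fs must be >= 10 Hz")
  hp <- signal::butter(2, 0.05 / (fs / 2), type = "high")
  # center first so the zero-padded filter start-up does not see the tonic
  # level as a step; keep a 2 s guard band clear of both trace edges
  phasic <- signal::filtfilt(hp, eda - mean(eda))
  guard <- if (length(eda) > 10 * fs) floor(2 * fs) else 0L
  lo <- max(1L + guard, floor(t_start * fs) + 1L)
  hi <- min(length(eda) - guard, ceiling(t_end * fs))
  phasic <- phasic[seq.int(lo, hi)]
  if (stats::sd(phasic) < 1e-9) {
    return(tibble::tibble(scr_peak_count = 0L, scr_peak_amp_mean_uS = NA_real_))
  }
  ext <- alternating_extrema(phasic - mean(phasic), fs)
  peaks <- which(ext$kind == "peak")
  rises <- purrr::map_dbl(peaks, function(p) {
    prev_troughs <- which(ext$kind == "trough" & seq_len(nrow(ext)) < p)
    if (length(prev_troughs) == 0L) return(NA_real_)
    ext$value[p] - ext$value[max(prev_troughs)]
  })
  # a genuine SCR both rises by >= threshold and carries its peak above the
  # phasic baseline; the second clause rejects filter-ringing recovery bumps
  qual <- !is.na(rises) & rises >= threshold_uS &
    ext$value[peaks] > threshold_uS / 2
  tibble::tibble(
    scr_peak_count = sum(qual),
    scr_peak_amp_mean_uS = if (any(qual)) mean(rises[qual]) else NA_real_
  )
}

#' Respiration cycle metrics
#'
#' Cycles are delimited by zero-crossings of the linearly detrended trace;
#' inspiration is the trough-to-peak limb and expiration the peak-to-trough
#' limb. Reports breathing rate (cycles/min), mean peak-trough amplitude,
#' mean phase durations and the inspiration/expiration duration ratio.
#'
#' @param rsp Respiration waveform.
#' @param fs Sampling rate (>= 10 Hz).
#' @param t_start,t_end Optional analysis window (s).
#' @return One-row tibble: `rsp_rate_mean_bpm`, `rsp_amp_mean`,
#'   `rsp_insp_s`, `rsp_exp_s`, `rsp_phase_ratio`; all `NA` with fewer than
#'   two complete cycles.
#' @export
rsp_metrics <- function(rsp, fs, t_start = 0, t_end = length(rsp) / fs) {
  if (fs < 10) rlang::abort("fs must be >= 10 Hz")
  idx <- seq.int(max(1L, floor(t_start * fs) + 1L), min(length(rsp), ceiling(t_end * fs)))
  x <- rsp[idx]
  tt <- seq_along(x) / fs
  x <- x - stats::lm.fit(cbind(1, tt), x)$fitted.values
  na_row <- tibble::tibble(rsp_rate_mean_bpm = NA_real_, rsp_amp_mean = NA_real_,
                           rsp_insp_s = NA_real_, rsp_exp_s = NA_real_,
                           rsp_phase_ratio = NA_real_)
  if (stats::sd(x) < 1e-12) return(na_row)
  ext <- alternating_extrema(x, fs)
  troughs <- which(ext$kind == "trough")
  insp <- c()
  expd <- c()
  amps <- c()
  for (tr in troughs) {
    if (tr + 2L > nrow(ext)) break
    # complete cycle: trough -> peak -> trough
    insp <- c(insp, ext$t_s[tr + 1L] - ext$t_s[tr])
    expd <- c(expd, ext$t_s[tr + 2L] - ext$t_s[tr + 1L])
    amps <- c(amps, ext$value[tr + 1L] - ext$value[tr])
  }
  if (length(insp) < 2L) return(na_row)
  cycle_dur <- insp + expd
  tibble::tibble(
    rsp_rate_mean_bpm = 60 / mean(cycle_dur),
    rsp_amp_mean = mean(amps),
    rsp_insp_s = mean(insp),
    rsp_exp_s = mean(expd),
    rsp_phase_ratio = mean(insp) / mean(expd)
  )
}
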