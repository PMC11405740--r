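#' Aggregate eye events into per-level metrics
#'
#' Assigns each saccade / fixation / blink to the level window containing
#' its onset time and summarizes the metrics compared across clusters:
#' counts, mean saccade velocity and amplitude, summed saccade duration,
#' mean fixation and blink durations. Events falling outside every window
#' are ignored (their count is reported via a message). Means over an empty
#' window are missing; counts are 0.
#'
#' @param events Event table with `type` (`"saccade"`, `"fixation"`,
#'   `"blink"`), `onset_s`, `duration_ms`, and for saccades
#'   `amplitude_deg`, `velocity_mean_deg_s`.
#' @param spans Per-level time spans (from [window_spans()]): `block`,
#'   `level`, `t_start`, `t_end`.
#' @return Tibble with one row per (block, level) and the eye metric
#'   columns.
#' @export
aggregate_eye <- function(events, spans) {
  needed <- c("type", "onset_s", "duration_ms")
  if (!all(needed %in% names(events))) {
    rlang::abort("events needs columns type, onset_s, duration_ms")
  }
  brk <- c(spans$t_start, spans$t_end[nrow(spans)])
  if (is.unsorted(brk)) rlang::abort("spans must be time-ordered and contiguous")
  win_of <- findInterval(events$onset_s, brk, rightmost.closed = FALSE)
  win_of[events$onset_s >= spans$t_end[nrow(spans)]] <- 0L
  # onsets in the inter-window gap belong to no window
  in_win <- win_of >= 1L & win_of <= nrow(spans) &
    events$onset_s < spans$t_end[pmax(win_of, 1L)]
  n_out <- sum(!in_win)
  if (n_out > 0) message(sprintf("aggregate_eye: %d event(s) outside all windows ignored", n_out))
  ev <- dplyr::mutate(events[in_win, ], .win = win_of[in_win])

  base <- dplyr::select(dplyr::mutate(spans, .win = dplyr::row_number()),
                        ".win", "block", "level")
  summarise_type <- function(type, exprs) {
    sub <- dplyr::group_by(ev[ev$type == type, ], .data$.win)
    dplyr::summarise(sub, !!!exprs, .groups = "drop")
  }
  sac <- summarise_type("saccade", rlang::quos(
    saccade_count = dplyr::n(),
    saccade_velocity_mean_deg_s = mean(.data$velocity_mean_deg_s),
    saccade_duration_sum_ms = sum(.data$duration_ms),
    saccade_amplitude_mean_deg = mean(.data$amplitude_deg)
  ))
  fix <- summarise_type("fixation", rlang::quos(
    fixation_count = dplyr::n(),
    fixation_duration_mean_ms = mean(.data$duration_ms)
  ))
  bli <- summarise_type("blink", rlang::quos(
    blink_count = dplyr::n(),
    blink_duration_mean_ms = mean(.data$duration_ms)
  ))
  out <- base |>
    dplyr::left_join(sac, by = ".win") |>
    dplyr::left_join(fix, by = ".win") |>
    dplyr::left_join(bli, by = ".win") |>
    dplyr::mutate(dplyr::across(dplyr::ends_with("_count"),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::select(-".win")
  out
}

#' Aggregate behavioral records into per-level metrics
#'
#' Per level: mean response time over trials with a response, mistake count
#' (incorrect responses), the level's single self-esteem rating, and the
#' level's summed response time. `total_time_ms` — the response-time sum
#' over the whole task — is attached to every row for convenience.
#'
#' @param trials One participant's trial table: `trial`, `block`, `level`,
#'   `rt_ms`, `correct`, `self_esteem`.
#' @return Tibble with one row per (block, level): `rt_mean_ms`, `mistakes`,
#'   `self_esteem`, `level_time_ms`, `total_time_ms`, `n_missing_response`.
#' @export
aggregate_behavior <- function(trials) {
  needed <- c("block", "level", "rt_ms", "correct", "self_esteem")
  if (!all(needed %in% names(trials))) {
    rlang::abort("trials needs columns block, level, rt_ms, correct, self_esteem")
  }
  total <- sum(trials$rt_ms, na.rm = TRUE)
  trials |>
    dplyr::group_by(.data$block, .data$level) |>
    dplyr::summarise(
      rt_mean_ms = mean(.data$rt_ms, na.rm = TRUE),
      mistakes = sum(!.data$correct, na.rm = TRUE),
      self_esteem = .data$self_esteem[1],
      level_time_ms = sum(.data$rt_ms, na.rm = TRUE),
      n_missing_response = sum(is.na(.data$rt_ms) | is.na(.data$correct)),
      .groups = "drop"
    ) |>
    dplyr::mutate(total_time_ms = total)
}

#' Long-format per-level metrics table for a whole cohort
#'
#' Runs the autonomic, oculomotor and behavioral aggregations for every
#' participant and stacks the results into the long table consumed by the
#' group-statistics stage, keyed by (participant, block, level, metric).
#'
#' @param cohort A `cohort`.
#' @param channels Which metric families to compute. Computing `"hrv"`
#'   requires the ECG channel in the cohort; `"scr"`/`"rsp"` their traces.
#' @param min_span_s Minimum span for frequency-domain HRV (s).
#' @return Long tibble: `participant`, `block`, `level`, `metric`, `value`.
#' @export
cohort_metrics <- function(cohort,
                           channels = c("hrv", "eye", "behavior", "scr", "rsp"),
                           min_span_s = 60) {
  stopifnot(inherits(cohort, "cohort"))
  channels <- match.arg(channels, several.ok = TRUE)
  ids <- cohort$truth$participant
  sched <- cohort$schedule

  one <- function(id) {
    tr <- cohort$trials[cohort$trials$participant == id, ]
    spans <- window_spans(tr, sched)
    parts <- list()
    if ("behavior" %in% channels) {
      parts$behavior <- aggregate_behavior(tr)
    }
    if ("eye" %in% channels && nrow(cohort$events) > 0) {
      ev <- cohort$events[cohort$events$participant == id, ]
      parts$eye <- aggregate_eye(ev, spans)
    }
    sig <- if (nrow(cohort$signals) > 0) {
      cohort$signals[cohort$signals$participant == id, ]
    } else {
      tibble::tibble(participant = character(), channel = character())
    }
    if ("hrv" %in% channels && "ecg" %in% sig$channel) {
      row <- sig[sig$channel == "ecg", ]
      ecg <- filter_ecg(row$trace[[1]], row$fs)
      nn <- detect_r_peaks(ecg, row$fs)
      nn <- clean_nn(nn)
      parts$hrv <- segment_hrv(nn, spans, min_span_s = min_span_s) |>
        dplyr::select(-"deceptive", -"n_nn")
    }
    if ("scr" %in% channels && "eda" %in% sig$channel) {
      row <- sig[sig$channel == "eda", ]
      parts$scr <- dplyr::bind_cols(
        spans[c("block", "level")],
        purrr::map2_dfr(spans$t_start, spans$t_end,
                        ~ scr_metrics(row$trace[[1]], row$fs, .x, .y))
      )
    }
    if ("rsp" %in% channels && "rsp" %in% sig$channel) {
      row <- sig[sig$channel == "rsp", ]
      parts$rsp <- dplyr::bind_cols(
        spans[c("block", "level")],
        purrr::map2_dfr(spans$t_start, spans$t_end,
                        ~ rsp_metrics(row$trace[[1]], row$fs, .x, .y))
      )
    }
    wide <- purrr::reduce(parts, dplyr::left_join, by = c("block", "level"))
    wide |>
      tidyr::pivot_longer(-c("block", "level"), names_to = "metric",
                          values_to = "value") |>
      dplyr::mutate(participant = id, .before = 1)
  }
  suppressMessages(purrr::map_dfr(ids, one))
}

#' Per-level normalized pupil summaries
#'
#' Mean of the processed (normalized, optionally smoothed) pupil trajectory
#' within each level window, as a long metrics table mergeable with
#' [cohort_metrics()] output.
#'
#' @param traj A `pupil_trajectories` (normalized or smoothed).
#' @param schedule A `task_schedule`.
#' @return Long tibble: `participant`, `block`, `level`, `metric`
#'   (`"pupil_norm_mean"`), `value`.
#' @export
pupil_level_metrics <- function(traj, schedule) {
  stopifnot(inherits(traj, "pupil_trajectories"))
  win <- level_windows(schedule)
  purrr::map_dfr(seq_len(nrow(win)), function(i) {
    idx <- (win$first_trial[i] + 1L):win$last_trial[i]
    tibble::tibble(
      participant = traj$participants,
      block = win$block[i], level = win$level[i],
      metric = "pupil_norm_mean",
      value = rowMeans(traj$values[, idx, drop = FALSE])
    )
  })
}
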