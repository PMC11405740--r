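#' Noise-free pupil shape of an archetype
#'
#' Evaluates the archetype's pupil trajectory shape on every trial of the
#' schedule, in z-shape units: a per-block linear segment
#' `block_start + within_block_slope * u` (with `u` the within-block position
#' in [0, 1]) plus, when `deception_peak > 0`, a Gaussian bump (SD 8 trials)
#' centered on the first deceptive (block, level) cell.
#'
#' @param arch An `archetype_spec`.
#' @param schedule A `task_schedule`.
#' @return Numeric vector of length `total_trials(schedule)`.
#' @export
pupil_shape <- function(arch, schedule) {
  stopifnot(inherits(arch, "archetype_spec"), inherits(schedule, "task_schedule"))
  tab <- schedule_table(schedule)
  per_block <- schedule$n_levels_per_block * schedule$n_trials_per_level
  pos <- tab$trial %% per_block
  u <- if (per_block > 1L) pos / (per_block - 1L) else rep(0, nrow(tab))
  shape <- arch$block_start + arch$within_block_slope * u
  dc <- schedule$deceptive_cells
  if (arch$deception_peak > 0 && nrow(dc) > 0L) {
    first_cell <- dc[1, ]
    win <- level_windows(schedule)
    w <- win[win$block == first_cell$block & win$level == first_cell$level, ]
    center <- (w$first_trial + w$last_trial - 1L) / 2
    shape <- shape + arch$deception_peak * exp(-0.5 * ((tab$trial - center) / 8)^2)
  }
  shape
}

#' Simulate one pupil trajectory
#'
#' The archetype shape plus iid Gaussian per-trial noise, in z-shape units.
#' Between-participant variation (baseline size, shape jitter) is added by
#' [generate_cohort()], not here.
#'
#' @param arch An `archetype_spec`.
#' @param schedule A `task_schedule`.
#' @param noise_sd Per-trial Gaussian noise SD (z-shape units); `0` returns
#'   the deterministic shape. Uses the current RNG state.
#' @return Numeric vector of per-trial pupil means, length
#'   `total_trials(schedule)`.
#' @export
pupil_trace <- function(arch, schedule, noise_sd = 0) {
  if (noise_sd < 0) rlang::abort("noise_sd must be >= 0")
  shape <- pupil_shape(arch, schedule)
  if (noise_sd > 0) shape <- shape + stats::rnorm(length(shape), 0, noise_sd)
  shape
}

#' Simulate an RR (NN) interval series
#'
#' Interval `i`, terminating at cumulative time `t_i`, is
#' `mean_nn + lf_mod_amp * sin(2*pi*0.1*t) + hf_mod_amp * sin(2*pi*0.25*t) +
#' e`, with `e ~ N(0, jitter_sd)` and `t` the interval's onset time. The
#' 0.1 Hz and 0.25 Hz carriers sit at the centers of the standard LF and HF
#' bands. Intervals are floored at 301 ms (physiological lower bound); the
#' deterministic part must stay above 300 ms or an error is raised.
#'
#' @param arch An `archetype_spec` (uses `mean_nn_ms`, `lf_mod_amp`,
#'   `hf_mod_amp`).
#' @param duration_s Series duration in seconds (>= 60).
#' @param jitter_sd Beat-to-beat Gaussian jitter SD in ms; the archetype's
#'   RMSSD target corresponds to `rmssd_target_ms / sqrt(2)`.
#' @return Tibble with columns `rr_ms` (interval length) and `t_s` (time of
#'   the interval's terminating beat, first beat at t = 0). Uses the current
#'   RNG state.
#' @export
rr_series <- function(arch, duration_s, jitter_sd = arch$rmssd_target_ms / sqrt(2)) {
  stopifnot(inherits(arch, "archetype_spec"))
  if (duration_s < 60) rlang::abort("duration_s must be >= 60 s")
  if (arch$mean_nn_ms - abs(arch$lf_mod_amp) - abs(arch$hf_mod_amp) <= 300) {
    rlang::abort("archetype parameters imply non-physiological (<= 300 ms) RR intervals")
  }
  n_max <- ceiling(duration_s * 1000 / (arch$mean_nn_ms - abs(arch$lf_mod_amp) -
                                          abs(arch$hf_mod_amp))) + 16L
  jit <- if (jitter_sd > 0) stats::rnorm(n_max, 0, jitter_sd) else numeric(n_max)
  rr <- numeric(n_max)
  t <- 0
  n <- 0L
  for (i in seq_len(n_max)) {
    x <- arch$mean_nn_ms +
      arch$lf_mod_amp * sin(2 * pi * 0.1 * t) +
      arch$hf_mod_amp * sin(2 * pi * 0.25 * t) +
      jit[i]
    x <- max(x, 301)
    if (t + x / 1000 > duration_s) break
    n <- i
    rr[i] <- x
    t <- t + x / 1000
  }
  rr <- rr[seq_len(n)]
  tibble::tibble(rr_ms = rr, t_s = cumsum(rr) / 1000)
}

#' Render a synthetic ECG from an RR series
#'
#' Places a narrow positive Gaussian QRS template (SD 12 ms) at each beat
#' time and adds white baseline noise and, optionally, slow sinusoidal
#' baseline wander (0.33 Hz). The first beat is at 0.2 s; ground-truth peak
#' sample indices are returned alongside the waveform.
#'
#' @param rr Numeric vector of RR intervals (ms) or a tibble from
#'   [rr_series()].
#' @param fs Sampling rate in Hz (>= 100).
#' @param qrs_amp QRS peak amplitude (arbitrary units).
#' @param baseline_noise_sd White-noise SD, same units as `qrs_amp`.
#' @param baseline_wander_amp Amplitude of the 0.33 Hz baseline wander.
#' @return A list of class `ecg_trace`: `signal`, `fs`, `peak_idx` (1-based
#'   ground-truth sample indices), `peak_times_s`. Uses the current RNG
#'   state when noise is requested.
#' @export
render_ecg <- function(rr, fs = 250, qrs_amp = 1, baseline_noise_sd = 0,
                       baseline_wander_amp = 0) {
  if (is.data.frame(rr)) rr <- rr$rr_ms
  if (fs < 100) rlang::abort("fs must be >= 100 Hz")
  peak_times <- 0.2 + c(0, cumsum(rr) / 1000)
  n <- ceiling((max(peak_times) + 0.5) * fs)
  sig <- numeric(n)
  width_s <- 0.012
  half <- ceiling(4 * width_s * fs)
  t_grid <- seq_len(n) / fs
  for (pt in peak_times) {
    c_idx <- round(pt * fs)
    lo <- max(1L, c_idx - half)
    hi <- min(n, c_idx + half)
    idx <- lo:hi
    sig[idx] <- sig[idx] + qrs_amp * exp(-0.5 * ((t_grid[idx] - pt) / width_s)^2)
  }
  if (baseline_wander_amp > 0) {
    sig <- sig + baseline_wander_amp * sin(2 * pi * 0.33 * t_grid)
  }
  if (baseline_noise_sd > 0) {
    sig <- sig + stats::rnorm(n, 0, baseline_noise_sd)
  }
  structure(
    list(
      signal = sig, fs = fs,
      peak_idx = pmin(pmax(round(peak_times * fs), 1L), n),
      peak_times_s = peak_times
    ),
    class = "ecg_trace"
  )
}

#' Simulate eye events and behavior for one participant
#'
#' Response times are gamma-distributed (shape 8) with mean
#' `rt_mean_ms + rt_level_slope_ms * (level - 1)`; correctness is Bernoulli
#' with the archetype's per-level error probability; trial duration is
#' RT + a fixed 1.8 s stimulus/feedback overhead, and trial onsets
#' accumulate on a contiguous timeline. Saccades, fixations and blinks are
#' homogeneous Poisson processes within each level's time span, with
#' lognormal amplitudes, velocities and durations. Self-esteem after each
#' level is `round(5.2 - 0.45*level + bias + N(0, 0.4))` clipped to 1..5.
#'
#' @param arch An `archetype_spec`.
#' @param schedule A `task_schedule`.
#' @param overhead_ms Fixed non-response time per trial (stimulus + feedback).
#' @param events Generate the eye-event table (`TRUE`) or only behavior.
#' @return A list with `trials` (tibble: trial, block, level, rt_ms, correct,
#'   response, t_on_s, t_off_s, self_esteem) and `events` (tibble: type,
#'   onset_s, duration_ms, amplitude_deg, velocity_mean_deg_s). Uses the
#'   current RNG state; behavioral draws precede event draws, so the trial
#'   table is unaffected by `events`.
#' @export
eye_and_behavior <- function(arch, schedule, overhead_ms = 1800, events = TRUE) {
  stopifnot(inherits(arch, "archetype_spec"), inherits(schedule, "task_schedule"))
  tab <- schedule_table(schedule)
  n <- nrow(tab)
  if (length(arch$error_prob_by_level) < schedule$n_levels_per_block) {
    rlang::abort("error_prob_by_level shorter than the number of levels")
  }
  rt_mean <- arch$rt_mean_ms + arch$rt_level_slope_ms * (tab$level - 1)
  shape <- 8
  rt_ms <- stats::rgamma(n, shape = shape, rate = shape / rt_mean)
  p_err <- arch$error_prob_by_level[tab$level]
  correct <- stats::rbinom(n, 1L, 1 - p_err) == 1L
  dur_s <- (rt_ms + overhead_ms) / 1000
  t_off <- cumsum(dur_s)
  t_on <- t_off - dur_s

  win <- level_windows(schedule)
  se_lvl <- pmin(pmax(round(
    5.2 - 0.45 * win$level + arch$self_esteem_bias + stats::rnorm(nrow(win), 0, 0.4)
  ), 1), 5)
  trials <- tibble::tibble(
    trial = tab$trial, block = tab$block, level = tab$level,
    rt_ms = rt_ms, correct = correct,
    response = ifelse(correct, "match_correct", "mismatch_wrong"),
    t_on_s = t_on, t_off_s = t_off,
    self_esteem = rep(se_lvl, each = schedule$n_trials_per_level)
  )

  if (!events) {
    return(list(trials = trials, events = tibble::tibble()))
  }
  spans <- tibble::tibble(
    t_start = t_on[win$first_trial + 1L],
    t_end = t_off[win$last_trial]
  )
  list(trials = trials, events = eye_events_for(arch, spans))
}

# Poisson eye events at archetype rates over the given time spans.
eye_events_for <- function(arch, spans) {
  gen_events <- function(rate, durations_median_ms, dur_sdlog = 0.3,
                         amp = NA_real_, vel = NA_real_, type = "saccade") {
    widths <- spans$t_end - spans$t_start
    k <- stats::rpois(nrow(spans), rate * widths)
    total <- sum(k)
    if (total == 0L) return(NULL)
    span_of <- rep.int(seq_len(nrow(spans)), k)
    onsets <- spans$t_start[span_of] + stats::runif(total) * widths[span_of]
    tibble::tibble(
      type = type,
      onset_s = onsets[order(span_of, onsets)],
      duration_ms = stats::rlnorm(total, log(durations_median_ms), dur_sdlog),
      amplitude_deg = if (is.na(amp)) NA_real_ else stats::rlnorm(total, log(amp), 0.4),
      velocity_mean_deg_s = if (is.na(vel)) NA_real_ else stats::rlnorm(total, log(vel), 0.25)
    )
  }
  ev <- dplyr::bind_rows(
    gen_events(arch$saccade_rate_hz, 30, amp = arch$saccade_amp_deg,
               vel = arch$saccade_vel_deg_s, type = "saccade"),
    gen_events(arch$fixation_rate_hz, arch$fixation_dur_ms, type = "fixation"),
    gen_events(arch$blink_rate_hz, arch$blink_dur_ms, type = "blink")
  )
  dplyr::arrange(ev, .data$onset_s)
}

# Tonic EDA drift plus exponential-recovery SCR events at Poisson times.
simulate_eda <- function(duration_s, fs, scr_rate_per_min = 3,
                         scr_amp_median_uS = 0.3, tonic_uS = 2) {
  n <- ceiling(duration_s * fs)
  t <- seq_len(n) / fs
  sig <- tonic_uS + 0.0005 * t
  k <- stats::rpois(1L, scr_rate_per_min * duration_s / 60)
  if (k > 0L) {
    onsets <- sort(stats::runif(k, 0, duration_s - 10))
    amps <- stats::rlnorm(k, log(scr_amp_median_uS), 0.4)
    for (j in seq_len(k)) {
      rel <- t - onsets[j]
      idx <- rel > 0 & rel < 15
      r <- rel[idx]
      # double-exponential SCR kernel: ~1 s rise, ~3 s recovery
      kern <- exp(-r / 3) - exp(-r / 0.75)
      sig[idx] <- sig[idx] + amps[j] * kern / max(kern)
    }
  }
  sig
}

# Sinusoidal respiration with breath-by-breath period jitter.
simulate_rsp <- function(duration_s, fs, rate_bpm = 15, amp = 1,
                         period_jitter_sd = 0.3) {
  n <- ceiling(duration_s * fs)
  out <- numeric(n)
  t0 <- 0
  while (t0 < duration_s) {
    period <- max(1.5, 60 / rate_bpm + stats::rnorm(1, 0, period_jitter_sd))
    idx_lo <- floor(t0 * fs) + 1L
    idx_hi <- min(n, ceiling((t0 + period) * fs))
    if (idx_lo > n) break
    tt <- (seq(idx_lo, idx_hi) / fs - t0) / period
    # start at a trough so each breath is trough -> peak -> trough
    out[idx_lo:idx_hi] <- -amp * cos(2 * pi * tt)
    t0 <- t0 + period
  }
  out
}

#' Generate a synthetic multimodal cohort
#'
#' Draws `n_per_archetype` participants per archetype and simulates every
#' channel on a contiguous timeline: trial-averaged pupil sizes (mm), trial
#' responses and times, eye events, continuous ECG / EDA / respiration at
#' `fs` Hz, questionnaires, and ground-truth archetype labels. Defaults
#' reproduce the study conditions: a 70-participant cohort split 33 / 37
#' across the two phenotypes, recorded at 250 Hz.
#'
#' Pupil values are `baseline + 0.6 mm * shape + noise`, where the shape is
#' the archetype's [pupil_shape()] with per-participant jitter on its offset
#' and slope; `noise_config` (see [default_noise()]) scales every stochastic
#' component, so a zero-noise cohort has identical pupil vectors within an
#' archetype.
#'
#' @param schedule A `task_schedule`.
#' @param archetypes List of two `archetype_spec`s (labels 0 and 1).
#' @param n_per_archetype Integer vector of length 2; both entries >= 2.
#' @param noise_config See [default_noise()].
#' @param seed Integer seed; the cohort is a pure function of its arguments.
#' @param fs Sampling rate for continuous channels (Hz).
#' @param channels Channels to simulate; dropping unused channels (e.g.
#'   everything but `"pupil"` for clustering-only studies) saves time and
#'   memory.
#' @return A list of class `cohort` with tibbles `trials`, `events`,
#'   `questionnaires`, `truth`, a `signals` tibble (participant, channel,
#'   fs, trace list-column, and for ECG the ground-truth peak indices), the
#'   `schedule`, and the generator parameters.
#' @export
generate_cohort <- function(schedule = build_schedule(),
                            archetypes = default_archetypes(),
                            n_per_archetype = c(33L, 37L),
                            noise_config = default_noise(),
                            seed = 1L,
                            fs = 250,
                            channels = c("pupil", "ecg", "eda", "rsp", "eye")) {
  stopifnot(inherits(schedule, "task_schedule"))
  if (length(archetypes) != 2L) rlang::abort("archetypes must be a list of two specs")
  n_per_archetype <- as.integer(n_per_archetype)
  if (any(n_per_archetype < 2L)) {
    rlang::abort("n_per_archetype entries must be >= 2 (group statistics undefined)")
  }
  channels <- match.arg(channels, several.ok = TRUE)

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)

  n_total <- sum(n_per_archetype)
  ids <- sprintf("P%03d", seq_len(n_total))
  arch_idx <- rep(c(1L, 2L), times = n_per_archetype)
  truth <- tibble::tibble(
    participant = ids,
    archetype = purrr::map_int(archetypes, "label")[arch_idx]
  )

  trials <- vector("list", n_total)
  events <- vector("list", n_total)
  signals <- vector("list", n_total)
  quest <- vector("list", n_total)
  pupil_unit_mm <- 0.6

  for (i in seq_len(n_total)) {
    # derived per-participant substream: within a participant, pupil and
    # behavior are drawn before the continuous channels, so dropping
    # trailing channels never perturbs the channels that are kept
    set.seed((seed %% 100000L) * 20011L + i)
    arch <- archetypes[[arch_idx[i]]]
    # per-participant shape jitter (z-shape units)
    jit <- noise_config$shape_jitter
    arch_i <- arch
    if (jit > 0) {
      arch_i$block_start <- arch$block_start + stats::rnorm(1, 0, jit)
      arch_i$within_block_slope <- arch$within_block_slope + stats::rnorm(1, 0, jit)
      if (arch$deception_peak > 0) {
        arch_i$deception_peak <- max(0, arch$deception_peak + stats::rnorm(1, 0, jit))
      }
    }
    baseline <- 4.0 + (if (noise_config$baseline_sd_mm > 0)
      stats::rnorm(1, 0, noise_config$baseline_sd_mm) else 0)

    beh <- eye_and_behavior(arch_i, schedule, events = FALSE)
    tr <- beh$trials
    if ("pupil" %in% channels) {
      noise_shape_sd <- noise_config$trial_sd_mm / pupil_unit_mm
      tr$pupil_mm <- baseline + pupil_unit_mm *
        pupil_trace(arch_i, schedule, noise_sd = noise_shape_sd)
    }
    quest[[i]] <- tibble::tibble(
      participant = ids[i],
      ess = round(pmin(pmax(stats::rnorm(1, arch$ess_mean, arch$ess_sd), 0), 24)),
      bdi = round(pmin(pmax(stats::rnorm(1, 9.3, 6.8), 0), 63)),
      stai_state = round(stats::rnorm(1, 42.7, 13)),
      stai_trait = round(stats::rnorm(1, 44.8, 9.7)),
      taylor = round(pmin(pmax(stats::rnorm(1, 20, 8.8), 0), 50)),
      bmi = stats::rnorm(1, 22, 2.85),
      smoking = stats::rbinom(1, 1L, arch$smoking_prob)
    )
    if ("eye" %in% channels) {
      spans_i <- window_spans(tr, schedule)
      ev <- eye_events_for(arch_i, spans_i)
      events[[i]] <- dplyr::mutate(ev, participant = ids[i], .before = 1)
    }
    duration_s <- max(tr$t_off_s) + 2
    sig_rows <- list()
    if ("ecg" %in% channels) {
      rrs <- rr_series(arch_i, duration_s)
      ecg <- render_ecg(rrs, fs = fs, qrs_amp = 1,
                        baseline_noise_sd = noise_config$ecg_noise_sd,
                        baseline_wander_amp = 0.05)
      sig_rows$ecg <- tibble::tibble(
        participant = ids[i], channel = "ecg", fs = fs,
        trace = list(ecg$signal), truth_peak_idx = list(ecg$peak_idx)
      )
    }
    if ("eda" %in% channels) {
      sig_rows$eda <- tibble::tibble(
        participant = ids[i], channel = "eda", fs = fs,
        trace = list(simulate_eda(duration_s, fs)), truth_peak_idx = list(NULL)
      )
    }
    if ("rsp" %in% channels) {
      sig_rows$rsp <- tibble::tibble(
        participant = ids[i], channel = "rsp", fs = fs,
        trace = list(simulate_rsp(duration_s, fs)), truth_peak_idx = list(NULL)
      )
    }
    trials[[i]] <- dplyr::mutate(tr, participant = ids[i], .before = 1)
    signals[[i]] <- dplyr::bind_rows(sig_rows)
  }

  structure(
    list(
      schedule = schedule,
      trials = dplyr::bind_rows(trials),
      events = if ("eye" %in% channels) dplyr::bind_rows(events) else
        tibble::tibble(),
      signals = dplyr::bind_rows(signals),
      questionnaires = dplyr::bind_rows(quest),
      truth = truth,
      params = list(
        archetypes = archetypes, n_per_archetype = n_per_archetype,
        noise_config = noise_config, seed = seed, fs = fs, channels = channels
      )
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d participants (%s per archetype), %d trials each, channels: %s\n",
    nrow(x$truth), paste(x$params$n_per_archetype, collapse = "/"),
    total_trials(x$schedule), paste(x$params$channels, collapse = ", ")
  ))
  invisible(x)
}

#' Write a cohort to a directory of tidy CSVs
#'
#' Writes `trials.csv`, `events.csv`, `questionnaires.csv`, a
#' `metadata.yaml` (sampling rate, seed, noise config), and the ground-truth
#' archetype labels in `truth.csv` — kept in a separate file that no
#' pipeline stage reads. Continuous traces are written one CSV per
#' participant/channel under `signals/` when `include_signals = TRUE` (they
#' are large).
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if absent).
#' @param include_signals Write continuous traces too.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, include_signals = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(cohort$events, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(cohort$questionnaires, file.path(dir, "questionnaires.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(
      seed = cohort$params$seed, fs = cohort$params$fs,
      n_per_archetype = cohort$params$n_per_archetype,
      noise_config = cohort$params$noise_config,
      schedule = schedule_to_config(cohort$schedule),
      channels = cohort$params$channels
    ),
    file.path(dir, "metadata.yaml")
  )
  if (include_signals && nrow(cohort$signals) > 0) {
    sdir <- file.path(dir, "signals")
    dir.create(sdir, showWarnings = FALSE)
    purrr::pwalk(cohort$signals[c("participant", "channel", "trace")],
                 function(participant, channel, trace) {
                   utils::write.csv(
                     data.frame(value = trace),
                     file.path(sdir, sprintf("%s_%s.csv", participant, channel)),
                     row.names = FALSE
                   )
                 })
  }
  invisible(dir)
}
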