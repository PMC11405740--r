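#' Per-participant pupil trajectories
#'
#' A `pupil_trajectories` object holds one trajectory per participant — the
#' vector of trial-averaged pupil sizes across the whole task (306 entries
#' under the default schedule) — together with its processing state
#' (`"raw"`, `"normalized"`, or `"smoothed"`). The fixed pipeline order is
#' raw trial means, per-participant z-scoring, moving-average smoothing,
#' then outlier screening.
#'
#' @param values Numeric matrix, participants x trials.
#' @param participants Character vector of row identities.
#' @param state Processing state.
#' @return A `pupil_trajectories` object.
#' @export
pupil_trajectories <- function(values, participants = rownames(values),
                               state = c("raw", "normalized", "smoothed")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (is.null(participants)) participants <- sprintf("P%03d", seq_len(nrow(values)))
  rownames(values) <- participants
  structure(
    list(values = values, participants = participants, state = state),
    class = "pupil_trajectories"
  )
}

#' @export
print.pupil_trajectories <- function(x, ...) {
  cat(sprintf("<pupil_trajectories> %d participants x %d trials (%s)\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @method as_tibble pupil_trajectories
#' @export
as_tibble.pupil_trajectories <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "participant") |>
    tidyr::pivot_longer(-"participant", names_to = "trial", values_to = "value") |>
    dplyr::mutate(trial = as.integer(sub("^V?", "", .data$trial)) - 1L,
                  state = x$state)
}

#' Trial-averaged pupil trajectories from sample- or trial-level data
#'
#' Collapses pupil samples to one arithmetic mean per (participant, trial)
#' and arranges them into the participants x trials trajectory matrix.
#' Works both on raw tracker samples (many rows per trial) and on tables
#' that already carry one mean per trial (identity). Trials with no valid
#' sample become missing values and are reported via a message.
#'
#' @param samples Data frame with columns `participant`, `trial` (0-based)
#'   and the pupil column named by `value`.
#' @param schedule A `task_schedule`; fixes the trajectory length.
#' @param value Name of the pupil column (default `"pupil_mm"`).
#' @return A `pupil_trajectories` object in state `"raw"`.
#' @export
trial_means <- function(samples, schedule, value = "pupil_mm") {
  stopifnot(inherits(schedule, "task_schedule"))
  if (!all(c("participant", "trial", value) %in% names(samples))) {
    rlang::abort(sprintf("samples needs columns participant, trial, %s", value))
  }
  n_tr <- total_trials(schedule)
  if (any(samples$trial < 0 | samples$trial >= n_tr)) {
    rlang::abort("trial indices outside the schedule's [0, total_trials) range")
  }
  means <- samples |>
    dplyr::group_by(.data$participant, .data$trial) |>
    dplyr::summarise(value = mean(.data[[value]], na.rm = TRUE), .groups = "drop")
  ids <- sort(unique(samples$participant))
  mat <- matrix(NA_real_, nrow = length(ids), ncol = n_tr,
                dimnames = list(ids, NULL))
  mat[cbind(match(means$participant, ids), means$trial + 1L)] <- means$value
  mat[is.nan(mat)] <- NA_real_
  n_missing <- sum(is.na(mat))
  if (n_missing > 0) {
    message(sprintf("trial_means: %d empty participant-trial cells left missing",
                    n_missing))
  }
  pupil_trajectories(mat, ids, state = "raw")
}

#' Z-score trajectories per participant
#'
#' Each participant's trajectory is centered on its own mean and divided by
#' its own standard deviation over the entire test period, removing
#' between-individual differences in absolute pupil size. The SD uses the
#' population (n) denominator, which makes the transform idempotent.
#' Missing entries stay missing and are excluded from the moments.
#'
#' @param traj A `pupil_trajectories` object.
#' @return A `pupil_trajectories` in state `"normalized"`.
#' @export
normalize_trajectories <- function(traj) {
  stopifnot(inherits(traj, "pupil_trajectories"))
  vals <- traj$values
  out <- t(apply(vals, 1, function(v) {
    ok <- !is.na(v)
    m <- mean(v[ok])
    s <- sqrt(mean((v[ok] - m)^2))
    if (!is.finite(s) || s == 0) return(rep(NaN, length(v)))
    (v - m) / s
  }))
  bad <- apply(out, 1, function(v) all(is.nan(v) | is.na(v))) &
    apply(vals, 1, function(v) !all(is.na(v)))
  if (any(bad)) {
    rlang::abort(sprintf("zero pupil-size SD for participant(s): %s",
                         paste(traj$participants[bad], collapse = ", ")))
  }
  dimnames(out) <- dimnames(vals)
  pupil_trajectories(out, traj$participants, state = "normalized")
}

# uniform moving average with shrinking edge windows ("same"-length output)
moving_average <- function(v, window) {
  n <- length(v)
  left <- floor((window - 1) / 2)
  right <- floor(window / 2)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Impute sporadic missing trials
#'
#' Linear interpolation over trial index for participants missing fewer than
#' `max_missing` of their trials; participants above the threshold are
#' dropped with a message. Run between normalization and smoothing.
#'
#' @param traj A `pupil_trajectories`.
#' @param max_missing Maximum tolerated missing fraction (default 0.05).
#' @return A `pupil_trajectories` with no missing values.
#' @export
impute_missing <- function(traj, max_missing = 0.05) {
  stopifnot(inherits(traj, "pupil_trajectories"))
  vals <- traj$values
  frac <- rowMeans(is.na(vals))
  drop <- frac >= max_missing & frac > 0
  if (any(drop)) {
    message(sprintf("impute_missing: excluding %d participant(s) with >= %.0f%% missing trials: %s",
                    sum(drop), 100 * max_missing,
                    paste(traj$participants[drop], collapse = ", ")))
    vals <- vals[!drop, , drop = FALSE]
  }
  fix <- which(rowSums(is.na(vals)) > 0)
  for (i in fix) {
    v <- vals[i, ]
    ok <- which(!is.na(v))
    vals[i, ] <- stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
  }
  pupil_trajectories(vals, rownames(vals), state = traj$state)
}

#' Smooth trajectories by uniform-kernel convolution
#'
#' Moving average with a uniform kernel whose width defaults to the number
#' of trials per difficulty level (17), so each smoothed point summarizes
#' roughly one level of the task. Output has the same length as the input;
#' edges use shrinking windows (the mean over the available neighbors).
#'
#' @param traj A `pupil_trajectories` (normalized; raw input is accepted and
#'   smoothed as-is).
#' @param window Kernel width in trials, >= 1.
#' @return A `pupil_trajectories` in state `"smoothed"`.
#' @export
smooth_trajectories <- function(traj, window = 17L) {
  stopifnot(inherits(traj, "pupil_trajectories"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L) rlang::abort("window must be >= 1")
  if (window > ncol(traj$values)) rlang::abort("window longer than the trajectory")
  if (anyNA(traj$values)) {
    rlang::abort("missing values present; run impute_missing() before smoothing")
  }
  out <- t(apply(traj$values, 1, moving_average, window = window))
  dimnames(out) <- dimnames(traj$values)
  pupil_trajectories(out, traj$participants, state = "smoothed")
}

#' Screen outlier trajectories with an isolation forest
#'
#' Scores every trajectory with [isolation_forest_scores()] and flags the
#' `ceiling(contamination * n)` highest-scoring participants. Flagged
#' participants are reported, never silently dropped: exclusion is an
#' explicit downstream choice.
#'
#' @param traj A `pupil_trajectories` (>= 10 participants).
#' @param contamination Expected outlier fraction, in (0, 0.5).
#' @param seed Integer seed for the forest.
#' @param n_trees Trees in the forest.
#' @return Tibble with columns `participant`, `score`, `flagged`.
#' @export
screen_outliers <- function(traj, contamination = 0.05, seed = 1L,
                            n_trees = 100L) {
  stopifnot(inherits(traj, "pupil_trajectories"))
  n <- nrow(traj$values)
  if (n < 10L) rlang::abort("outlier screening needs >= 10 trajectories")
  if (contamination <= 0 || contamination >= 0.5) {
    rlang::abort("contamination must lie in (0, 0.5)")
  }
  scores <- isolation_forest_scores(traj$values, n_trees = n_trees, seed = seed)
  k <- ceiling(contamination * n)
  thresh <- sort(scores, decreasing = TRUE)[k]
  tibble::tibble(
    participant = traj$participants,
    score = scores,
    flagged = rank(-scores, ties.method = "first") <= k & scores >= thresh
  )
}

#' Full pupil preprocessing pipeline
#'
#' Fixed order: trial means (taken from the cohort's per-trial table),
#' per-participant z-scoring, missing-trial imputation, uniform smoothing,
#' isolation-forest screening.
#'
#' @param trials Per-trial table with `participant`, `trial` and `pupil_mm`.
#' @param schedule A `task_schedule`.
#' @param window Smoothing window (trials).
#' @param contamination Outlier fraction for screening.
#' @param seed Seed for the isolation forest.
#' @param smooth Apply the smoothing stage (kept configurable; on by
#'   default).
#' @return List with `trajectories` (processed `pupil_trajectories`) and
#'   `outliers` (screening tibble).
#' @export
prepare_trajectories <- function(trials, schedule, window = 17L,
                                 contamination = 0.05, seed = 1L,
                                 smooth = TRUE) {
  traj <- trial_means(trials, schedule) |>
    normalize_trajectories() |>
    impute_missing()
  if (smooth) traj <- smooth_trajectories(traj, window = window)
  list(trajectories = traj, outliers = screen_outliers(traj, contamination, seed))
}
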