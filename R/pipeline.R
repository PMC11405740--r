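#' Default pipeline configuration
#'
#' @param output_dir Where the run writes its tables.
#' @param seed Master seed: the generator uses it directly and the
#'   clustering / screening stages use fixed offsets from it, so a config
#'   (with its seed) fully determines every output.
#' @return A nested list understood by [run_pipeline()].
#' @export
default_config <- function(output_dir = tempfile("pupilclust_run_"), seed = 1L) {
  list(
    mode = "synthetic",
    schedule = list(n_blocks = 3L, n_levels = 6L, n_trials = 17L),
    generator = list(
      n_per_archetype = c(33L, 37L),
      noise_scale = 1,
      seed = seed,
      fs = 250,
      channels = c("pupil", "ecg", "eda", "rsp", "eye")
    ),
    input_dir = NULL,
    pipeline = list(
      smoothing_window = 17L,
      smooth = TRUE,
      contamination = 0.05,
      drop_outliers = FALSE,
      k = 2L,
      n_init = 25L,
      kmeans_seed = seed + 1000L,
      screen_seed = seed + 2000L
    ),
    stats = list(alpha_normality = 0.05),
    metrics_channels = c("hrv", "eye", "behavior", "scr", "rsp"),
    output_dir = output_dir
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  base <- default_config()
  utils::modifyList(base, config)
}

#' Read a cohort from a directory layout
#'
#' Inverse of [write_cohort()]; the ground-truth `truth.csv` is
#' deliberately **not** read (only [validate_run()] touches it).
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `cohort` (without truth labels).
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("trials.csv", "metadata.yaml"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    rlang::abort(sprintf("input directory incomplete; first missing file: %s",
                         missing[1]))
  }
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  schedule <- schedule_from_config(meta$schedule)
  trials <- tibble::as_tibble(utils::read.csv(file.path(dir, "trials.csv")))
  events_path <- file.path(dir, "events.csv")
  events <- if (file.exists(events_path)) {
    tibble::as_tibble(utils::read.csv(events_path))
  } else tibble::tibble()
  q_path <- file.path(dir, "questionnaires.csv")
  quest <- if (file.exists(q_path)) {
    tibble::as_tibble(utils::read.csv(q_path))
  } else tibble::tibble()
  sdir <- file.path(dir, "signals")
  signals <- tibble::tibble()
  if (dir.exists(sdir)) {
    files <- list.files(sdir, pattern = "\\.csv$", full.names = TRUE)
    signals <- purrr::map_dfr(files, function(f) {
      parts <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
      tibble::tibble(
        participant = parts[1], channel = parts[2], fs = meta$fs,
        trace = list(utils::read.csv(f)$value), truth_peak_idx = list(NULL)
      )
    })
  }
  ids <- sort(unique(trials$participant))
  structure(
    list(
      schedule = schedule, trials = trials, events = events,
      signals = signals, questionnaires = quest,
      truth = tibble::tibble(participant = ids, archetype = NA_integer_),
      params = list(
        n_per_archetype = meta$n_per_archetype %||% NA_integer_,
        noise_config = meta$noise_config, seed = meta$seed, fs = meta$fs,
        channels = meta$channels %||% character()
      )
    ),
    class = "cohort"
  )
}

log_stage <- function(lines, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  c(lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate/ingest, pupil preprocessing, clustering with label
#' alignment, per-level metric extraction, cluster statistics, and report
#' writing, with stage-boundary logging and a JSON run manifest recording
#' seeds, a config hash, and row counts. Deterministic given the config.
#'
#' @param config A config list (see [default_config()]) or path to a YAML
#'   file with the same structure.
#' @return The output directory, invisibly. Side effects: writes
#'   `cohort/` (tidy inputs), `trajectories.csv`, `outliers.csv`,
#'   `labels.csv`, `centroids.csv`, `metrics.csv`, `report_levels.csv`,
#'   `report_blocks.csv`, `peak_reactions.csv`, `questionnaire_stats.csv`,
#'   `manifest.json`, `run.log`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- character()
  schedule <- build_schedule(cfg$schedule$n_blocks, cfg$schedule$n_levels,
                             cfg$schedule$n_trials)

  if (identical(cfg$mode, "synthetic")) {
    lines <- log_stage(lines, "generating synthetic cohort (seed %d)",
                       cfg$generator$seed)
    cohort <- generate_cohort(
      schedule = schedule,
      n_per_archetype = cfg$generator$n_per_archetype,
      noise_config = default_noise(cfg$generator$noise_scale),
      seed = cfg$generator$seed,
      fs = cfg$generator$fs,
      channels = cfg$generator$channels
    )
    write_cohort(cohort, file.path(cfg$output_dir, "cohort"))
  } else if (identical(cfg$mode, "directory")) {
    lines <- log_stage(lines, "reading cohort from %s", cfg$input_dir)
    cohort <- read_cohort(cfg$input_dir)
  } else {
    rlang::abort("config$mode must be 'synthetic' or 'directory'")
  }
  lines <- log_stage(lines, "cohort: %d participants, %d trial rows",
                     length(unique(cohort$trials$participant)),
                     nrow(cohort$trials))

  prep <- prepare_trajectories(
    cohort$trials, schedule,
    window = cfg$pipeline$smoothing_window,
    contamination = cfg$pipeline$contamination,
    seed = cfg$pipeline$screen_seed,
    smooth = cfg$pipeline$smooth
  )
  traj <- prep$trajectories
  utils::write.csv(as.data.frame(traj$values),
                   file.path(cfg$output_dir, "trajectories.csv"))
  utils::write.csv(prep$outliers, file.path(cfg$output_dir, "outliers.csv"),
                   row.names = FALSE)
  lines <- log_stage(lines, "trajectories: %d x %d (%s), %d flagged outliers",
                     nrow(traj$values), ncol(traj$values), traj$state,
                     sum(prep$outliers$flagged))

  fit_traj <- traj
  if (isTRUE(cfg$pipeline$drop_outliers)) {
    keep <- !prep$outliers$flagged[match(traj$participants,
                                         prep$outliers$participant)]
    fit_traj <- pupil_trajectories(traj$values[keep, , drop = FALSE],
                                   traj$participants[keep], state = traj$state)
    lines <- log_stage(lines, "dropped %d flagged participant(s) before clustering",
                       sum(!keep))
  }
  fit <- kmeans_fit(fit_traj, k = cfg$pipeline$k, n_init = cfg$pipeline$n_init,
                    seed = cfg$pipeline$kmeans_seed)
  if (cfg$pipeline$k == 2L) fit <- align_labels(fit, schedule, fit_traj)
  write_clustering(fit, cfg$output_dir)
  lines <- log_stage(lines, "clustering: k = %d, inertia %.3f, sizes %s",
                     fit$k, fit$inertia,
                     paste(table(fit$labels$cluster), collapse = "/"))

  metrics <- cohort_metrics(cohort, channels = cfg$metrics_channels)
  metrics <- dplyr::bind_rows(metrics, pupil_level_metrics(traj, schedule))
  utils::write.csv(metrics, file.path(cfg$output_dir, "metrics.csv"),
                   row.names = FALSE)
  lines <- log_stage(lines, "metrics: %d rows, %d metrics", nrow(metrics),
                     length(unique(metrics$metric)))

  alpha <- cfg$stats$alpha_normality
  lv <- suppressMessages(report_levels(metrics, fit, alpha_normality = alpha))
  bl <- suppressMessages(report_blocks(metrics, fit, alpha_normality = alpha))
  pk <- peak_reactions(metrics, fit, schedule)
  utils::write.csv(lv, file.path(cfg$output_dir, "report_levels.csv"),
                   row.names = FALSE)
  utils::write.csv(bl, file.path(cfg$output_dir, "report_blocks.csv"),
                   row.names = FALSE)
  utils::write.csv(pk, file.path(cfg$output_dir, "peak_reactions.csv"),
                   row.names = FALSE)
  if (nrow(cohort$questionnaires) > 0) {
    qs <- compare_questionnaires(cohort$questionnaires, fit)
    utils::write.csv(qs, file.path(cfg$output_dir, "questionnaire_stats.csv"),
                     row.names = FALSE)
  }
  lines <- log_stage(lines, "reports: %d level rows, %d block rows",
                     nrow(lv), nrow(bl))

  manifest <- list(
    package_version = as.character(utils::packageVersion("pupilclust")),
    config = cfg[setdiff(names(cfg), "output_dir")],
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "output_dir")]),
    seeds = list(generator = cfg$generator$seed,
                 kmeans = cfg$pipeline$kmeans_seed,
                 screening = cfg$pipeline$screen_seed),
    inertia = fit$inertia,
    row_counts = list(
      trials = nrow(cohort$trials), metrics = nrow(metrics),
      report_levels = nrow(lv), report_blocks = nrow(bl)
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(lines, file.path(cfg$output_dir, "run.log"))
  invisible(cfg$output_dir)
}

#' Validate a completed synthetic run against its ground truth
#'
#' Computes the adjusted Rand index between recovered clusters and the
#' generator's archetype labels, the aligned cluster sizes, and the
#' direction (sign) pattern of the block-level report for the phenotype
#' contrasts the generator encodes: cluster 0 higher MeanNN / SDNN /
#' RMSSD / HF; cluster 1 higher saccade, fixation and blink counts and
#' total response time. Writes `validation.json` into the run directory.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return A list (also serialized as JSON): `status`, `ari`,
#'   `cluster_sizes`, `sign_checks`.
#' @export
validate_run <- function(run_dir) {
  labels_path <- file.path(run_dir, "labels.csv")
  truth_path <- file.path(run_dir, "cohort", "truth.csv")
  if (!file.exists(labels_path)) rlang::abort("run directory has no labels.csv")
  labels <- utils::read.csv(labels_path)
  if (!file.exists(truth_path)) {
    out <- list(status = "skipped", note = "no truth file (non-synthetic run)")
    jsonlite::write_json(out, file.path(run_dir, "validation.json"),
                         auto_unbox = TRUE)
    return(out)
  }
  truth <- utils::read.csv(truth_path)
  merged <- dplyr::inner_join(labels, truth, by = "participant")
  ari <- adjusted_rand(merged$cluster, merged$archetype)

  sign_checks <- list()
  bl_path <- file.path(run_dir, "report_blocks.csv")
  if (file.exists(bl_path)) {
    bl <- utils::read.csv(bl_path)
    expect_dir <- c(
      mean_nn_ms = -1, sdnn_ms = -1, rmssd_ms = -1, hf_power = -1,
      saccade_count = 1, fixation_count = 1, blink_count = 1, total_time_ms = 1
    )
    for (m in names(expect_dir)) {
      rows <- bl[bl$metric == m, ]
      if (nrow(rows) == 0) next
      ok <- sign(rows$mean1 - rows$mean0) == expect_dir[[m]]
      sign_checks[[m]] <- list(expected = unname(expect_dir[[m]]),
                               blocks_consistent = sum(ok), blocks = nrow(rows))
    }
  }
  out <- list(
    status = if (ari >= 0.9) "pass" else "check",
    ari = ari,
    cluster_sizes = as.list(table(merged$cluster)),
    sign_checks = sign_checks
  )
  jsonlite::write_json(out, file.path(run_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)
  out
}
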