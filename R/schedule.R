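#' Build a task schedule
#'
#' Encodes the trial lattice of the cognitive-load task: `n_blocks` blocks of
#' `n_levels` escalating difficulty levels with `n_trials` trials per level,
#' plus the set of (block, level) cells in which feedback is deceptive. The
#' defaults reproduce the study design: 3 blocks x 6 levels x 17 trials
#' (306 trials, 102 per block), with deceptive feedback in Block 2,
#' levels 3-6.
#'
#' Blocks and levels are 1-based throughout; trial indices are 0-based and
#' half-open so that slicing other signals is unambiguous. Inter-block breaks
#' are not part of the lattice: every analysis is per-trial or per-level.
#'
#' @param n_blocks Number of blocks (default 3).
#' @param n_levels Number of difficulty levels per block (default 6).
#' @param n_trials Number of trials per level (default 17).
#' @param deceptive_cells Two-column data frame or matrix of (block, level)
#'   pairs receiving deceptive feedback. Default: block 2, levels 3-6.
#' @return An object of class `task_schedule`: a list with the counts and a
#'   tibble of deceptive cells.
#' @examples
#' sched <- build_schedule()
#' total_trials(sched) # 306
#' @export
build_schedule <- function(n_blocks = 3L, n_levels = 6L, n_trials = 17L,
                           deceptive_cells = default_deceptive_cells()) {
  n_blocks <- as.integer(n_blocks)
  n_levels <- as.integer(n_levels)
  n_trials <- as.integer(n_trials)
  if (any(is.na(c(n_blocks, n_levels, n_trials))) ||
      n_blocks < 1L || n_levels < 1L || n_trials < 1L) {
    rlang::abort("n_blocks, n_levels and n_trials must all be >= 1")
  }
  dc <- as_deceptive_cells(deceptive_cells)
  if (nrow(dc) > 0L) {
    bad <- dc$block < 1L | dc$block > n_blocks | dc$level < 1L | dc$level > n_levels
    if (any(bad)) {
      rlang::abort(sprintf(
        "deceptive cell (%d, %d) lies outside the %d x %d lattice",
        dc$block[which(bad)[1]], dc$level[which(bad)[1]], n_blocks, n_levels
      ))
    }
  }
  structure(
    list(
      n_blocks = n_blocks,
      n_levels_per_block = n_levels,
      n_trials_per_level = n_trials,
      deceptive_cells = dc
    ),
    class = "task_schedule"
  )
}

#' @rdname build_schedule
#' @export
default_deceptive_cells <- function() {
  tibble::tibble(block = 2L, level = 3:6)
}

as_deceptive_cells <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) ||
      (is.matrix(x) && nrow(x) == 0L) || (is.atomic(x) && length(x) == 0L)) {
    return(tibble::tibble(block = integer(), level = integer()))
  }
  x <- as.data.frame(x)
  if (ncol(x) != 2L) rlang::abort("deceptive_cells must have two columns: block, level")
  names(x) <- c("block", "level")
  out <- tibble::tibble(block = as.integer(x$block), level = as.integer(x$level))
  dplyr::distinct(dplyr::arrange(out, .data$block, .data$level))
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf(
    "<task_schedule> %d blocks x %d levels x %d trials = %d trials (%d deceptive)\n",
    x$n_blocks, x$n_levels_per_block, x$n_trials_per_level,
    total_trials(x), sum(deceptive_trial_mask(x))
  ))
  invisible(x)
}

#' Total number of trials in a schedule
#' @param schedule A `task_schedule`.
#' @return Integer trial count.
#' @export
total_trials <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  schedule$n_blocks * schedule$n_levels_per_block * schedule$n_trials_per_level
}

#' Per-level trial windows
#'
#' Returns one row per (block, level) cell with the half-open 0-based trial
#' index window `[first_trial, last_trial)`. Windows are in (block, level)
#' lexicographic order and partition `[0, total_trials)`.
#'
#' @param schedule A `task_schedule`.
#' @return A tibble with columns `block`, `level`, `first_trial`,
#'   `last_trial`, `deceptive`.
#' @export
level_windows <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  nb <- schedule$n_blocks
  nl <- schedule$n_levels_per_block
  nt <- schedule$n_trials_per_level
  grid <- tidyr::expand_grid(block = seq_len(nb), level = seq_len(nl))
  idx <- seq_len(nrow(grid)) - 1L
  dc <- schedule$deceptive_cells
  dplyr::mutate(
    grid,
    first_trial = idx * nt,
    last_trial = (idx + 1L) * nt,
    deceptive = paste(.data$block, .data$level) %in% paste(dc$block, dc$level)
  )
}

#' Deceptive-feedback trial mask
#'
#' @param schedule A `task_schedule`.
#' @return Logical vector of length `total_trials(schedule)`, `TRUE` exactly
#'   on trials belonging to deceptive (block, level) cells.
#' @export
deceptive_trial_mask <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  win <- level_windows(schedule)
  mask <- logical(total_trials(schedule))
  for (i in which(win$deceptive)) {
    mask[(win$first_trial[i] + 1L):win$last_trial[i]] <- TRUE
  }
  mask
}

#' Schedule as a tidy per-trial table
#'
#' @param schedule A `task_schedule`.
#' @return Tibble with one row per trial: `trial` (0-based), `block`, `level`,
#'   `trial_in_level` (1-based), `deceptive`.
#' @export
schedule_table <- function(schedule) {
  win <- level_windows(schedule)
  nt <- schedule$n_trials_per_level
  tibble::tibble(
    trial = seq_len(total_trials(schedule)) - 1L,
    block = rep(win$block, each = nt),
    level = rep(win$level, each = nt),
    trial_in_level = rep(seq_len(nt), times = nrow(win)),
    deceptive = deceptive_trial_mask(schedule)
  )
}

#' Read/write a schedule as a config list
#'
#' `schedule_to_config()` returns a plain list suitable for YAML
#' serialization; `schedule_from_config()` inverts it.
#' @param schedule A `task_schedule`.
#' @return A list (`schedule_to_config`) or `task_schedule`
#'   (`schedule_from_config`).
#' @export
schedule_to_config <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  list(
    n_blocks = schedule$n_blocks,
    n_levels = schedule$n_levels_per_block,
    n_trials = schedule$n_trials_per_level,
    deceptive_cells = purrr::pmap(schedule$deceptive_cells, function(block, level) {
      list(block = block, level = level)
    })
  )
}

#' @rdname schedule_to_config
#' @param config A list as produced by `schedule_to_config()`.
#' @export
schedule_from_config <- function(config) {
  dc <- if (length(config$deceptive_cells) == 0L) {
    tibble::tibble(block = integer(), level = integer())
  } else {
    purrr::map_dfr(config$deceptive_cells, tibble::as_tibble)
  }
  build_schedule(config$n_blocks, config$n_levels, config$n_trials, dc)
}
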