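#' Cohen's d with confidence interval
#'
#' Standardized mean difference `(mean(x1) - mean(x0)) / s_pooled`, with the
#' pooled SD on `n0 + n1 - 2` degrees of freedom, and a normal-approximation
#' confidence interval based on the large-sample variance of d,
#' `(n0 + n1)/(n0 n1) + d^2 / (2 (n0 + n1 - 2))`.
#'
#' @param x0,x1 Numeric samples (cluster 0 and cluster 1); the sign is
#'   "cluster 1 relative to cluster 0".
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `d`, `d_lo`, `d_hi`.
#' @export
cohens_d <- function(x0, x1, conf_level = 0.95) {
  n0 <- length(x0)
  n1 <- length(x1)
  if (n0 < 2 || n1 < 2) rlang::abort("cohens_d needs >= 2 observations per group")
  sp2 <- ((n0 - 1) * stats::var(x0) + (n1 - 1) * stats::var(x1)) / (n0 + n1 - 2)
  if (sp2 <= 0) rlang::abort("pooled SD is zero; d undefined")
  d <- (mean(x1) - mean(x0)) / sqrt(sp2)
  se <- sqrt((n0 + n1) / (n0 * n1) + d^2 / (2 * (n0 + n1 - 2)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(d = d, d_lo = d - z * se, d_hi = d + z * se)
}

#' Rank-based effect sizes for two samples
#'
#' The normative definition is pairwise enumeration: CLES is the
#' probability that a random member of `x1` exceeds a random member of
#' `x0`, ties counted half; `RBC = 2 * CLES - 1`; and `U` is the
#' Mann-Whitney statistic in the same orientation
#' (`U = #(x1 > x0) + 0.5 * #(ties)`). Computed via midranks, which is
#' exactly equivalent.
#'
#' @param x0,x1 Numeric samples; orientation is "cluster 1 relative to
#'   cluster 0".
#' @return One-row tibble: `u_statistic`, `rbc`, `cles`.
#' @export
rank_effects <- function(x0, x1) {
  n0 <- length(x0)
  n1 <- length(x1)
  if (n0 < 1 || n1 < 1) rlang::abort("both samples must be non-empty")
  r <- rank(c(x0, x1))
  u1 <- sum(r[seq_len(n1) + n0]) - n1 * (n1 + 1) / 2
  cles <- u1 / (n0 * n1)
  tibble::tibble(u_statistic = u1, rbc = 2 * cles - 1, cles = cles)
}

#' Point-biserial correlation with Fisher-z confidence interval
#' @noRd
point_biserial <- function(x0, x1, conf_level = 0.95) {
  g <- c(rep(0, length(x0)), rep(1, length(x1)))
  v <- c(x0, x1)
  r <- stats::cor(g, v)
  n <- length(v)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(r = r, r_lo = tanh(z - q * se), r_hi = tanh(z + q * se))
}

#' Compare two groups with a normality-gated test
#'
#' Both samples are screened with Shapiro-Wilk at `alpha_normality`. If
#' both pass, a two-sided Student's t-test (pooled variance) is used,
#' reported with Cohen's d (and CI) and the point-biserial correlation
#' (and CI). Otherwise — or when a group is degenerate (all values
#' identical) — a two-sided Mann-Whitney U test is used, reported with the
#' rank-biserial correlation and the common-language effect size. All
#' effect sizes are oriented "cluster 1 relative to cluster 0". A Welch
#' test can be requested instead of the pooled-variance t.
#'
#' @param x0,x1 Numeric samples, `n >= 3` each (NAs dropped).
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @param welch Use Welch's t instead of Student's t on the parametric
#'   branch.
#' @param conf_level Confidence level for effect-size CIs.
#' @return One-row tibble (a comparison record): `n0`, `n1`, `test`,
#'   `statistic`, `p_value`, `d`, `d_lo`, `d_hi`, `r`, `r_lo`, `r_hi`,
#'   `rbc`, `cles`, `direction` (sign-convention note).
#' @export
compare_groups <- function(x0, x1, alpha_normality = 0.05, welch = FALSE,
                           conf_level = 0.95) {
  x0 <- x0[!is.na(x0)]
  x1 <- x1[!is.na(x1)]
  if (length(x0) < 3 || length(x1) < 3) {
    rlang::abort("compare_groups needs >= 3 observations per group")
  }
  degenerate <- stats::sd(x0) == 0 || stats::sd(x1) == 0
  normal <- FALSE
  if (!degenerate) {
    p0 <- stats::shapiro.test(x0)$p.value
    p1 <- stats::shapiro.test(x1)$p.value
    normal <- p0 > alpha_normality && p1 > alpha_normality
  }
  base <- tibble::tibble(
    n0 = length(x0), n1 = length(x1),
    direction = "effect sign: cluster 1 relative to cluster 0"
  )
  if (normal) {
    tt <- stats::t.test(x1, x0, var.equal = !welch)
    es <- cohens_d(x0, x1, conf_level)
    pb <- point_biserial(x0, x1, conf_level)
    dplyr::bind_cols(
      base[1:2],
      tibble::tibble(test = if (welch) "welch_t" else "student_t",
                     statistic = unname(tt$statistic), p_value = tt$p.value),
      es, pb,
      tibble::tibble(rbc = NA_real_, cles = NA_real_),
      base[3]
    )
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x1, x0, exact = FALSE,
                                              correct = FALSE))
    re <- rank_effects(x0, x1)
    dplyr::bind_cols(
      base[1:2],
      tibble::tibble(test = "mann_whitney",
                     statistic = re$u_statistic, p_value = wt$p.value),
      tibble::tibble(d = NA_real_, d_lo = NA_real_, d_hi = NA_real_,
                     r = NA_real_, r_lo = NA_real_, r_hi = NA_real_),
      re[c("rbc", "cles")],
      base[3]
    )
  }
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's statistic without continuity correction by default (Yates
#' available via `yates = TRUE`), df = 1. Errors on a zero margin.
#'
#' @param table 2x2 count matrix.
#' @param yates Apply Yates continuity correction.
#' @return One-row tibble: `chi2`, `p_value`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) rlang::abort("table must be 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    rlang::abort("zero margin: chi-square undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  tibble::tibble(chi2 = unname(ct$statistic), p_value = ct$p.value)
}

append_bh <- function(out) {
  if (nrow(out) == 0L || !"p_value" %in% names(out)) {
    return(dplyr::mutate(out, p_bh = numeric(nrow(out))))
  }
  out |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(p_bh = stats::p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup()
}

join_labels <- function(metrics, labels) {
  if (inherits(labels, "pupil_kmeans")) labels <- labels$labels
  if (!all(c("participant", "cluster") %in% names(labels))) {
    rlang::abort("labels needs columns participant, cluster")
  }
  dplyr::inner_join(metrics, labels, by = "participant")
}

compare_rows <- function(df, alpha_normality, min_coverage = 0.5) {
  split_vals <- split(df$value, df$cluster)
  x0 <- split_vals[["0"]]
  x1 <- split_vals[["1"]]
  n0_all <- sum(df$cluster == 0)
  n1_all <- sum(df$cluster == 1)
  if (is.null(x0) || is.null(x1) ||
      sum(!is.na(x0)) < max(3, min_coverage * n0_all) ||
      sum(!is.na(x1)) < max(3, min_coverage * n1_all)) {
    return(NULL)
  }
  res <- compare_groups(x0, x1, alpha_normality = alpha_normality)
  dplyr::bind_cols(
    tibble::tibble(mean0 = mean(x0, na.rm = TRUE), sd0 = stats::sd(x0, na.rm = TRUE),
                   mean1 = mean(x1, na.rm = TRUE), sd1 = stats::sd(x1, na.rm = TRUE)),
    res
  )
}

#' Per-level cluster comparison table
#'
#' One comparison per metric and (block, level) cell: cluster descriptive
#' statistics, the gated test, and effect sizes, mirroring a per-level
#' comparison table. Headline p-values are raw (uncorrected);
#' Benjamini-Hochberg adjusted values are appended per metric as a separate
#' column, never substituted. Rows where either cluster has fewer than 3
#' values, or is missing more than half its participants, are skipped with
#' a message.
#'
#' @param metrics Long metrics table (`participant`, `block`, `level`,
#'   `metric`, `value`).
#' @param labels Cluster labels (`pupil_kmeans` or tibble
#'   participant/cluster), aligned to the reporting convention.
#' @param alpha_normality Shapiro-Wilk gate level.
#' @return Tibble with one row per metric x (block, level), columns
#'   `metric`, `block`, `level`, descriptives, test fields, effect sizes,
#'   `p_bh`.
#' @export
report_levels <- function(metrics, labels, alpha_normality = 0.05) {
  joined <- join_labels(metrics, labels)
  out <- joined |>
    dplyr::group_by(.data$metric, .data$block, .data$level) |>
    dplyr::group_modify(function(df, key) {
      res <- compare_rows(df, alpha_normality)
      if (is.null(res)) {
        message(sprintf("report_levels: skipped %s block %s level %s (insufficient data)",
                        key$metric, key$block, key$level))
        return(tibble::tibble())
      }
      res
    }) |>
    dplyr::ungroup()
  append_bh(out)
}

#' Per-block cluster comparison table
#'
#' Each participant's block value is the mean of their per-level values
#' within the block; blocks are then compared with the same gated
#' machinery as [report_levels()].
#'
#' @inheritParams report_levels
#' @return Tibble with one row per metric x block.
#' @export
report_blocks <- function(metrics, labels, alpha_normality = 0.05) {
  block_vals <- metrics |>
    dplyr::group_by(.data$participant, .data$metric, .data$block) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  joined <- join_labels(block_vals, labels)
  out <- joined |>
    dplyr::group_by(.data$metric, .data$block) |>
    dplyr::group_modify(function(df, key) {
      res <- compare_rows(df, alpha_normality)
      if (is.null(res)) {
        message(sprintf("report_blocks: skipped %s block %s (insufficient data)",
                        key$metric, key$block))
        return(tibble::tibble())
      }
      res
    }) |>
    dplyr::ungroup()
  append_bh(out)
}

#' Per-cluster extreme segments ("peaking reactions")
#'
#' For every cluster and metric, locates the (block, level) cell where the
#' cluster mean attains its maximum and its minimum, and flags whether the
#' extremum falls on a deceptive-feedback cell. Ties return the earliest
#' segment in (block, level) order with `tie = TRUE`.
#'
#' @param metrics Long per-level metrics table.
#' @param labels Cluster labels.
#' @param schedule A `task_schedule` (for the deceptive cells).
#' @return Tibble: `cluster`, `metric`, `extremum` (max/min), `block`,
#'   `level`, `value`, `deceptive`, `tie`.
#' @export
peak_reactions <- function(metrics, labels, schedule) {
  joined <- join_labels(metrics, labels)
  dc <- schedule$deceptive_cells
  cell_means <- joined |>
    dplyr::group_by(.data$cluster, .data$metric, .data$block, .data$level) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::arrange(.data$cluster, .data$metric, .data$block, .data$level)
  pick <- function(df, which_ext) {
    v <- df$value
    idx <- if (which_ext == "max") which(v == max(v)) else which(v == min(v))
    row <- df[idx[1], ]
    tibble::tibble(
      extremum = which_ext, block = row$block, level = row$level,
      value = row$value,
      deceptive = paste(row$block, row$level) %in% paste(dc$block, dc$level),
      tie = length(idx) > 1
    )
  }
  cell_means |>
    dplyr::group_by(.data$cluster, .data$metric) |>
    dplyr::group_modify(~ dplyr::bind_rows(pick(.x, "max"), pick(.x, "min"))) |>
    dplyr::ungroup()
}

#' Questionnaire comparison between clusters
#'
#' Continuous questionnaire scores go through [compare_groups()]; binary
#' ones (e.g. smoking) through the 2x2 chi-square.
#'
#' @param questionnaires Tibble with `participant` and score columns.
#' @param labels Cluster labels.
#' @param binary Character vector naming the binary columns.
#' @return Tibble with one row per variable.
#' @export
compare_questionnaires <- function(questionnaires, labels,
                                   binary = "smoking") {
  joined <- join_labels(questionnaires, labels)
  vars <- setdiff(names(joined), c("participant", "cluster"))
  purrr::map_dfr(vars, function(v) {
    if (v %in% binary) {
      tab <- table(factor(joined$cluster, levels = 0:1),
                   factor(joined[[v]], levels = sort(unique(joined[[v]]))))
      if (any(dim(tab) != 2L) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        return(tibble::tibble(variable = v, test = "chi_square",
                              statistic = NA_real_, p_value = NA_real_))
      }
      cs <- chi_square_2x2(tab)
      tibble::tibble(variable = v, test = "chi_square",
                     statistic = cs$chi2, p_value = cs$p_value)
    } else {
      res <- compare_groups(joined[[v]][joined$cluster == 0],
                            joined[[v]][joined$cluster == 1])
      dplyr::bind_cols(tibble::tibble(variable = v), res["test"],
                       res[c("statistic", "p_value", "d", "rbc", "cles")])
    }
  })
}
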