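test_that("Cohen's d matches its definition and is antisymmetric", {
  # means one pooled SD apart -> d = 1
  x0 <- c(1, 2, 3, 4, 5)
  x1 <- x0 + stats::sd(x0)  # equal group SDs, so pooled SD = sd(x0)
  expect_equal(cohens_d(x0, x1)$d, 1.0, tolerance = 1e-12)
  set.seed(12)
  a <- stats::rnorm(20)
  b <- stats::rnorm(25, 0.8)
  d1 <- cohens_d(a, b)
  d2 <- cohens_d(b, a)
  expect_equal(d1$d, -d2$d, tolerance = 1e-12)
  expect_equal(d1$d_lo, -d2$d_hi, tolerance = 1e-12)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "zero")
})

test_that("d estimates recover a known standardized difference", {
  set.seed(77)
  dhat <- replicate(400, {
    cohens_d(stats::rnorm(50), stats::rnorm(50, 0.5))$d
  })
  expect_lt(abs(mean(dhat) - 0.5), 0.05)
})

test_that("rank effects equal pairwise enumeration, including ties", {
  expect_equal(rank_effects(1, 1)$cles, 0.5)
  expect_equal(rank_effects(1, 1)$rbc, 0)
  expect_equal(rank_effects(c(1, 2), c(3, 4)),
               tibble::tibble(u_statistic = 4, rbc = 1, cles = 1))
  set.seed(40)
  for (i in 1:300) {
    # integer draws force frequent ties
    x0 <- sample(1:6, sample(1:12, 1), replace = TRUE)
    x1 <- sample(1:6, sample(1:12, 1), replace = TRUE)
    got <- rank_effects(x0, x1)
    oracle <- rank_effects_oracle(x0, x1)
    expect_identical(got$cles, oracle$cles)
    expect_identical(got$u_statistic, oracle$u)
    expect_identical(got$rbc, 2 * got$cles - 1)
  }
})

test_that("gated comparison picks the right branch and orientation", {
  set.seed(50)
  x <- stats::rnorm(60)
  same <- compare_groups(x, x)
  expect_gt(same$p_value, 0.99)
  expect_lt(abs(same$d), 1e-9)
  expect_equal(same$test, "student_t")
  # complete separation: nonparametric effect sizes maxed
  re <- rank_effects(c(1, 2, 3), c(4, 5, 6))
  expect_equal(re$cles, 1)
  expect_equal(re$rbc, 1)
  # heavy-tailed data drop to the rank branch
  set.seed(51)
  skew <- compare_groups(stats::rexp(40)^2, stats::rexp(40)^2)
  expect_equal(skew$test, "mann_whitney")
  expect_true(is.na(skew$d))
  # degenerate constant group: forced nonparametric
  con <- compare_groups(rep(2, 10), stats::rnorm(10))
  expect_equal(con$test, "mann_whitney")
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("chi-square matches the closed form and its scale property", {
  flat <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)
  tab <- matrix(c(10, 20, 20, 10), 2)
  out <- chi_square_2x2(tab)
  # N(ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(out$chi2, 60 * (10 * 10 - 20 * 20)^2 / 30^4, tolerance = 1e-9)
  expect_equal(out$chi2, 6.667, tolerance = 1e-3)
  doubled <- chi_square_2x2(2 * tab)
  expect_equal(doubled$chi2, 2 * out$chi2, tolerance = 1e-9)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
  # Yates correction is available and shrinks the statistic
  expect_lt(chi_square_2x2(tab, yates = TRUE)$chi2, out$chi2)
})

make_metrics <- function(seed = 60, gap = 2) {
  # 12 participants, 2 blocks x 2 levels, one metric with a known group gap
  set.seed(seed)
  grid <- tidyr::expand_grid(participant = sprintf("P%02d", 1:12),
                             block = 1:2, level = 1:2)
  cl <- as.integer(sub("P", "", grid$participant)) > 6
  dplyr::mutate(grid, metric = "m",
                value = stats::rnorm(nrow(grid)) + gap * cl)
}

toy_labels <- tibble::tibble(participant = sprintf("P%02d", 1:12),
                             cluster = rep(0:1, each = 6))

test_that("level report detects a constructed group gap", {
  m <- make_metrics(gap = 3)
  rep_lv <- report_levels(m, toy_labels)
  expect_equal(nrow(rep_lv), 4L)
  expect_true(all(rep_lv$p_value < 0.05))
  expect_true(all(rep_lv$mean1 > rep_lv$mean0))
  expect_true(all(c("p_bh", "direction") %in% names(rep_lv)))
  # permuted labels: no systematic effect on a null metric
  m0 <- make_metrics(gap = 0)
  rep_null <- report_levels(m0, toy_labels)
  expect_true(mean(rep_null$p_value < 0.05) <= 0.5)
  # an all-missing metric is skipped with a message
  m_bad <- dplyr::bind_rows(m, dplyr::mutate(m, metric = "empty", value = NA_real_))
  expect_message(rep2 <- report_levels(m_bad, toy_labels), "skipped")
  expect_setequal(unique(rep2$metric), "m")
})

test_that("block report averages levels within participant first", {
  m <- make_metrics(gap = 3)
  rep_bl <- report_blocks(m, toy_labels)
  expect_equal(nrow(rep_bl), 2L)
  # block value of a constant per-level metric is that constant
  m_const <- dplyr::mutate(make_metrics(gap = 0), value = 7)
  joined <- m_const |>
    dplyr::group_by(participant, metric, block) |>
    dplyr::summarise(value = mean(value), .groups = "drop")
  expect_true(all(joined$value == 7))
})

test_that("peak reactions locate extrema and deception flags", {
  sched <- build_schedule()
  win <- level_windows(sched)
  # monotone increasing metric: max at (3, 6), min at (1, 1)
  mono <- tidyr::expand_grid(participant = c("A", "B"), win[c("block", "level")]) |>
    dplyr::mutate(metric = "mono", value = block * 10 + level)
  labs <- tibble::tibble(participant = c("A", "B"), cluster = 0:1)
  pk <- peak_reactions(mono, labs, sched)
  mx <- pk[pk$extremum == "max" & pk$cluster == 0, ]
  expect_equal(c(mx$block, mx$level), c(3L, 6L))
  expect_false(mx$deceptive)
  # constant metric: earliest segment with the tie flag
  const <- dplyr::mutate(mono, metric = "const", value = 1)
  pk <- peak_reactions(const, labs, sched)
  cmax <- pk[pk$extremum == "max" & pk$cluster == 1, ]
  expect_equal(c(cmax$block, cmax$level), c(1L, 1L))
  expect_true(cmax$tie)
  # archetype-1 pupil peak: (2, 3), flagged deceptive
  coh <- generate_cohort(sched, n_per_archetype = c(3L, 3L),
                         noise_config = default_noise(0), seed = 2,
                         channels = "pupil")
  traj <- trial_means(coh$trials, sched) |>
    normalize_trajectories() |>
    smooth_trajectories()
  pm <- pupil_level_metrics(traj, sched)
  labs2 <- dplyr::rename(coh$truth, cluster = "archetype")
  pk <- peak_reactions(pm, labs2, sched)
  arc1_max <- pk[pk$cluster == 1 & pk$extremum == "max", ]
  expect_equal(c(arc1_max$block, arc1_max$level), c(2L, 3L))
  expect_true(arc1_max$deceptive)
})

test_that("questionnaire comparisons use the right test per variable type", {
  set.seed(90)
  q <- tibble::tibble(
    participant = sprintf("P%02d", 1:20),
    ess = c(stats::rnorm(10, 10, 2), stats::rnorm(10, 7, 2)),
    smoking = stats::rbinom(20, 1, 0.5)
  )
  labs <- tibble::tibble(participant = sprintf("P%02d", 1:20),
                         cluster = rep(0:1, each = 10))
  out <- compare_questionnaires(q, labs)
  expect_equal(out$test[out$variable == "smoking"], "chi_square")
  expect_true(out$test[out$variable == "ess"] %in% c("student_t", "mann_whitney"))
})
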