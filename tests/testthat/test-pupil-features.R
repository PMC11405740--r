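toy_sched <- build_schedule(1, 2, 3, deceptive_cells = NULL)  # 6 trials

test_that("trial means average samples within trials", {
  samples <- tibble::tibble(
    participant = "P1",
    trial = c(0, 0, 0, 1:5),
    pupil_mm = c(2, 4, 6, 5, 4, 3, 2, 1)
  )
  traj <- trial_means(samples, toy_sched)
  expect_equal(unname(traj$values[1, ]), c(4, 5, 4, 3, 2, 1))
  expect_equal(traj$state, "raw")
})

test_that("piecewise-constant high-rate traces recover their trial constants", {
  # 500 Hz trace, constant within each trial
  constants <- c(3.1, 3.5, 2.9, 4.2, 3.8, 3.3)
  samples <- tibble::tibble(
    participant = "P1",
    trial = rep(0:5, each = 500),
    pupil_mm = rep(constants, each = 500)
  )
  traj <- trial_means(samples, toy_sched)
  expect_equal(unname(traj$values[1, ]), constants)
})

test_that("normalization z-scores per participant with population SD", {
  traj <- pupil_trajectories(matrix(c(1, 2, 3, 10, 20, 30), 2, byrow = TRUE))
  norm <- normalize_trajectories(traj)
  expect_equal(unname(rowMeans(norm$values)), c(0, 0), tolerance = 1e-12)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(unname(apply(norm$values, 1, pop_sd)), c(1, 1), tolerance = 1e-12)
  # affine invariance: a*x + b normalizes to the same vector as x (a > 0)
  x <- stats::rnorm(50)
  n1 <- normalize_trajectories(pupil_trajectories(rbind(x)))
  n2 <- normalize_trajectories(pupil_trajectories(rbind(2.7 * x + 13)))
  expect_equal(n1$values, n2$values, tolerance = 1e-10, ignore_attr = TRUE)
  # idempotence
  n3 <- normalize_trajectories(n1)
  expect_equal(n3$values, n1$values, tolerance = 1e-12)
  # constant vector: zero SD names the participant
  expect_error(
    normalize_trajectories(pupil_trajectories(matrix(5, 1, 10,
                                                     dimnames = list("P9", NULL)))),
    "P9"
  )
})

test_that("smoothing is a uniform moving average with shrinking edges", {
  const <- pupil_trajectories(matrix(2.5, 1, 306))
  sm <- smooth_trajectories(const, 17)
  expect_equal(unname(sm$values[1, ]), rep(2.5, 306), tolerance = 1e-12)
  # unit impulse at center: plateau of 1/17 over 17 interior positions
  imp <- numeric(306)
  imp[150] <- 1
  sm <- smooth_trajectories(pupil_trajectories(rbind(imp)), 17)
  expect_equal(unname(sm$values[1, 142:158]), rep(1 / 17, 17), tolerance = 1e-14)
  expect_equal(unname(sm$values[1, 141]), 0)
  expect_equal(unname(sm$values[1, 159]), 0)
  # linear ramp: interior values unchanged by a symmetric uniform kernel
  ramp <- seq_len(306)
  sm <- smooth_trajectories(pupil_trajectories(rbind(ramp)), 17)
  expect_equal(unname(sm$values[1, 9:298]), as.numeric(ramp[9:298]),
               tolerance = 1e-10)
  # interior kernel preserves the mean of a constant input exactly
  expect_error(smooth_trajectories(const, 0), ">= 1")
  expect_error(smooth_trajectories(const, 400), "longer")
})

test_that("missing trials are interpolated or the participant is dropped", {
  m <- matrix(stats::rnorm(4 * 100), 4, 100,
              dimnames = list(sprintf("P%d", 1:4), NULL))
  m[1, 50] <- NA          # sporadic: interpolated
  m[2, 1:20] <- NA        # 20% missing: dropped
  traj <- pupil_trajectories(m)
  expect_message(out <- impute_missing(traj), "P2")
  expect_equal(out$participants, c("P1", "P3", "P4"))
  expect_false(anyNA(out$values))
  expect_equal(unname(out$values[1, 50]), unname(mean(m[1, c(49, 51)])))
})

test_that("isolation forest flags a shape-flipped trajectory", {
  set.seed(3)
  base <- sin(seq(0, 4 * pi, length.out = 306))
  m <- t(replicate(30, base + stats::rnorm(306, 0, 0.05)))
  m <- rbind(m, -base)  # sign-flipped intruder
  rownames(m) <- sprintf("P%02d", 1:31)
  traj <- pupil_trajectories(m)
  scr <- screen_outliers(traj, contamination = 0.05, seed = 7)
  expect_equal(sum(scr$flagged), 2L)  # ceiling(0.05 * 31)
  expect_true(scr$flagged[scr$participant == "P31"])
  # determinism under the seed
  scr2 <- screen_outliers(traj, contamination = 0.05, seed = 7)
  expect_identical(scr, scr2)
  # contamination bounds
  expect_error(screen_outliers(traj, contamination = 0.6), "contamination")
  expect_error(screen_outliers(pupil_trajectories(m[1:5, ]), 0.05), ">= 10")
})
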