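# small cohorts and schedules shared across test files

default_sched <- build_schedule()

# pupil-only cohort at the study's size; pupil draws are invariant to the
# channel set by construction (verified in test-cohort.R)
pupil_cohort <- function(seed = 1L, n = c(33L, 37L), noise = default_noise()) {
  generate_cohort(default_sched, n_per_archetype = n, noise_config = noise,
                  seed = seed, channels = "pupil")
}

small_cohort <- function(seed = 1L, channels = c("pupil", "eye")) {
  generate_cohort(default_sched, n_per_archetype = c(6L, 6L), seed = seed,
                  channels = channels)
}

# exhaustive 2-cluster search: minimum inertia over all non-trivial splits
# (element 1 fixed to group a; codes enumerate membership of elements 2..n,
# including code 0 = element 1 alone)
brute_force_k2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 0:(2^(n - 1) - 2)) {
    grp <- c(TRUE, as.logical(bitwAnd(code, 2^(seq_len(n - 1) - 1))))
    a <- x[grp, , drop = FALSE]
    b <- x[!grp, , drop = FALSE]
    ina <- sum(sweep(a, 2, colMeans(a))^2)
    inb <- sum(sweep(b, 2, colMeans(b))^2)
    best <- min(best, ina + inb)
  }
  best
}

# pairwise-enumeration oracle for rank effects (ties counted half)
rank_effects_oracle <- function(x0, x1) {
  gt <- sum(outer(x1, x0, ">"))
  ties <- sum(outer(x1, x0, "=="))
  cles <- (gt + 0.5 * ties) / (length(x0) * length(x1))
  list(u = gt + 0.5 * ties, cles = cles, rbc = 2 * cles - 1)
}
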