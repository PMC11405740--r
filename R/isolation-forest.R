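# Isolation forest (Liu, Ting & Zhou 2008), as used to screen multivariate
# outliers among trajectory vectors. Scores in (0, 1); higher = more isolable.

# average unsuccessful-search path length in a BST of n points
iforest_c <- function(n) {
  if (n <= 1) return(0)
  h <- log(n - 1) + 0.5772156649015329
  2 * h - 2 * (n - 1) / n
}

iforest_build <- function(x, depth, height_limit) {
  n <- nrow(x)
  if (depth >= height_limit || n <= 1L) {
    return(list(external = TRUE, size = n))
  }
  # candidate attributes with spread; degenerate nodes become external
  rng <- apply(x, 2, range)
  ok <- which(rng[2, ] > rng[1, ])
  if (length(ok) == 0L) return(list(external = TRUE, size = n))
  q <- if (length(ok) == 1L) ok else sample(ok, 1L)
  p <- stats::runif(1, rng[1, q], rng[2, q])
  left <- x[, q] < p
  list(
    external = FALSE, attr = q, split = p,
    left = iforest_build(x[left, , drop = FALSE], depth + 1L, height_limit),
    right = iforest_build(x[!left, , drop = FALSE], depth + 1L, height_limit)
  )
}

iforest_path <- function(node, x, depth = 0) {
  if (node$external) return(depth + iforest_c(node$size))
  if (x[node$attr] < node$split) {
    iforest_path(node$left, x, depth + 1)
  } else {
    iforest_path(node$right, x, depth + 1)
  }
}

#' Isolation-forest anomaly scores
#'
#' @param x Numeric matrix, one observation per row.
#' @param n_trees Number of isolation trees.
#' @param sample_size Subsample size per tree (capped at `nrow(x)`).
#' @param seed Integer seed; scores are deterministic given the seed.
#' @return Numeric vector of anomaly scores in (0, 1), one per row.
#' @export
isolation_forest_scores <- function(x, n_trees = 100L, sample_size = 256L,
                                    seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  psi <- min(sample_size, n)
  height_limit <- ceiling(log2(max(psi, 2)))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(i) {
    idx <- sample.int(n, psi)
    iforest_build(x[idx, , drop = FALSE], 0L, height_limit)
  })
  mean_depth <- vapply(seq_len(n), function(i) {
    mean(vapply(trees, iforest_path, numeric(1), x = x[i, ]))
  }, numeric(1))
  2^(-mean_depth / iforest_c(psi))
}
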