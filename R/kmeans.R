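# k-means++ initial centroids
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

# squared Euclidean distances from every row of x to every centroid
dist2_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

lloyd_once <- function(x, k, max_iter, tol, init = c("kmeans++", "partition")) {
  init <- match.arg(init)
  if (init == "kmeans++") {
    centers <- kmeanspp_init(x, k)
  } else {
    # random-partition seeding: centroids of a uniformly random assignment
    # with every cluster non-empty; reaches Lloyd basins that no point-pair
    # seeding can enter
    lab <- sample(rep_len(seq_len(k), nrow(x)))
    centers <- t(vapply(seq_len(k), function(j) {
      colMeans(x[lab == j, , drop = FALSE])
    }, numeric(ncol(x))))
  }
  prev_inertia <- Inf
  labels <- integer(nrow(x))
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(nrow(x)), labels)])
    # Lloyd monotonicity: assignment + update can only decrease the objective
    stopifnot(inertia <= prev_inertia + 1e-8 * max(1, prev_inertia))
    new_centers <- centers
    shift <- 0
    for (j in seq_len(k)) {
      members <- labels == j
      if (!any(members)) {
        # empty cluster: reseed at the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(nrow(x)), labels)])
        new_centers[j, ] <- x[far, ]
      } else {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
      shift <- max(shift, sqrt(sum((new_centers[j, ] - centers[j, ])^2)))
    }
    centers <- new_centers
    if (shift < tol) break
    prev_inertia <- inertia
  }
  d2 <- dist2_to_centers(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  list(labels = labels, centers = centers, inertia = inertia, iter = iter)
}

#' Euclidean k-means over trajectory vectors
#'
#' Lloyd's algorithm run `n_init` times — odd restarts seeded with
#' k-means++, even restarts with the centroids of a uniformly random
#' partition (which can enter Lloyd basins no point seeding reaches) — and
#' the restart with the lowest within-cluster sum of squared Euclidean
#' distances (inertia) is kept. Inertia is asserted non-increasing at every
#' Lloyd iteration; an empty cluster is reseeded at the point farthest from
#' its current centroid.
#'
#' @param x A `pupil_trajectories` object or numeric matrix (rows =
#'   participants).
#' @param k Number of clusters (default 2).
#' @param n_init Number of k-means++ restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Centroid-shift convergence threshold (Euclidean norm).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return An object of class `pupil_kmeans`: `labels` (tibble participant /
#'   cluster, 0-based cluster indices), `centroids` (k x trials matrix),
#'   `inertia`, `k`, `n_init`, `seed`, `aligned` flag.
#' @export
kmeans_fit <- function(x, k = 2L, n_init = 25L, max_iter = 300L,
                       tol = 1e-6, seed = 1L) {
  if (inherits(x, "pupil_trajectories")) {
    participants <- x$participants
    x <- x$values
  } else {
    x <- as.matrix(x)
    participants <- rownames(x) %||% sprintf("P%03d", seq_len(nrow(x)))
  }
  if (anyNA(x) || any(!is.finite(x))) rlang::abort("vectors must be finite")
  k <- as.integer(k)
  if (nrow(x) < k) rlang::abort("need at least k vectors")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- lloyd_once(x, k, max_iter, tol,
                      init = if (r %% 2 == 0) "partition" else "kmeans++")
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(
    list(
      labels = tibble::tibble(participant = participants,
                              cluster = best$labels - 1L),
      centroids = best$centers,
      inertia = best$inertia,
      k = k, n_init = n_init, seed = seed,
      n_iter = best$iter,
      aligned = FALSE
    ),
    class = "pupil_kmeans"
  )
}

#' @export
print.pupil_kmeans <- function(x, ...) {
  cat(sprintf("<pupil_kmeans> k = %d, n = %d, inertia = %.4g%s\n",
              x$k, nrow(x$labels), x$inertia,
              if (x$aligned) ", labels aligned" else ""))
  print(dplyr::count(x$labels, .data$cluster))
  invisible(x)
}

#' Align two-cluster labels to the reporting convention
#'
#' Cluster 0 is defined as the cluster whose centroid has the larger mean
#' over the Block 1, Level 1 trial window — the "high initial pupil size"
#' phenotype. Exact ties fall back to ordering by inertia contribution, with
#' a warning.
#'
#' @param result A `pupil_kmeans` with `k = 2`.
#' @param schedule The `task_schedule` the trajectories follow.
#' @param x Optional trajectory matrix / `pupil_trajectories`; only needed
#'   to break an exact start-window tie by per-cluster inertia contribution.
#' @return The `pupil_kmeans` with labels (and centroids) possibly swapped
#'   and `aligned = TRUE`.
#' @export
align_labels <- function(result, schedule, x = NULL) {
  stopifnot(inherits(result, "pupil_kmeans"), inherits(schedule, "task_schedule"))
  if (result$k != 2L) rlang::abort("label alignment is defined for k = 2")
  win <- level_windows(schedule)
  w <- win[win$block == 1L & win$level == 1L, ]
  idx <- (w$first_trial + 1L):w$last_trial
  start_means <- rowMeans(result$centroids[, idx, drop = FALSE])
  if (start_means[1] == start_means[2]) {
    rlang::warn("start-window centroid means tied; ordering clusters by inertia contribution")
    if (!is.null(x)) {
      mat <- if (inherits(x, "pupil_trajectories")) x$values else as.matrix(x)
      d2 <- dist2_to_centers(mat, result$centroids)
      contrib <- vapply(0:1, function(cl) {
        sum(d2[result$labels$cluster == cl, cl + 1L])
      }, numeric(1))
      swap <- contrib[1] > contrib[2]
    } else {
      swap <- FALSE
    }
  } else {
    swap <- start_means[2] > start_means[1]
  }
  if (swap) {
    result$labels$cluster <- 1L - result$labels$cluster
    result$centroids <- result$centroids[2:1, , drop = FALSE]
  }
  result$aligned <- TRUE
  result
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions,
#' ~0 for independent ones.
#'
#' @param labels,truth Vectors of equal length (any label coding).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand <- function(labels, truth) {
  if (length(labels) != length(truth)) rlang::abort("length mismatch")
  tab <- table(labels, truth)
  n <- length(labels)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Silhouette width by number of clusters
#'
#' Reporting aid for choosing `k`; computes the mean silhouette width of
#' k-means fits over a range of `k`. Never auto-selects: the default
#' analysis fixes `k = 2`.
#'
#' @param x A `pupil_trajectories` or matrix.
#' @param ks Candidate cluster counts.
#' @param seed Seed passed to each fit.
#' @return Tibble with `k`, `inertia`, `mean_silhouette`.
#' @export
silhouette_by_k <- function(x, ks = 2:6, seed = 1L) {
  mat <- if (inherits(x, "pupil_trajectories")) x$values else as.matrix(x)
  d <- as.matrix(stats::dist(mat))
  purrr::map_dfr(ks, function(k) {
    fit <- kmeans_fit(mat, k = k, seed = seed)
    cl <- fit$labels$cluster
    sil <- vapply(seq_len(nrow(mat)), function(i) {
      own <- cl == cl[i]
      a <- if (sum(own) > 1) mean(d[i, own & seq_len(nrow(mat)) != i]) else 0
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(o) mean(d[i, cl == o]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    tibble::tibble(k = k, inertia = fit$inertia, mean_silhouette = mean(sil))
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a k-means clustering of trajectories
#'
#' @param x A `pupil_kmeans`.
#' @param ... Unused.
#' @return One row per participant: `participant`, `cluster`.
#' @method tidy pupil_kmeans
#' @export
tidy.pupil_kmeans <- function(x, ...) x$labels

#' One-row model summary of a k-means clustering
#'
#' @param x A `pupil_kmeans`.
#' @param ... Unused.
#' @return Tibble with `k`, `n`, `inertia`, `n_init`, `n_iter`, `seed`,
#'   `aligned`.
#' @method glance pupil_kmeans
#' @export
glance.pupil_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$labels), inertia = x$inertia,
                 n_init = x$n_init, n_iter = x$n_iter, seed = x$seed,
                 aligned = x$aligned)
}

#' Write clustering outputs to disk
#'
#' Labels CSV, centroid matrix CSV, and a JSON run manifest (seed, n_init,
#' inertia, k).
#'
#' @param result A `pupil_kmeans`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_clustering <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$centroids),
                   file.path(dir, "centroids.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k = result$k, seed = result$seed, n_init = result$n_init,
         inertia = result$inertia, aligned = result$aligned),
    file.path(dir, "clustering_manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
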