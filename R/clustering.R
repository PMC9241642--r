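#' Spearman rank-correlation distance between metabolite trajectories
#'
#' Distance between two features is `1 - |rs|`, with `rs` the Spearman rank
#' correlation between their time-course summaries (average-rank tie
#' handling). Taking the absolute value groups trajectories that co-vary in
#' either direction, and ranking makes the distance invariant to any
#' strictly monotone transform of a trajectory, so clustering is unaffected
#' by log transformation or per-feature scaling.
#'
#' @param summary features x time points matrix, typically from
#'   [summarize_timepoints()] (at least 3 columns).
#' @return symmetric distance matrix in [0, 1] with zero diagonal. Features
#'   that are constant across all time points have undefined correlation;
#'   they are assigned distance 1 to all partners, with a warning.
#' @examples
#' m <- rbind(a = 1:4, b = c(1, 3, 2, 4))
#' spearman_distance_matrix(m) # d(a, b) = 0.2
#' @export
spearman_distance_matrix <- function(summary) {
  if (!is.matrix(summary) || ncol(summary) < 3)
    stopf("need a feature x time-point matrix with >= 3 time points")
  const <- apply(summary, 1, function(x) stats::sd(x, na.rm = TRUE) == 0)
  if (any(const))
    warnf("%d constant feature(s) have undefined rank correlation; assigned distance 1",
          sum(const))
  rs <- suppressWarnings(stats::cor(t(summary), method = "spearman"))
  d <- 1 - abs(rs)
  d[is.na(d)] <- 1
  # numerical guard: clamp tiny negatives from |rs| marginally above 1
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(summary), rownames(summary))
  d
}

#' Hierarchical clustering of metabolite trajectories
#'
#' Agglomerative clustering on a Spearman trajectory distance matrix,
#' cut into `k` clusters. Average linkage (UPGMA) is the default pairing
#' for correlation-type distances; complete and single linkage are
#' available. Merging is deterministic for a given input order.
#'
#' @param dist symmetric distance matrix from [spearman_distance_matrix()].
#' @param k number of clusters to cut (default 10).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an object of class `trajectory_clusters`: list with the `hclust`
#'   tree, `k`, and `assignment` (named integer vector, feature -> cluster).
#' @export
hierarchical_cluster <- function(dist, k = 10, linkage = "average") {
  linkage <- match.arg(linkage, c("average", "complete", "single"))
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stopf("`dist` must be a square distance matrix")
  n <- nrow(dist)
  if (k < 1) stopf("`k` must be >= 1")
  if (k > n) stopf("cannot cut %d features into %d clusters", n, k)
  tree <- stats::hclust(stats::as.dist(dist), method = linkage)
  assignment <- stats::cutree(tree, k = k)
  structure(list(tree = tree, k = k, assignment = assignment),
            class = "trajectory_clusters")
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("Trajectory clustering: %d features in %d clusters (%s linkage)\n",
              length(x$assignment), x$k, x$tree$method))
  cat("  sizes:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = " "),
      "\n")
  invisible(x)
}

#' Phase-wise log rate of abundance change
#'
#' For each feature and each phase transition (uninfected to early, early to
#' middle, middle to late), the log (base 2 by default, so +1 means the mean
#' abundance doubled) of the ratio of the phase mean to the previous phase
#' mean. Nonpositive phase means are replaced by half the feature's minimum
#' positive phase mean before taking ratios; a feature with no positive
#' phase mean at all gets `NA` across the row.
#'
#' @param phase_means features x 4 phase matrix from [summarize_phases()],
#'   columns in order uninfected, early, middle, late.
#' @param log_base logarithm base (default 2).
#' @return features x 3 matrix with columns `uninfected_to_early`,
#'   `early_to_middle`, `middle_to_late`.
#' @export
rate_of_change <- function(phase_means, log_base = 2) {
  expect <- c("uninfected", "early", "middle", "late")
  if (!is.matrix(phase_means) || ncol(phase_means) != 4 ||
      !identical(colnames(phase_means), expect))
    stopf("`phase_means` must have the 4 phase columns in order: %s",
          paste(expect, collapse = ", "))
  filled <- t(apply(phase_means, 1, function(m) {
    bad <- !is.finite(m) | m <= 0
    if (any(bad)) {
      pos <- m[is.finite(m) & m > 0]
      m[bad] <- if (length(pos)) min(pos) / 2 else NA_real_
    }
    m
  }))
  out <- log(filled[, 2:4, drop = FALSE] / filled[, 1:3, drop = FALSE],
             base = log_base)
  colnames(out) <- c("uninfected_to_early", "early_to_middle",
                     "middle_to_late")
  rownames(out) <- rownames(phase_means)
  out
}

#' Per-cluster summary of phase rate-of-change profiles
#'
#' @param clusters a [hierarchical_cluster()] result.
#' @param changes the features x transitions matrix from [rate_of_change()];
#'   feature ids must match the clustering.
#' @return list with `by_cluster` (data frame: cluster, n_features, mean log
#'   rate per transition, and a direction pattern such as `"down-down-up"`),
#'   `n_late_increase` / `pct_late_increase`: how many features (and what
#'   percentage, rounded) have a positive middle-to-late change.
#' @export
cluster_report <- function(clusters, changes) {
  stopifnot(inherits(clusters, "trajectory_clusters"))
  feats <- names(clusters$assignment)
  if (!setequal(feats, rownames(changes)))
    stopf("cluster assignment and change matrix must share feature ids")
  changes <- changes[feats, , drop = FALSE]
  ids <- sort(unique(clusters$assignment))
  by_cluster <- do.call(rbind, lapply(ids, function(cl) {
    sub <- changes[clusters$assignment == cl, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    data.frame(cluster = cl, n_features = nrow(sub),
               mean_uninfected_to_early = mu[1],
               mean_early_to_middle = mu[2],
               mean_middle_to_late = mu[3],
               pattern = paste(ifelse(mu >= 0, "up", "down"), collapse = "-"))
  }))
  rownames(by_cluster) <- NULL
  pos <- sum(changes[, "middle_to_late"] > 0, na.rm = TRUE)
  list(by_cluster = by_cluster,
       n_late_increase = pos,
       pct_late_increase = round_half_up(100 * pos / nrow(changes), 0))
}
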