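#' Shortest-path (geodesic-approximating) distances between samples
#'
#' Builds the complete graph on the samples with edges weighted by squared
#' Euclidean distance and returns all-pairs shortest-path lengths. Squaring
#' breaks the triangle inequality for straight-line hops, so paths through
#' intermediate samples can be shorter than direct edges; the resulting
#' metric approximates distance travelled through the point cloud and
#' separates points lying in distinct subspaces even when the subspaces
#' touch.
#'
#' @param coords numeric matrix, samples x dimensions.
#' @return symmetric numeric matrix of shortest-path lengths with zero
#'   diagonal.
#' @export
geodesicDistances <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  if (nrow(coords) < 2) stop("need at least 2 points")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  W <- as.matrix(stats::dist(coords))^2
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(D) <- dimnames(W)
  # exact symmetry (Dijkstra is run per source; tidy up fp noise)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

# assignment step: nearest medoid in geodesic distance, ties to the lowest
# medoid index
.assignToMedoids <- function(D, medoids) {
  A <- D[, medoids, drop = FALSE]
  max.col(-A, ties.method = "first")
}

# medoid update per the printed k-medoids rule: the data point (within the
# cluster) nearest in Euclidean distance to the Euclidean mean of the
# cluster
.updateMedoids <- function(coords, labels, k) {
  vapply(seq_len(k), function(c) {
    idx <- which(labels == c)
    ctr <- colMeans(coords[idx, , drop = FALSE])
    d2 <- colSums((t(coords[idx, , drop = FALSE]) - ctr)^2)
    idx[which.min(d2)]
  }, 0L)
}

.withinCost <- function(D, labels, medoids) {
  sum(D[cbind(seq_along(labels), medoids[labels])])
}

#' Geodesic k-medoids clustering
#'
#' Partitions samples into `k` clusters using the shortest-path distances
#' from [geodesicDistances()] for the assignment step and the data point
#' nearest (Euclidean) to the cluster mean as the medoid. Runs
#' `nRestarts` seeded random initializations and keeps the partition with
#' the lowest total within-cluster geodesic cost.
#'
#' @param D symmetric distance matrix from [geodesicDistances()].
#' @param coords numeric matrix, samples x dimensions (used for the medoid
#'   update rule).
#' @param k number of clusters, `1 <= k <= nrow(coords)`.
#' @param nRestarts random restarts (default 20).
#' @param seed integer seed; the run is deterministic given it.
#' @param maxIter iteration cap per restart (default 100).
#' @return list with `labels` (integer vector in 1..k), `medoids`
#'   (sample indices), `cost` (total within-cluster geodesic distance),
#'   and `costTrace` (per-iteration cost of the winning restart).
#' @export
kmedoidsCluster <- function(D, coords, k, nRestarts = 20, seed = 1L,
                            maxIter = 100) {
  s <- nrow(D)
  if (k < 1 || k > s) stop("k must be in [1, number of samples]")
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  stopifnot(nrow(coords) == s)
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(nRestarts)) {
      medoids <- sort(sample.int(s, k))
      labels <- .assignToMedoids(D, medoids)
      trace <- numeric()
      for (it in seq_len(maxIter)) {
        # refill clusters emptied by the assignment step with the point
        # whose minimum geodesic distance to the current medoids is largest
        for (c in which(tabulate(labels, k) == 0)) {
          far <- which.max(apply(D[, medoids, drop = FALSE], 1, min))
          medoids[c] <- far
          labels <- .assignToMedoids(D, medoids)
        }
        medoids <- .updateMedoids(coords, labels, k)
        newLabels <- .assignToMedoids(D, medoids)
        trace <- c(trace, .withinCost(D, newLabels, medoids))
        if (all(newLabels == labels)) { labels <- newLabels; break }
        labels <- newLabels
      }
      cost <- .withinCost(D, labels, medoids)
      if (is.null(best) || cost < best$cost - 1e-12) {
        best <- list(labels = labels, medoids = medoids, cost = cost,
                     costTrace = trace)
      }
    }
  })
  best
}

#' Scan cluster counts by cluster-size balance
#'
#' For each candidate `k`, repeats the seeded clustering `nReps` times and
#' reports the mean (over repetitions) variance of the cluster sizes. A low
#' size variance indicates a balanced, stable partition; the scan supports
#' an empirical choice of `k` and imposes no automatic selection.
#'
#' @param D,coords as in [kmedoidsCluster()].
#' @param kRange integer vector of candidate cluster counts.
#' @param nReps clustering repetitions per `k` (default 5).
#' @param seed integer seed.
#' @param nRestarts restarts per repetition (default 5).
#' @return data.frame with columns `k` and `meanSizeVariance`.
#' @export
scanClusterCounts <- function(D, coords, kRange, nReps = 5, seed = 1L,
                              nRestarts = 5) {
  repSeeds <- withr::with_seed(as.integer(seed),
                               sample.int(.Machine$integer.max - 1,
                                          nReps * length(kRange)))
  res <- data.frame(k = integer(), meanSizeVariance = numeric())
  i <- 0
  for (k in kRange) {
    v <- numeric(nReps)
    for (r in seq_len(nReps)) {
      i <- i + 1
      cl <- kmedoidsCluster(D, coords, k, nRestarts = nRestarts,
                            seed = repSeeds[i])
      sizes <- tabulate(cl$labels, k)
      v[r] <- if (k > 1) stats::var(sizes) else 0
    }
    res <- rbind(res, data.frame(k = k, meanSizeVariance = mean(v)))
  }
  res
}
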