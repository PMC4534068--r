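#' Match two vertex sets by minimum-cost assignment
#'
#' Finds the permutation of `otherK`'s rows minimizing the total Euclidean
#' distance to the rows of `refK` (the assignment problem), used to align
#' bootstrap replicates before averaging. Solved exactly by depth-first
#' branch and bound with a per-row lower bound.
#'
#' @param refK,otherK numeric matrices with equal vertex counts.
#' @return integer permutation `perm` such that `otherK[perm, ]` aligns
#'   row-wise with `refK`.
#' @export
matchVertexSets <- function(refK, otherK) {
  if (is.null(dim(refK))) refK <- matrix(refK, nrow = 1)
  if (is.null(dim(otherK))) otherK <- matrix(otherK, nrow = 1)
  if (nrow(refK) != nrow(otherK)) stop("vertex counts differ")
  m <- nrow(refK)
  C <- matrix(0, m, m)
  for (i in seq_len(m)) {
    C[i, ] <- sqrt(colSums((t(otherK) - refK[i, ])^2))
  }
  .assignmentBB(C)
}

# exact assignment: rows of C assigned to distinct columns minimizing total
# cost; branch and bound with remaining-row minima as the bound
.assignmentBB <- function(C) {
  m <- nrow(C)
  rowMin <- apply(C, 1, min)
  best <- list(cost = Inf, perm = integer(m))
  used <- rep(FALSE, ncol(C))
  perm <- integer(m)
  recurse <- function(i, acc) {
    if (i > m) {
      if (acc < best$cost - 1e-15) best <<- list(cost = acc, perm = perm)
      return(invisible())
    }
    bound <- if (i < m) sum(rowMin[(i + 1):m]) else 0
    ord <- order(C[i, ])
    for (j in ord) {
      if (used[j]) next
      if (acc + C[i, j] + bound >= best$cost - 1e-15) {
        if (C[i, j] + bound >= best$cost) break
        next
      }
      used[j] <<- TRUE
      perm[i] <<- j
      recurse(i + 1, acc + C[i, j])
      used[j] <<- FALSE
    }
  }
  recurse(1L, 0)
  best$perm
}

#' Bootstrap replicates of a simplex fit
#'
#' Resamples the cluster's points with replacement (`B` replicates, same
#' size), refits the simplex on each replicate independently (so the
#' replicate spread reflects the full fitting pipeline, including the
#' data-driven initialization), aligns each replicate's vertices to the
#' first by [matchVertexSets()], and summarizes per-vertex mean positions
#' and positional standard deviations (root of the summed per-dimension
#' bootstrap variances).
#'
#' @param X numeric matrix, points x dimensions.
#' @param m number of vertices.
#' @param cfg an [objectiveConfig()].
#' @param B number of replicates (default 10).
#' @param seed integer seed.
#' @return a [BootstrapEnsemble-class].
#' @export
bootstrapSimplex <- function(X, m, cfg = objectiveConfig(), B = 10,
                             seed = 1L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  n <- nrow(X)
  if (n < m) stop("cluster smaller than requested vertex count")
  if (B < 2) stop("need at least 2 bootstrap replicates")
  idxList <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
  })
  reps <- list()
  for (b in seq_len(B)) {
    fit <- tryCatch(fitSimplex(X[idxList[[b]], , drop = FALSE], m, cfg),
                    error = function(e) {
                      warning("bootstrap replicate ", b, " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit)) reps[[length(reps) + 1]] <- fit@K
  }
  if (length(reps) < 2) stop("fewer than 2 bootstrap replicates succeeded")
  for (b in seq_along(reps)[-1]) {
    perm <- matchVertexSets(reps[[1]], reps[[b]])
    reps[[b]] <- reps[[b]][perm, , drop = FALSE]
  }
  arr <- simplify2array(reps)                   # m x d x B
  # componentwise median: a robust location for the replicate vertices
  # (an occasional replicate stuck in a poor local optimum would otherwise
  # drag the plain mean); the spread summary keeps the full variance so
  # such replicates still widen the merge tolerance
  vertexMean <- apply(arr, c(1, 2), stats::median)
  perDimVar <- apply(arr, c(1, 2), stats::var)
  vertexSd <- sqrt(rowSums(perDimVar))
  new("BootstrapEnsemble", replicateK = reps, vertexMean = vertexMean,
      vertexSd = vertexSd, B = length(reps))
}

#' Bootstrap the clustering-plus-fitting inference jointly
#'
#' Resamples the full sample set with replacement and reruns the whole
#' per-replicate inference: geodesic k-medoids clustering, then one
#' simplex fit per cluster. Replicate clusters are matched to the
#' reference clustering by sample overlap (assignment problem) and
#' replicate vertices to the reference fit by [matchVertexSets()]. The
#' resulting per-vertex spreads therefore include the variability of the
#' cluster boundaries -- the dominant uncertainty for vertices shared
#' between subsimplices, which a within-cluster resample cannot see.
#'
#' @param P numeric matrix, samples x reduced dimensions.
#' @param k number of clusters.
#' @param mPerCluster integer vector (length k) of vertex counts.
#' @param cfg an [objectiveConfig()].
#' @param B bootstrap replicates (default 10).
#' @param seed integer seed.
#' @param nRestarts k-medoids restarts for the reference clustering;
#'   replicates use `max(5, nRestarts %/% 4)`.
#' @param refLabels optional reference cluster labels (integer vector) to
#'   reuse; computed when `NULL`.
#' @return list with `labels` (reference clustering) and `ensembles` (one
#'   [BootstrapEnsemble-class] per cluster).
#' @export
bootstrapPipeline <- function(P, k, mPerCluster, cfg = objectiveConfig(),
                              B = 10, seed = 1L, nRestarts = 20,
                              refLabels = NULL) {
  n <- nrow(P)
  mPerCluster <- rep_len(as.integer(mPerCluster), k)
  if (B < 2) stop("need at least 2 bootstrap replicates")
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1, 2 * B + 1))
  if (is.null(refLabels)) {
    D <- geodesicDistances(P)
    refLabels <- kmedoidsCluster(D, P, k, nRestarts = nRestarts,
                                 seed = seeds[2 * B + 1])$labels
  }
  refK <- lapply(seq_len(k), function(c) {
    fitSimplex(P[refLabels == c, , drop = FALSE], mPerCluster[c], cfg)@K
  })
  repK <- lapply(seq_len(k), function(c) list())
  for (b in seq_len(B)) {
    idx <- withr::with_seed(seeds[b], sample.int(n, n, replace = TRUE))
    Pb <- P[idx, , drop = FALSE]
    fitOne <- function() {
      Db <- geodesicDistances(Pb)
      lb <- kmedoidsCluster(Db, Pb, k, nRestarts = max(5, nRestarts %/% 4),
                            seed = seeds[B + b])$labels
      # match replicate clusters to reference clusters by sample overlap
      O <- matrix(0, k, k)
      for (c0 in seq_len(k)) {
        for (cb in seq_len(k)) {
          O[c0, cb] <- sum(refLabels[idx] == c0 & lb == cb)
        }
      }
      perm <- .assignmentBB(max(O) - O)
      out <- vector("list", k)
      for (c0 in seq_len(k)) {
        Xc <- Pb[lb == perm[c0], , drop = FALSE]
        if (nrow(Xc) < mPerCluster[c0]) stop("replicate cluster too small")
        fit <- fitSimplex(Xc, mPerCluster[c0], cfg)
        vperm <- matchVertexSets(refK[[c0]], fit@K)
        out[[c0]] <- fit@K[vperm, , drop = FALSE]
      }
      out
    }
    res <- tryCatch(fitOne(), error = function(e) {
      warning("bootstrap replicate ", b, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      for (c0 in seq_len(k)) repK[[c0]][[length(repK[[c0]]) + 1]] <- res[[c0]]
    }
  }
  ensembles <- lapply(seq_len(k), function(c0) {
    reps <- repK[[c0]]
    if (length(reps) < 2) stop("fewer than 2 bootstrap replicates succeeded")
    arr <- simplify2array(reps)
    vertexMean <- apply(arr, c(1, 2), stats::median)
    perDimVar <- apply(arr, c(1, 2), stats::var)
    new("BootstrapEnsemble", replicateK = reps,
        vertexMean = vertexMean, vertexSd = sqrt(rowSums(perDimVar)),
        B = length(reps))
  })
  list(labels = refLabels, ensembles = ensembles)
}

#' Are two vertices indistinct?
#'
#' Two bootstrap-summarized vertices are merged when their Euclidean
#' distance does not exceed the sum of their positional standard
#' deviations (boundary inclusive, so exactly coincident zero-sd vertices
#' merge). Symmetric in its arguments.
#'
#' @param v1,v2 numeric vectors, vertex mean positions.
#' @param sd1,sd2 nonnegative scalars, positional standard deviations.
#' @return logical.
#' @export
shouldMerge <- function(v1, sd1, v2, sd2) {
  stopifnot(is.finite(v1), is.finite(v2), sd1 >= 0, sd2 >= 0)
  sqrt(sum((v1 - v2)^2)) <= sd1 + sd2
}

#' Merge per-cluster simplices into a simplicial complex
#'
#' Evaluates [shouldMerge()] over every pair of vertices, both across and
#' within clusters, takes connected components of the indistinct relation,
#' and replaces each component by a single merged vertex (position: mean of
#' members; sd: max of members). Subsimplex index sets are remapped onto
#' the merged vertices; merged vertices are ordered canonically by
#' coordinates so the result does not depend on cluster input order.
#'
#' @param ensembles list of [BootstrapEnsemble-class] objects, one per
#'   cluster.
#' @return a [SimplicialComplex-class].
#' @export
buildComplex <- function(ensembles) {
  if (!length(ensembles)) stop("need at least one ensemble")
  means <- do.call(rbind, lapply(ensembles, function(e) e@vertexMean))
  sds <- unlist(lapply(ensembles, function(e) e@vertexSd))
  clus <- rep(seq_along(ensembles),
              vapply(ensembles, function(e) nrow(e@vertexMean), 0L))
  vtx <- unlist(lapply(ensembles,
                       function(e) seq_len(nrow(e@vertexMean))))
  nV <- nrow(means)
  adj <- matrix(FALSE, nV, nV)
  for (i in seq_len(nV)) {
    for (j in seq_len(nV)) {
      if (j > i && shouldMerge(means[i, ], sds[i], means[j, ], sds[j])) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  nM <- max(comp)
  pos <- t(vapply(seq_len(nM), function(c) {
    colMeans(means[comp == c, , drop = FALSE])
  }, numeric(ncol(means))))
  if (ncol(means) == 1) pos <- matrix(pos, ncol = 1)
  sdM <- vapply(seq_len(nM), function(c) max(sds[comp == c]), 0)
  # canonical order: lexicographic by coordinates, for input-order
  # invariance
  ord <- do.call(order, as.data.frame(pos))
  rank <- integer(nM)
  rank[ord] <- seq_len(nM)
  pos <- pos[ord, , drop = FALSE]
  sdM <- sdM[ord]
  merged <- rank[comp]
  sub <- lapply(seq_along(ensembles), function(c) {
    s <- sort(unique(merged[clus == c]))
    if (length(s) < 2) {
      warning("subsimplex ", c,
              " collapsed to a single shared vertex after merging")
    }
    s
  })
  mergeMap <- data.frame(cluster = clus, vertex = vtx, merged = merged)
  new("SimplicialComplex", vertices = pos, vertexSd = sdM,
      subsimplices = sub, mergeMap = mergeMap)
}

#' MST phylogeny over a simplicial complex
#'
#' Builds the minimum spanning tree over the merged vertex positions with
#' Euclidean edge weights (Kruskal with ties broken by lexicographic
#' vertex-id pair) and reads it as a tree of ancestral relationships among
#' the inferred cell populations.
#'
#' @param cx a [SimplicialComplex-class].
#' @return a [PhylogenyTree-class]; a single-vertex complex yields a
#'   single-node tree with no edges.
#' @export
mstPhylogeny <- function(cx) {
  pos <- cx@vertices
  n <- nrow(pos)
  ids <- paste0("v", seq_len(n))
  if (n < 2) {
    return(new("PhylogenyTree", nodes = ids,
               edges = data.frame(from = character(), to = character(),
                                  length = numeric())))
  }
  pairs <- t(utils::combn(n, 2))
  len <- sqrt(rowSums((pos[pairs[, 1], , drop = FALSE] -
                         pos[pairs[, 2], , drop = FALSE])^2))
  ord <- order(len, pairs[, 1], pairs[, 2])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- data.frame(from = character(), to = character(),
                      length = numeric())
  for (e in ord) {
    a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
    if (a != b) {
      parent[a] <- b
      edges <- rbind(edges, data.frame(from = ids[pairs[e, 1]],
                                       to = ids[pairs[e, 2]],
                                       length = len[e]))
      if (nrow(edges) == n - 1) break
    }
  }
  new("PhylogenyTree", nodes = ids, edges = edges)
}

#' Serialize a phylogeny as Newick
#'
#' Roots the (unrooted) MST at its highest-degree vertex (ties broken by
#' lowest id) and writes a Newick string with MST edge lengths as branch
#' lengths.
#'
#' @param tree a [PhylogenyTree-class].
#' @param path optional file to write to.
#' @return the Newick string, invisibly when `path` is given.
#' @export
writeNewick <- function(tree, path = NULL) {
  nodes <- tree@nodes
  e <- tree@edges
  if (!nrow(e)) {
    s <- paste0(nodes[1], ";")
  } else {
    deg <- table(factor(c(e$from, e$to), levels = nodes))
    root <- nodes[which.max(deg)]
    adj <- lapply(stats::setNames(nodes, nodes), function(x) {
      rbind(e[e$from == x, c("to", "length")],
            stats::setNames(e[e$to == x, c("from", "length")],
                            c("to", "length")))
    })
    rec <- function(node, from) {
      nb <- adj[[node]]
      nb <- nb[nb$to != from, , drop = FALSE]
      if (!nrow(nb)) return(node)
      kids <- vapply(seq_len(nrow(nb)), function(i) {
        paste0(rec(nb$to[i], node), ":", format(nb$length[i], digits = 10))
      }, "")
      paste0("(", paste(kids, collapse = ","), ")", node)
    }
    s <- paste0(rec(root, ""), ";")
  }
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
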