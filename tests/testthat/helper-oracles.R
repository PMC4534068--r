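# Independent oracles, deliberately written with different algorithms than
# the implementation they check.

# all-pairs shortest paths by Floyd-Warshall on the complete graph with
# squared-Euclidean edge weights
fwGeodesicOracle <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  D <- as.matrix(dist(coords))^2
  n <- nrow(D)
  for (l in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, l] + D[l, j] < D[i, j]) D[i, j] <- D[i, l] + D[l, j]
      }
    }
  }
  D
}

# minimum spanning tree length by enumerating all spanning trees (via
# edge-subset enumeration with a connectivity check); feasible for m <= 5
mstEnumOracle <- function(K) {
  m <- nrow(K)
  W <- as.matrix(dist(K))
  pairs <- t(combn(m, 2))
  ne <- nrow(pairs)
  best <- Inf
  for (mask in 0:(2^ne - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(ne) - 1)) > 0)
    if (length(sel) != m - 1) next
    # connectivity via repeated relaxation
    comp <- seq_len(m)
    for (rep in seq_len(m)) {
      for (e in sel) {
        a <- pairs[e, 1]; b <- pairs[e, 2]
        mn <- min(comp[a], comp[b])
        comp[a] <- mn; comp[b] <- mn
        comp[comp == max(comp[a], comp[b])] <- mn
      }
    }
    if (length(unique(comp)) == 1) {
      best <- min(best, sum(W[pairs[sel, , drop = FALSE]]))
    }
  }
  best
}

# exact assignment by enumerating all permutations (m <= 6)
assignmentEnumOracle <- function(C) {
  m <- nrow(C)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  bestCost <- Inf
  for (p in perms(seq_len(m))) {
    cost <- sum(C[cbind(seq_len(m), p)])
    if (cost < bestCost - 1e-15) { bestCost <- cost; best <- p }
  }
  list(perm = best, cost = bestCost)
}

# residual of the best simplex-constrained fraction vector found on a
# dense grid with the given step (2 or 3 vertices)
gridFractionOracle <- function(K, x, step = 0.01) {
  m <- nrow(K)
  if (m == 2) {
    a <- seq(0, 1, step)
    G <- cbind(a, 1 - a)
  } else if (m == 3) {
    g <- expand.grid(a = seq(0, 1, step), b = seq(0, 1, step))
    g <- g[g$a + g$b <= 1 + 1e-12, ]
    G <- cbind(g$a, g$b, 1 - g$a - g$b)
  } else {
    stop("grid oracle supports 2 or 3 vertices")
  }
  min(colSums((t(G %*% K) - x)^2))
}
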