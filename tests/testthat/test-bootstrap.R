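test_that("vertex matching recovers shuffles and beats greedy pairings", {
  set.seed(10)
  K <- matrix(rnorm(12), 4, 3)
  perm <- c(3, 1, 4, 2)
  expect_equal(matchVertexSets(K, K[perm, ]), order(perm))

  # 2 x 2 case with an attractive wrong pairing
  ref <- rbind(0, 10)
  oth <- rbind(1, 11)   # costs: 1/11 vs 9/... optimal is the diagonal
  expect_equal(matchVertexSets(matrix(ref), matrix(oth)), c(1, 2))

  expect_equal(matchVertexSets(matrix(1, 1, 1), matrix(2, 1, 1)), 1)
  expect_error(matchVertexSets(matrix(0, 2, 2), matrix(0, 3, 2)), "differ")
})

test_that("assignment equals permutation enumeration for m <= 6", {
  set.seed(12)
  for (m in c(2, 4, 6)) {
    C <- matrix(runif(m * m), m, m)
    got <- simplicialUnmix:::.assignmentBB(C)
    oracle <- assignmentEnumOracle(C)
    expect_equal(sum(C[cbind(seq_len(m), got)]), oracle$cost,
                 tolerance = 1e-12)
  }
})

test_that("bootstrap replicates of a clean triangle agree tightly", {
  K <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- sampleSimplex(K, 150, seed = 21)
  ens <- bootstrapSimplex(X, 3, objectiveConfig(tol = 1e-4), B = 5,
                          seed = 33)
  expect_equal(ens@B, 5L)
  # zero noise: positional sd well under 5 percent of the data scale
  scale <- max(dist(X))
  expect_true(all(ens@vertexSd < 0.05 * scale))
  # the ensemble centre sits near the true corners
  perm <- matchVertexSets(K, ens@vertexMean)
  expect_lt(max(abs(ens@vertexMean[perm, ] - K)), 0.05 * scale)

  expect_error(bootstrapSimplex(X, 3, B = 1), "at least 2")
})

test_that("identical replicates collapse to zero positional sd", {
  e <- fakeEnsemble(rbind(c(0, 0), c(1, 1)), c(0, 0))
  expect_true(validObject(e))
  expect_equal(vertexSd(e), c(0, 0))
})

test_that("the merge rule compares distance with summed sds, boundary inclusive", {
  expect_true(shouldMerge(c(0, 0), 0.6, c(1, 0), 0.5))    # 1 <= 1.1
  expect_false(shouldMerge(c(0, 0), 0.4, c(2, 0), 0.6))   # 2 > 1
  expect_true(shouldMerge(c(1, 2), 0, c(1, 2), 0))        # equality merges
  expect_equal(shouldMerge(c(0, 0), 0.3, c(1, 0), 0.6),
               shouldMerge(c(1, 0), 0.6, c(0, 0), 0.3))   # symmetric
})

test_that("complex building merges shared structure and remaps subsimplices", {
  # two triangles whose nearest vertex pair is within summed sds: a
  # point-joined complex of 5 vertices, the shared one in both index sets
  t1 <- rbind(c(0, 0), c(10, 0), c(0, 10))
  t2 <- rbind(c(0.5, 0.2), c(-10, 0), c(0, -10))
  cx <- buildComplex(list(fakeEnsemble(t1, c(0.4, 0.4, 0.4)),
                          fakeEnsemble(t2, c(0.4, 0.4, 0.4))))
  expect_equal(nrow(vertices(cx)), 5)
  expect_equal(length(intersect(subsimplices(cx)[[1]],
                                subsimplices(cx)[[2]])), 1)
  # merged position is the member mean, sd the member max
  shared <- intersect(subsimplices(cx)[[1]], subsimplices(cx)[[2]])
  expect_equal(as.numeric(vertices(cx)[shared, ]), c(0.25, 0.1))

  # two close vertex pairs: 4 vertices sharing an edge
  t3 <- rbind(c(0.3, 0), c(10.2, 0.1), c(5, -10))
  cxE <- buildComplex(list(fakeEnsemble(t1, c(0.3, 0.3, 0.3)),
                           fakeEnsemble(t3, c(0.3, 0.3, 0.3))))
  expect_equal(nrow(vertices(cxE)), 4)
  expect_equal(length(intersect(subsimplices(cxE)[[1]],
                                subsimplices(cxE)[[2]])), 2)

  # nothing within tolerance: disjoint union
  t4 <- t2 + 100
  cxD <- buildComplex(list(fakeEnsemble(t1, c(0.1, 0.1, 0.1)),
                           fakeEnsemble(t4, c(0.1, 0.1, 0.1))))
  expect_equal(nrow(vertices(cxD)), 6)
  expect_equal(length(intersect(subsimplices(cxD)[[1]],
                                subsimplices(cxD)[[2]])), 0)

  # merge map is total and single-valued
  mm <- cx@mergeMap
  expect_equal(nrow(mm), 6)
  expect_false(anyDuplicated(mm[, c("cluster", "vertex")]) > 0)
})

test_that("complex building warns when a subsimplex collapses", {
  t1 <- rbind(c(0, 0), c(1, 0))
  t2 <- rbind(c(0.1, 0), c(0.9, 0))
  w <- capture_warnings(
    cx <- buildComplex(list(fakeEnsemble(t1, c(2, 2)),
                            fakeEnsemble(t2, c(2, 2)))))
  expect_true(any(grepl("collapsed", w)))
})

test_that("complex building is invariant to cluster input order", {
  set.seed(31)
  e1 <- fakeEnsemble(matrix(rnorm(6), 3, 2), c(0.2, 0.2, 0.2))
  e2 <- fakeEnsemble(matrix(rnorm(6), 3, 2) + 3, c(0.2, 0.2, 0.2))
  a <- buildComplex(list(e1, e2))
  b <- buildComplex(list(e2, e1))
  expect_lt(max(abs(vertices(a) - vertices(b))), 1e-10)
  expect_equal(subsimplices(a)[[1]], subsimplices(b)[[2]])
})

test_that("the MST phylogeny spans merged vertices with Euclidean lengths", {
  cx <- new("SimplicialComplex",
            vertices = matrix(c(0, 1, 3), 3, 1), vertexSd = rep(0, 3),
            subsimplices = list(1:3),
            mergeMap = data.frame(cluster = 1, vertex = 1:3, merged = 1:3))
  tr <- mstPhylogeny(cx)
  expect_equal(nrow(tr@edges), 2)
  expect_setequal(paste(tr@edges$from, tr@edges$to),
                  c("v1 v2", "v2 v3"))
  expect_equal(sum(tr@edges$length), 3)

  # two vertices: the single edge
  cx2 <- new("SimplicialComplex",
             vertices = rbind(c(0, 0), c(3, 4)), vertexSd = c(0, 0),
             subsimplices = list(1:2),
             mergeMap = data.frame(cluster = 1, vertex = 1:2, merged = 1:2))
  tr2 <- mstPhylogeny(cx2)
  expect_equal(tr2@edges$length, 5)
})

test_that("the phylogeny MST length matches vegan's spanning tree", {
  skip_if_not_installed("vegan")
  set.seed(17)
  V <- matrix(rnorm(14), 7, 2)
  cx <- new("SimplicialComplex", vertices = V, vertexSd = rep(0, 7),
            subsimplices = list(1:7),
            mergeMap = data.frame(cluster = 1, vertex = 1:7, merged = 1:7))
  tr <- mstPhylogeny(cx)
  sp <- vegan::spantree(dist(V))
  expect_equal(sum(tr@edges$length), sum(sp$dist), tolerance = 1e-10)
})

test_that("Newick serialization round-trips through ape", {
  skip_if_not_installed("ape")
  set.seed(23)
  V <- matrix(rnorm(10), 5, 2)
  cx <- new("SimplicialComplex", vertices = V, vertexSd = rep(0, 5),
            subsimplices = list(1:5),
            mergeMap = data.frame(cluster = 1, vertex = 1:5, merged = 1:5))
  tr <- mstPhylogeny(cx)
  nwk <- writeNewick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_equal(sort(ph$tip.label),
               sort(setdiff(tr@nodes, c(ph$node.label))))
  expect_equal(sum(ph$edge.length), sum(tr@edges$length),
               tolerance = 1e-8)
})
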