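test_that("vertex RMSD is zero up to permutation and scales with offsets", {
  set.seed(14)
  C <- matrix(rnorm(20), 4, 5)
  r <- vertexRMSD(C, C)
  expect_equal(r$rmsd, 0)
  expect_equal(r$matching, 1:4)

  # every coordinate off by 0.5 gives RMSD exactly 0.5
  r2 <- vertexRMSD(C[1, , drop = FALSE] + 0.5, C[1, , drop = FALSE])
  expect_equal(r2$rmsd, 0.5)

  # shuffled truth: matching recovers the order
  perm <- c(3, 1, 4, 2)
  r3 <- vertexRMSD(C[perm, ], C)
  expect_equal(r3$rmsd, 0, tolerance = 1e-12)
  expect_equal(r3$matching, perm)

  # surplus estimated vertices are reported, not scored
  r4 <- vertexRMSD(rbind(C, C[1, ] + 100), C)
  expect_equal(r4$nMatched, 4)
  expect_equal(r4$nVerticesEst, 5)
  expect_equal(r4$rmsd, 0, tolerance = 1e-12)
  expect_error(vertexRMSD(C, matrix(0, 0, 5)), "empty")
})

test_that("fraction RMSD covers both normalizations and unmatched mass", {
  set.seed(15)
  Ct <- matrix(rnorm(3 * 40), 3, 40)
  F <- matrix(rgamma(3 * 8, 1), 3, 8)
  F <- sweep(F, 2, colSums(F), "/")
  expect_equal(fractionRMSD(F, F, 1:3, mode = "fractions"), 0)
  expect_equal(fractionRMSD(F, F, 1:3, Ctrue = Ct), 0)

  # single sample, two components swapped: reconstruction error d/sqrt(g)
  C2 <- rbind(rep(0, 16), rep(0, 16))
  C2[2, 1] <- 3                                  # rows at distance 3
  Fe <- matrix(c(1, 0), 2, 1)
  Ft <- matrix(c(0, 1), 2, 1)
  got <- fractionRMSD(Fe, Ft, 1:2, Ctrue = C2)
  expect_equal(got, 3 / sqrt(16))

  # permuted components score zero once the matching is applied
  perm <- c(2, 3, 1)
  expect_equal(fractionRMSD(F[perm, ], F, perm, mode = "fractions"), 0)

  # unmatched estimated component with usage triggers a warning
  expect_warning(
    fractionRMSD(rbind(F, 0.5), rbind(F[1:2, ], F[3, ] * 0.5),
                 c(1, 2, 3, NA), mode = "fractions"),
    "unmatched")
})

test_that("the Gaussian-mixture baseline finds blob centres and normalized responsibilities", {
  set.seed(16)
  X <- rbind(matrix(rnorm(100, sd = 0.2), 50, 2),
             matrix(rnorm(100, sd = 0.2), 50, 2) + 5)
  g <- gmmBaseline(X, 2, seed = 1)
  centers <- rbind(colMeans(X[1:50, ]), colMeans(X[51:100, ]))
  perm <- matchVertexSets(centers, g$means)
  expect_lt(max(abs(g$means[perm, ] - centers)), 0.1)
  expect_equal(rowSums(g$responsibilities), rep(1, 100))

  # k = 1: the mean is the sample mean exactly
  g1 <- gmmBaseline(X, 1)
  expect_equal(as.numeric(g1$means), colMeans(X))
  expect_error(gmmBaseline(X, 200), "exceed")
})

test_that("the chi-squared association test matches the hand computation", {
  a <- rep(c("x", "y"), each = 20)
  out <- contingencyChiSq(a, a)
  expect_equal(out$statistic, 40)                # n for a perfect 2x2
  expect_equal(out$df, 1)
  expect_lt(out$p.value, 0.001)

  # under independence the rejection rate stays near the nominal level
  set.seed(18)
  ps <- replicate(200, {
    contingencyChiSq(sample(c("a", "b"), 200, TRUE),
                     sample(c("u", "v"), 200, TRUE))$p.value
  })
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)

  expect_warning(
    expect_error(contingencyChiSq(factor(rep("a", 10), levels = c("a", "z")),
                                  rep(c("u", "v"), 5)),
                 "at least 2"),
    "zero-margin")
  expect_error(contingencyChiSq(1:3, 1:4), "length")
})

test_that("the single-simplex baseline passes its configuration through", {
  K <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
  X <- sampleSimplex(K, 80, seed = 3)
  fit <- singleSimplexBaseline(X, 4, objectiveConfig(maxIter = 5))
  expect_s4_class(fit, "SimplexModel")
  expect_equal(nrow(fit@F), 4)
  expect_equal(ncol(fit@F), 80)
  fv <- singleSimplexBaseline(X[, 1:2], 3, objectiveConfig(penalty = "volume",
                                                           maxIter = 5))
  expect_equal(fv@penalty, "volume")
})
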