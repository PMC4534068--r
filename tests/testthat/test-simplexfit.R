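test_that("vertex-count heuristic follows the eigenvalue spectrum", {
  seg <- cbind(seq(0, 1, length.out = 30), 0, 0) +
    matrix(rnorm(90, sd = 1e-4), 30)
  expect_equal(estimateNumVertices(seg), 2L)

  tri <- sampleSimplex(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)), 60)
  expect_equal(estimateNumVertices(tri), 3L)

  tet <- sampleSimplex(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
                             c(0, 0, 10)), 120, seed = 3)
  expect_equal(estimateNumVertices(tet, threshold = 0.05), 4L)

  expect_warning(m1 <- estimateNumVertices(matrix(1, 5, 3)), "degenerate")
  expect_equal(m1, 1L)
  expect_error(estimateNumVertices(matrix(0, 2, 3)), "at least 3")
})

test_that("the initializer recovers canonical enclosing simplices", {
  # the three corners alone are their own minimal enclosing simplex
  K <- rbind(c(0, 0), c(1, 0), c(0, 1))
  K0 <- mvesInit(K, 3)
  perm <- matchVertexSets(K, K0)
  expect_lt(max(abs(K0[perm, ] - K)), 1e-8)

  # dense uniform segment: endpoints within 0.05
  seg <- matrix(seq(0, 1, length.out = 120), ncol = 1)
  e <- sort(as.numeric(mvesInit(seg, 2)))
  expect_lt(max(abs(e - c(0, 1))), 0.05)

  # collinear points cannot support a triangle
  expect_error(mvesInit(cbind(1:20, 2 * (1:20)), 3), "affine")
})

test_that("fraction solving reproduces barycentric coordinates and hull projections", {
  K <- rbind(c(0, 0), c(1, 0), c(0, 1))
  # interior point: exact barycentric coordinates
  f <- solveFractions(K, matrix(c(0.25, 0.25), 1))
  expect_equal(as.numeric(f), c(0.5, 0.25, 0.25), tolerance = 1e-8)
  # a vertex maps to a unit vector
  f2 <- solveFractions(K, K)
  expect_equal(unname(f2), diag(3), tolerance = 1e-8)
  # point outside a 1-D simplex projects to the nearest vertex
  f3 <- solveFractions(matrix(c(0, 1), 2, 1), matrix(-1, 1, 1))
  expect_equal(as.numeric(f3), c(1, 0))
  # columns live on the probability simplex
  set.seed(2)
  X <- matrix(runif(40, -1, 2), 20, 2)
  F <- solveFractions(K, X)
  expect_true(all(F >= 0))
  expect_equal(colSums(F), rep(1, 20))
})

test_that("no dense-grid fraction vector beats the solver", {
  set.seed(5)
  for (K in list(matrix(c(0, 1), 2, 1),
                 rbind(c(0, 0), c(1, 0), c(0, 1)),
                 rbind(c(0, 0), c(2, 1), c(-1, 1)))) {
    X <- matrix(runif(2 * 15 * ncol(K), -1, 2), ncol = ncol(K))
    F <- solveFractions(K, X)
    for (j in seq_len(nrow(X))) {
      got <- sum((X[j, ] - as.numeric(t(K) %*% F[, j]))^2)
      grid <- gridFractionOracle(K, X[j, ])
      expect_lt(got, grid + 1e-3)
    }
  }
})

test_that("MST length matches spanning-tree enumeration", {
  expect_equal(mstLength(rbind(c(0, 0), c(1, 0), c(0, 1))), 2)
  expect_equal(mstLength(matrix(c(0, 1, 3), 3, 1)), 3)
  # coincident pair plus one vertex at distance 1
  expect_equal(mstLength(rbind(c(0, 0), c(0, 0), c(1, 0))), 1)
  set.seed(6)
  for (m in 3:5) {
    K <- matrix(rnorm(m * 3), m, 3)
    expect_equal(mstLength(K), mstEnumOracle(K), tolerance = 1e-12)
  }
  expect_error(mstLength(matrix(0, 1, 2)), "fewer than 2")
})

test_that("simplex volume uses the Gram determinant in the affine span", {
  expect_equal(simplexVolume(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(simplexVolume(matrix(c(0, 1), 2, 1)), 1)
  expect_equal(simplexVolume(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
  # embedding in higher dimension leaves the volume unchanged
  expect_equal(simplexVolume(cbind(rbind(c(0, 0), c(1, 0), c(0, 1)), 5)), 0.5)
})

test_that("the objective decomposes into residual and log-penalty terms", {
  K <- rbind(c(0, 0), c(1, 0), c(0, 1))
  X <- sampleSimplex(K, 50, seed = 9)
  F <- solveFractions(K, X)
  cfg <- objectiveConfig(gamma = 10)
  o <- evaluateObjective(K, F, X, cfg)
  expect_equal(o$residualTerm, 0, tolerance = 1e-8)
  expect_equal(o$objective, 10 * log(2), tolerance = 1e-6)

  o0 <- evaluateObjective(K, F, X, objectiveConfig(gamma = 0))
  expect_equal(o0$objective, o0$residualTerm)

  ov <- evaluateObjective(K, F, X, objectiveConfig(gamma = 1,
                                                   penalty = "volume"))
  expect_equal(ov$penaltyTerm, log(0.5), tolerance = 1e-10)

  Kdeg <- rbind(c(0, 0), c(0, 0), c(0, 0))
  expect_error(evaluateObjective(Kdeg, F, X, cfg), "degenerate")
})

test_that("fitting attains zero objective on noiseless enclosed data with gamma 0", {
  seg <- matrix(seq(0, 1, length.out = 80), ncol = 1)
  fit <- fitSimplex(seg, 2, objectiveConfig(gamma = 0, maxIter = 100))
  expect_lt(fit@objective, 1e-6)
  expect_lt(max(abs(sort(as.numeric(fit@K)) - c(0, 1))), 0.05)
})

test_that("maxIter = 0 returns the initialization and the trace is monotone", {
  K <- rbind(c(0, 0), c(1, 0), c(0, 1))
  X <- sampleSimplex(K, 60, seed = 4) +
    matrix(rnorm(120, sd = 0.05), 60, 2)
  f0 <- fitSimplex(X, 3, objectiveConfig(maxIter = 0))
  expect_equal(f0@nIter, 0L)
  expect_false(f0@converged)
  expect_equal(unname(f0@K), unname(mvesInit(X, 3)))

  fit <- fitSimplex(X, 3, objectiveConfig())
  tr <- attr(fit, "objectiveTrace")
  expect_true(all(diff(tr) < 1e-8))
  expect_equal(fit@objective, fit@residualTerm + fit@gamma * fit@penaltyTerm,
               tolerance = 1e-8)
  # F columns on the simplex
  expect_true(min(fit@F) >= -1e-9)
  expect_lt(max(abs(colSums(fit@F) - 1)), 1e-6)
})

test_that("stronger MST regularization never lengthens the fitted tree", {
  X <- matrix(c(seq(0, 1, length.out = 60)), ncol = 1)
  lens <- vapply(c(0, 5, 20, 100), function(g) {
    mstLength(fitSimplex(X, 2, objectiveConfig(gamma = g))@K)
  }, 0)
  expect_true(all(diff(lens) < 1e-6))
})

test_that("summed MST penalties of separate clusters share one scale", {
  # a segment (1-simplex) and a triangle (2-simplex): both penalties are
  # log-lengths, so the complex-level score is a plain sum of finite terms
  seg <- cbind(seq(0, 2, length.out = 50), 0)
  tri <- sampleSimplex(rbind(c(5, 5), c(7, 5), c(5, 8)), 80, seed = 2)
  f1 <- fitSimplex(seg, 2, objectiveConfig())
  f2 <- fitSimplex(tri, 3, objectiveConfig())
  expect_true(is.finite(f1@penaltyTerm) && is.finite(f2@penaltyTerm))
  expect_lt(abs(f1@penaltyTerm - f2@penaltyTerm), 10)
  total <- f1@objective + f2@objective
  expect_true(is.finite(total))
})
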