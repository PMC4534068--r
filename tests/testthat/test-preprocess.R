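test_that("expression matrices load with ids preserved in either orientation", {
  f <- system.file("extdata", "mini_expression.tsv",
                   package = "simplicialUnmix")
  M <- readExpressionMatrix(f)
  expect_equal(dim(M), c(3, 4))
  expect_equal(rownames(M), c("TP53", "BRCA1", "ERBB2"))
  expect_equal(colnames(M), c("s1", "s2", "s3", "s4"))
  expect_equal(M["TP53", "s3"], 3)

  Mt <- readExpressionMatrix(f, orientation = "samples_by_genes")
  expect_equal(Mt, t(M))

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(gene = rownames(M), M, check.names = FALSE), csv,
            row.names = FALSE, quote = FALSE)
  expect_equal(readExpressionMatrix(csv), M)
})

test_that("loading rejects duplicates, non-numeric cells, and empty input", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3", "TP53\t1\t2\t3", "TP53\t4\t5\t6",
               "EGFR\t1\t1\t2"), bad)
  expect_error(readExpressionMatrix(bad), "TP53")

  nn <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3", "TP53\t1\tx\t3", "EGFR\t1\t1\t2"), nn)
  expect_error(readExpressionMatrix(nn), "non-numeric")

  empty <- tempfile(fileext = ".tsv")
  writeLines("gene\ts1", empty)
  expect_error(readExpressionMatrix(empty), "empty")

  expect_error(readExpressionMatrix(tempfile()), "not found")
})

test_that("Z-scoring yields mean 0 / sd 1 rows, applies the constant-gene policy, and is idempotent", {
  M <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 8, 5))
  Z <- zscoreGenes(M, constantGenePolicy = "drop")
  expect_equal(unname(Z["a", ]), c(-1, 0, 1))
  expect_equal(nrow(Z), 2)            # constant row dropped
  expect_equal(attr(Z, "dropped"), "b")
  expect_true(all(abs(rowMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 1, sd) - 1) < 1e-10))

  Z0 <- zscoreGenes(M, constantGenePolicy = "zero")
  expect_equal(nrow(Z0), 3)
  expect_equal(unname(Z0["b", ]), c(0, 0, 0))

  # idempotence
  Z2 <- zscoreGenes(Z)
  expect_lt(max(abs(Z2 - Z)), 1e-8)

  expect_error(zscoreGenes(M[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("PCA recovers exact low-rank structure and fixed axis signs", {
  # points on a 2-D plane inside 5-D space: full recovery with 2 components
  set.seed(42)
  B <- matrix(rnorm(10), 2, 5)
  S <- matrix(rnorm(40), 20, 2)
  Z <- t(S %*% B)                      # 5 genes x 20 samples
  R <- pcaReduce(Z, 2)
  expect_lt(max(abs(backProject(R@coords, R) - t(Z))), 1e-8)

  # full rank: total explained variance equals total variance
  Zr <- matrix(rnorm(5 * 12), 5, 12)
  Rf <- pcaReduce(Zr, 5)
  expect_lt(abs(sum(Rf@explainedVariance) -
                  sum(apply(t(Zr), 2, var))), 1e-8)

  # axis-aligned rectangle with sides 2 (x) and 1 (y): one component,
  # scores at -1/+1 along the long axis (covariance eigenvalues 4/3, 1/3)
  rect <- cbind(c(-1, -0.5), c(-1, 0.5), c(1, -0.5), c(1, 0.5))
  R1 <- pcaReduce(rect, 1)
  expect_equal(sort(unname(R1@coords[, 1])), c(-1, -1, 1, 1),
               tolerance = 1e-10)
  # sign convention: the dominant loading is positive
  expect_gt(R1@basis[1, which.max(abs(R1@basis[1, ]))], 0)

  expect_error(pcaReduce(Zr, 12), "nComponents")
})

test_that("back-projection inverts the reduction on in-span points", {
  set.seed(7)
  Z <- matrix(rnorm(30 * 15), 30, 15)
  R <- pcaReduce(Z, 4)
  # reduced-space origin maps to the offset
  expect_equal(as.numeric(backProject(rep(0, 4), R)), unname(R@offset))
  # round-trip project -> backproject -> project is a fixed point
  v <- matrix(rnorm(8), 2, 4)
  g <- backProject(v, R)
  expect_lt(max(abs(projectReduced(g, R) - v)), 1e-8)
  # full-rank round-trip is the identity on the data
  Rf <- pcaReduce(Z, 14)
  expect_lt(max(abs(backProject(Rf@coords, Rf) - t(Z))), 1e-6)
  expect_error(backProject(matrix(0, 1, 3), R), "columns")
})

test_that("PCA reconstruction error is non-increasing in the component count", {
  set.seed(11)
  Z <- matrix(rnorm(25 * 18), 25, 18)
  errs <- vapply(1:6, function(q) {
    R <- pcaReduce(Z, q)
    sqrt(sum((backProject(R@coords, R) - t(Z))^2))
  }, 0)
  expect_true(all(diff(errs) < 1e-8))
})
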