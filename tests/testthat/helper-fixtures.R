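# Small in-code fixtures shared across test files.

# uniform samples from a simplex with the given vertex matrix (vertices x
# dims), by normalized exponentials
sampleSimplex <- function(K, n, seed = 1) {
  withr::with_seed(seed, {
    F <- matrix(rgamma(nrow(K) * n, shape = 1), nrow(K))
    F <- sweep(F, 2, colSums(F), "/")
    t(F) %*% K
  })
}

# a desk-scale scenario: small ambient dimension so unit tests stay fast
smallScenario <- function(scen = "C", n = 200, dim = 120, noise = 0.1,
                          seed = 1) {
  simulateScenario(scenarioCatalog(nSamples = n, ambientDim = dim,
                                   noiseLevel = noise,
                                   seed = seed)[[scen]])
}

# ground-truth vertices mapped into the fitted reduced space of a
# Z-score + PCA preprocessing
truthInReducedSpace <- function(Ctrue, Z, R) {
  ctr <- attr(Z, "center")
  scl <- attr(Z, "scale")
  projectReduced(sweep(sweep(Ctrue, 2, ctr), 2, scl, "/"), R)
}

# hand-built bootstrap ensemble for merge tests
fakeEnsemble <- function(means, sds) {
  means <- as.matrix(means)
  new("BootstrapEnsemble",
      replicateK = list(means, means),
      vertexMean = means,
      vertexSd = sds,
      B = 2L)
}
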