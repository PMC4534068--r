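#' Construct a validation scenario specification
#'
#' @param name scenario name.
#' @param subsimplexVertexSets list of integer vectors indexing a global
#'   vertex list 1..V; shared vertices appear in several sets.
#' @param nSamples number of samples (default 400).
#' @param ambientDim number of simulated genes (default 25000).
#' @param noiseLevel additive noise sd as a multiple of the per-dimension
#'   sd of the noiseless mixed data (default 0.1).
#' @param vertexScale sd of the spherical Gaussian for vertex placement
#'   (default 1, mimicking Z-scored expression).
#' @param seed integer seed.
#' @return a [ScenarioSpec-class].
#' @export
scenarioSpec <- function(name = "custom", subsimplexVertexSets,
                         nSamples = 400L, ambientDim = 25000L,
                         noiseLevel = 0.1, vertexScale = 1, seed = 1L) {
  new("ScenarioSpec", name = name,
      subsimplexVertexSets = lapply(subsimplexVertexSets, as.integer),
      nSamples = as.integer(nSamples), ambientDim = as.integer(ambientDim),
      noiseLevel = noiseLevel, vertexScale = vertexScale,
      seed = as.integer(seed))
}

#' Catalog of the four tumor-evolution validation scenarios
#'
#' Four tree-structured mixing scenarios, each describing tumors evolving
#' into two subtypes: (A) two line segments joined at a point (3 vertices;
#' a shared healthy ancestor with one progression state per subtype); (B)
#' two tetrahedra joined at a point (7 vertices; early/intermediate/late
#' stages per subtype); (C) two triangles joined at a point (5 vertices);
#' (D) two triangles sharing an edge (4 vertices; a shared
#' healthy-to-precancerous edge branching into two late states).
#'
#' @param nSamples,ambientDim,noiseLevel,vertexScale,seed defaults applied
#'   to every spec; see [scenarioSpec()].
#' @return named list of [ScenarioSpec-class] objects `A`, `B`, `C`, `D`.
#' @export
scenarioCatalog <- function(nSamples = 400L, ambientDim = 25000L,
                            noiseLevel = 0.1, vertexScale = 1, seed = 1L) {
  sets <- list(
    A = list(c(1L, 2L), c(2L, 3L)),
    B = list(1:4, 4:7),
    C = list(1:3, 3:5),
    D = list(1:3, 2:4)
  )
  names <- c(A = "A_two_lines_point", B = "B_two_tetrahedra_point",
             C = "C_two_triangles_point", D = "D_two_triangles_edge")
  out <- lapply(c("A", "B", "C", "D"), function(s) {
    scenarioSpec(name = names[[s]], subsimplexVertexSets = sets[[s]],
                 nSamples = nSamples, ambientDim = ambientDim,
                 noiseLevel = noiseLevel, vertexScale = vertexScale,
                 seed = seed)
  })
  stats::setNames(out, c("A", "B", "C", "D"))
}

#' Simulate mixed samples from a tree-structured simplicial complex
#'
#' Global vertices are drawn i.i.d. from a spherical Gaussian of scale
#' `vertexScale` in `ambientDim` dimensions. Each sample is assigned
#' uniformly to one subsimplex and its mixture fractions drawn
#' Dirichlet(1, ..., 1) over that subsimplex's vertices; the noiseless
#' sample is the corresponding convex combination of vertices. Additive
#' i.i.d. Gaussian noise is applied per dimension with sd equal to
#' `noiseLevel` times the per-dimension sd of the noiseless mixed data.
#' Bit-identical given the spec's seed.
#'
#' @param spec a [ScenarioSpec-class].
#' @return list with `expression` (genes x samples matrix with ids),
#'   `truth` (list: `C_true` vertices x genes, `F_true` vertices x
#'   samples, `subsimplexLabel` per sample, `noiselessX` samples x genes),
#'   and `spec`.
#' @export
simulateScenario <- function(spec) {
  validObject(spec)
  sets <- spec@subsimplexVertexSets
  nV <- length(unique(unlist(sets)))
  n <- spec@nSamples
  d <- spec@ambientDim
  withr::with_seed(spec@seed, {
    C <- matrix(stats::rnorm(nV * d, sd = spec@vertexScale), nrow = nV)
    lab <- sample.int(length(sets), n, replace = TRUE)
    F <- matrix(0, nV, n)
    for (j in seq_len(n)) {
      vs <- sets[[lab[j]]]
      w <- stats::rgamma(length(vs), shape = 1)
      F[vs, j] <- w / sum(w)
    }
    X0 <- t(F) %*% C                            # n x d noiseless
    if (spec@noiseLevel > 0) {
      sdDim <- apply(X0, 2, stats::sd)
      noise <- matrix(stats::rnorm(n * d), n, d) *
        rep(spec@noiseLevel * sdDim, each = n)
      X <- X0 + noise
    } else {
      X <- X0
    }
  })
  M <- t(X)
  rownames(M) <- paste0("g", seq_len(d))
  colnames(M) <- paste0("s", seq_len(n))
  rownames(C) <- paste0("v", seq_len(nV))
  list(expression = M,
       truth = list(C_true = C, F_true = F, subsimplexLabel = lab,
                    noiselessX = X0),
       spec = spec)
}

#' Total vertex count of a scenario
#'
#' @param spec a [ScenarioSpec-class].
#' @return integer.
#' @export
totalVertices <- function(spec) {
  length(unique(unlist(spec@subsimplexVertexSets)))
}

#' Number of vertices shared between a scenario's subsimplices
#'
#' 1 for the point-joined scenarios, 2 for the shared-edge scenario.
#'
#' @param spec a [ScenarioSpec-class].
#' @return integer.
#' @export
sharedVertices <- function(spec) {
  sets <- spec@subsimplexVertexSets
  if (length(sets) < 2) return(0L)
  length(Reduce(intersect, sets))
}
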