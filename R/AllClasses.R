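#' @import methods
NULL

#' ReducedRepresentation: a PCA embedding with an exact back-projection
#'
#' Holds the low-dimensional coordinates of the samples together with the
#' orthonormal basis and per-gene offset needed to map points (and inferred
#' simplex vertices) back into gene space without loss beyond the truncated
#' components.
#'
#' @slot coords numeric matrix, samples x reduced dimensions (scores along
#'   the principal axes, in Z-score units when fit on Z-scored data).
#' @slot basis numeric matrix, reduced dimensions x genes; rows are
#'   orthonormal principal axes.
#' @slot offset numeric vector of length genes; the per-gene mean removed
#'   before projection.
#' @slot explainedVariance numeric vector; variance along each retained
#'   axis, non-increasing.
#'
#' @seealso [pcaReduce()], [backProject()]
#' @export
setClass("ReducedRepresentation",
  representation(
    coords = "matrix",
    basis = "matrix",
    offset = "numeric",
    explainedVariance = "numeric"
  )
)

setValidity("ReducedRepresentation", function(object) {
  msg <- character()
  gp <- nrow(object@basis)
  if (ncol(object@coords) != gp) {
    msg <- c(msg, "ncol(coords) must equal nrow(basis)")
  }
  if (length(object@offset) != ncol(object@basis)) {
    msg <- c(msg, "length(offset) must equal ncol(basis)")
  }
  if (gp > ncol(object@basis)) {
    msg <- c(msg, "reduced dimension cannot exceed the gene dimension")
  }
  if (length(object@explainedVariance) != gp) {
    msg <- c(msg, "explainedVariance must have one entry per component")
  }
  if (gp > 1 && any(diff(object@explainedVariance) > 1e-8)) {
    msg <- c(msg, "explainedVariance must be non-increasing")
  }
  G <- object@basis %*% t(object@basis)
  if (max(abs(G - diag(gp))) > 1e-8) {
    msg <- c(msg, "rows of basis must be orthonormal")
  }
  if (length(msg)) msg else TRUE
})

#' SimplexModel: one fitted bounding simplex
#'
#' Result of fitting a noise-tolerant simplex to a point cloud under the
#' regularized objective `sum_j ||x_j - K' f_j||_p + gamma * log(penalty(K))`
#' where the penalty is the minimum-spanning-tree length over the vertices
#' (default) or the simplex volume.
#'
#' @slot K numeric matrix, vertices x reduced dimensions.
#' @slot F numeric matrix, vertices x points; each column is on the
#'   probability simplex (nonnegative, sums to 1).
#' @slot residualTerm,penaltyTerm,objective numeric scalars; the objective
#'   decomposition, `objective = residualTerm + gamma * penaltyTerm`.
#' @slot gamma,p numeric; hyperparameters used for the reported objective.
#' @slot penalty character; `"mst"` or `"volume"`.
#' @slot converged logical; `FALSE` when the iteration limit was reached or
#'   the degeneracy floor inside the log penalty was active at the solution.
#' @slot nIter integer; accepted alternating iterations.
#'
#' @seealso [fitSimplex()]
#' @export
setClass("SimplexModel",
  representation(
    K = "matrix",
    F = "matrix",
    residualTerm = "numeric",
    penaltyTerm = "numeric",
    objective = "numeric",
    gamma = "numeric",
    p = "numeric",
    penalty = "character",
    converged = "logical",
    nIter = "integer"
  )
)

setValidity("SimplexModel", function(object) {
  msg <- character()
  if (nrow(object@K) < 2) msg <- c(msg, "a simplex needs at least 2 vertices")
  if (nrow(object@F) != nrow(object@K)) {
    msg <- c(msg, "F must have one row per vertex")
  }
  if (ncol(object@F) > 0) {
    if (min(object@F) < -1e-9) msg <- c(msg, "F entries must be >= -1e-9")
    if (max(abs(colSums(object@F) - 1)) > 1e-6) {
      msg <- c(msg, "F columns must sum to 1 within 1e-6")
    }
  }
  recon <- object@residualTerm + object@gamma * object@penaltyTerm
  if (abs(object@objective - recon) > 1e-8 * max(1, abs(object@objective))) {
    msg <- c(msg, "objective must equal residualTerm + gamma * penaltyTerm")
  }
  if (length(msg)) msg else TRUE
})

#' BootstrapEnsemble: matched bootstrap replicates of one simplex fit
#'
#' @slot replicateK list of vertex matrices, one per retained replicate,
#'   all vertex-aligned to the first replicate by minimum-cost matching.
#' @slot vertexMean numeric matrix, vertices x reduced dimensions; the
#'   central vertex positions over replicates (componentwise median, a
#'   robust mean).
#' @slot vertexSd numeric vector; per-vertex positional standard deviation,
#'   the square root of the summed per-dimension bootstrap variances (i.e.
#'   the root expected squared distance of a replicate vertex from its mean).
#' @slot B integer; number of retained replicates.
#'
#' @seealso [bootstrapSimplex()], [buildComplex()]
#' @export
setClass("BootstrapEnsemble",
  representation(
    replicateK = "list",
    vertexMean = "matrix",
    vertexSd = "numeric",
    B = "integer"
  )
)

setValidity("BootstrapEnsemble", function(object) {
  msg <- character()
  if (object@B < 2L) msg <- c(msg, "B must be >= 2")
  if (length(object@replicateK) != object@B) {
    msg <- c(msg, "replicateK must have B elements")
  }
  m <- nrow(object@vertexMean)
  if (!all(vapply(object@replicateK, nrow, 0L) == m)) {
    msg <- c(msg, "all replicates must share the matched vertex count")
  }
  if (length(object@vertexSd) != m) {
    msg <- c(msg, "vertexSd must have one entry per vertex")
  }
  if (any(object@vertexSd < 0)) msg <- c(msg, "vertexSd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' SimplicialComplex: merged vertex set with subsimplex structure
#'
#' @slot vertices numeric matrix, merged vertices x reduced dimensions.
#' @slot vertexSd numeric vector; per merged vertex, the maximum positional
#'   sd among its members.
#' @slot subsimplices list of integer vectors; for each original cluster,
#'   the merged vertex indices spanning its subsimplex.
#' @slot mergeMap data.frame with columns `cluster`, `vertex`, `merged`
#'   mapping every original (cluster, vertex) pair to its merged index.
#'
#' @seealso [buildComplex()], [mstPhylogeny()]
#' @export
setClass("SimplicialComplex",
  representation(
    vertices = "matrix",
    vertexSd = "numeric",
    subsimplices = "list",
    mergeMap = "data.frame"
  )
)

setValidity("SimplicialComplex", function(object) {
  msg <- character()
  nv <- nrow(object@vertices)
  if (length(object@vertexSd) != nv) {
    msg <- c(msg, "vertexSd must have one entry per merged vertex")
  }
  idx <- unlist(object@subsimplices)
  if (length(idx) && (min(idx) < 1 || max(idx) > nv)) {
    msg <- c(msg, "subsimplices must reference valid merged indices")
  }
  mm <- object@mergeMap
  if (!all(c("cluster", "vertex", "merged") %in% names(mm))) {
    msg <- c(msg, "mergeMap needs columns cluster, vertex, merged")
  } else {
    if (anyDuplicated(mm[, c("cluster", "vertex")])) {
      msg <- c(msg, "each original vertex must map to exactly one merged vertex")
    }
    if (nrow(mm) < nv) msg <- c(msg, "merged count cannot exceed original count")
  }
  if (length(msg)) msg else TRUE
})

#' PhylogenyTree: MST-derived tree over merged complex vertices
#'
#' @slot nodes character vector of vertex ids.
#' @slot edges data.frame with columns `from`, `to`, `length` (Euclidean
#'   edge lengths in reduced-space units); a spanning tree, so
#'   `nrow(edges) == length(nodes) - 1`.
#'
#' @seealso [mstPhylogeny()], [writeNewick()]
#' @export
setClass("PhylogenyTree",
  representation(nodes = "character", edges = "data.frame")
)

setValidity("PhylogenyTree", function(object) {
  msg <- character()
  n <- length(object@nodes)
  e <- object@edges
  if (!all(c("from", "to", "length") %in% names(e))) {
    msg <- c(msg, "edges needs columns from, to, length")
  } else {
    if (n >= 2 && nrow(e) != n - 1) {
      msg <- c(msg, "a tree on n nodes has n - 1 edges")
    }
    if (nrow(e) && !all(c(e$from, e$to) %in% object@nodes)) {
      msg <- c(msg, "edge endpoints must be listed nodes")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ScenarioSpec: generative description of a validation scenario
#'
#' Describes a tree-structured simplicial complex from which mixed samples
#' are drawn: a global vertex list, subsimplices as index sets (shared
#' vertices appear in several sets), and sampling/noise parameters.
#'
#' @slot name character; one of the four named tumor-evolution scenarios or
#'   `"custom"`.
#' @slot subsimplexVertexSets list of integer vectors indexing the global
#'   vertex list.
#' @slot nSamples integer; samples to draw.
#' @slot ambientDim integer; number of simulated genes.
#' @slot noiseLevel numeric in [0, 1]; additive Gaussian noise sd as a
#'   multiple of the per-dimension sd of the noiseless mixed data.
#' @slot vertexScale numeric; sd of the spherical Gaussian from which the
#'   global vertices are drawn.
#' @slot seed integer.
#'
#' @seealso [scenarioCatalog()], [simulateScenario()]
#' @export
setClass("ScenarioSpec",
  representation(
    name = "character",
    subsimplexVertexSets = "list",
    nSamples = "integer",
    ambientDim = "integer",
    noiseLevel = "numeric",
    vertexScale = "numeric",
    seed = "integer"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  sets <- object@subsimplexVertexSets
  if (!length(sets)) msg <- c(msg, "need at least one subsimplex")
  if (any(vapply(sets, length, 0L) < 2)) {
    msg <- c(msg, "every subsimplex needs >= 2 vertices")
  }
  nv <- length(unique(unlist(sets)))
  if (length(sets) && !setequal(unlist(sets), seq_len(nv))) {
    msg <- c(msg, "vertex sets must index 1..totalVertices contiguously")
  }
  if (object@nSamples < nv) msg <- c(msg, "nSamples must be >= total vertex count")
  if (object@noiseLevel < 0) msg <- c(msg, "noiseLevel must be >= 0")
  if (object@ambientDim < 2) msg <- c(msg, "ambientDim must be >= 2")
  if (length(msg)) msg else TRUE
})

#' UnmixResult: end-to-end pipeline output
#'
#' @slot components numeric matrix, merged components x genes, in the units
#'   of the input matrix (Z-scored internal estimates are rescaled back by
#'   the stored per-gene center and scale).
#' @slot fractions numeric matrix, merged components x samples; per sample,
#'   nonnegative, summing to 1 over its own subsimplex's components and
#'   exactly 0 elsewhere (the model's structural-zero constraint).
#' @slot complex the fitted [SimplicialComplex-class].
#' @slot tree the [PhylogenyTree-class] over merged vertices.
#' @slot clusterLabels integer vector; per-sample cluster (subsimplex).
#' @slot reduced the [ReducedRepresentation-class] used internally.
#' @slot provenance list; seeds, per-stage bookkeeping, gene centering and
#'   scaling vectors, dropped constant genes.
#'
#' @seealso [runPipeline()]
#' @export
setClass("UnmixResult",
  representation(
    components = "matrix",
    fractions = "matrix",
    complex = "SimplicialComplex",
    tree = "PhylogenyTree",
    clusterLabels = "integer",
    reduced = "ReducedRepresentation",
    provenance = "list"
  )
)

setValidity("UnmixResult", function(object) {
  msg <- character()
  if (nrow(object@fractions) != nrow(object@complex@vertices)) {
    msg <- c(msg, "fractions must have one row per merged component")
  }
  if (length(object@clusterLabels) != ncol(object@fractions)) {
    msg <- c(msg, "one cluster label per sample required")
  }
  if (ncol(object@fractions) > 0) {
    if (min(object@fractions) < -1e-9) msg <- c(msg, "fractions must be >= 0")
    if (max(abs(colSums(object@fractions) - 1)) > 1e-6) {
      msg <- c(msg, "fraction columns must sum to 1")
    }
  }
  if (length(msg)) msg else TRUE
})
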