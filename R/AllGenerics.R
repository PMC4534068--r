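#' @include AllClasses.R
NULL

#' Accessors for fitted objects
#'
#' `vertices()` returns the vertex matrix of a [SimplexModel-class],
#' [BootstrapEnsemble-class] (the replicate mean) or
#' [SimplicialComplex-class]; `fractions()` the mixture-fraction matrix;
#' `components()` the gene-space component matrix of an
#' [UnmixResult-class]; `vertexSd()` the per-vertex positional standard
#' deviations; `subsimplices()` the merged vertex index sets per cluster.
#'
#' @param object a fitted object.
#' @return A matrix, numeric vector, or list, depending on the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("components", function(object) standardGeneric("components"))

#' @rdname accessors
#' @export
setGeneric("vertexSd", function(object) standardGeneric("vertexSd"))

#' @rdname accessors
#' @export
setGeneric("subsimplices", function(object) standardGeneric("subsimplices"))

#' @rdname accessors
#' @export
setMethod("vertices", "SimplexModel", function(object) object@K)

#' @rdname accessors
#' @export
setMethod("vertices", "BootstrapEnsemble", function(object) object@vertexMean)

#' @rdname accessors
#' @export
setMethod("vertices", "SimplicialComplex", function(object) object@vertices)

#' @rdname accessors
#' @export
setMethod("fractions", "SimplexModel", function(object) object@F)

#' @rdname accessors
#' @export
setMethod("fractions", "UnmixResult", function(object) object@fractions)

#' @rdname accessors
#' @export
setMethod("components", "UnmixResult", function(object) object@components)

#' @rdname accessors
#' @export
setMethod("vertexSd", "BootstrapEnsemble", function(object) object@vertexSd)

#' @rdname accessors
#' @export
setMethod("vertexSd", "SimplicialComplex", function(object) object@vertexSd)

#' @rdname accessors
#' @export
setMethod("subsimplices", "SimplicialComplex", function(object) object@subsimplices)

setMethod("show", "ReducedRepresentation", function(object) {
  cat("ReducedRepresentation:", nrow(object@coords), "samples in",
      ncol(object@coords), "of", ncol(object@basis), "dimensions\n")
  ev <- object@explainedVariance
  cat("  explained variance share:",
      paste(sprintf("%.3f", ev / sum(ev)), collapse = " "), "\n")
})

setMethod("show", "SimplexModel", function(object) {
  cat("SimplexModel:", nrow(object@K), "vertices,", ncol(object@F),
      "points,", ncol(object@K), "dims\n")
  cat(sprintf("  objective %.6g = residual %.6g + gamma %.3g x penalty %.6g (%s, p=%g)\n",
              object@objective, object@residualTerm, object@gamma,
              object@penaltyTerm, object@penalty, object@p))
  cat("  converged:", object@converged, "after", object@nIter, "iterations\n")
})

setMethod("show", "BootstrapEnsemble", function(object) {
  cat("BootstrapEnsemble:", object@B, "replicates,",
      nrow(object@vertexMean), "matched vertices\n")
  cat("  vertex sd:", paste(sprintf("%.4g", object@vertexSd), collapse = " "), "\n")
})

setMethod("show", "SimplicialComplex", function(object) {
  cat("SimplicialComplex:", nrow(object@vertices), "merged vertices,",
      length(object@subsimplices), "subsimplices\n")
  for (i in seq_along(object@subsimplices)) {
    cat("  subsimplex", i, ": {",
        paste(object@subsimplices[[i]], collapse = ", "), "}\n")
  }
})

setMethod("show", "PhylogenyTree", function(object) {
  cat("PhylogenyTree:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

setMethod("show", "ScenarioSpec", function(object) {
  cat("ScenarioSpec", object@name, ":",
      length(object@subsimplexVertexSets), "subsimplices on",
      length(unique(unlist(object@subsimplexVertexSets))), "vertices;",
      object@nSamples, "samples,", object@ambientDim, "dims, noise",
      object@noiseLevel, "\n")
})

setMethod("show", "UnmixResult", function(object) {
  cat("UnmixResult:", nrow(object@components), "components x",
      ncol(object@components), "genes;", ncol(object@fractions), "samples\n")
  show(object@complex)
})
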