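#' Run the full simplicial-complex unmixing pipeline
#'
#' End-to-end orchestration: per-gene Z-scoring, PCA reduction, geodesic
#' k-medoids clustering into putative subsimplices, per-cluster bootstrap
#' simplex fitting, merging of indistinct vertices into a single
#' simplicial complex, a per-sample refit of mixture fractions against the
#' merged vertices of the sample's own subsimplex (the merge moves
#' vertices, so pre-merge fractions are stale), back-projection of merged
#' vertices into gene space, and extraction of the MST phylogeny.
#'
#' A sample's fraction on any component outside its assigned subsimplex is
#' exactly 0: this structural-zero property is the model's defining
#' constraint (and a known limitation for populations, such as
#' infiltrating immune cells, that violate the tree assumption).
#'
#' @param M numeric matrix, genes x samples, in arbitrary units.
#' @param k number of clusters/subsimplices (a user decision, typically
#'   informed by [scanClusterCounts()]).
#' @param nPcs number of principal components (default 10).
#' @param mPerCluster integer vector of per-cluster vertex counts, recycled
#'   to length `k`; `NULL` (default) estimates each count with
#'   [estimateNumVertices()].
#' @param vertexThreshold variance-share threshold for the vertex-count
#'   heuristic (default 0.05).
#' @param cfg an [objectiveConfig()]; its seed drives all fitting.
#' @param B bootstrap replicates per cluster (default 10).
#' @param nRestarts k-medoids restarts (default 20).
#' @param seed integer seed for clustering and bootstrap resampling.
#' @param constantGenePolicy passed to [zscoreGenes()].
#' @param verbose print per-stage progress lines.
#' @return an [UnmixResult-class].
#' @export
runPipeline <- function(M, k, nPcs = 10, mPerCluster = NULL,
                        vertexThreshold = 0.05,
                        cfg = objectiveConfig(), B = 10, nRestarts = 20,
                        seed = 1L, constantGenePolicy = "drop",
                        verbose = FALSE) {
  validateExpressionMatrix(M)
  say <- function(...) if (verbose) message("[simplicialUnmix] ", ...)

  say("z-scoring ", nrow(M), " genes x ", ncol(M), " samples")
  Z <- zscoreGenes(M, constantGenePolicy = constantGenePolicy)
  ctr <- attr(Z, "center"); scl <- attr(Z, "scale")
  dropped <- attr(Z, "dropped")

  nPcs <- min(nPcs, nrow(Z), ncol(Z) - 1)
  say("PCA to ", nPcs, " components")
  R <- pcaReduce(Z, nPcs)
  P <- R@coords                                # samples x nPcs

  say("geodesic distances + k-medoids, k = ", k)
  D <- geodesicDistances(P)
  cl <- kmedoidsCluster(D, P, k, nRestarts = nRestarts, seed = seed)
  labels <- cl$labels

  if (is.null(mPerCluster)) {
    mPerCluster <- vapply(seq_len(k), function(c) {
      estimateNumVertices(P[labels == c, , drop = FALSE],
                          threshold = vertexThreshold)
    }, 0L)
    say("estimated vertex counts: ", paste(mPerCluster, collapse = ", "))
  } else {
    mPerCluster <- rep_len(as.integer(mPerCluster), k)
  }
  if (any(mPerCluster < 2)) {
    stop("every cluster needs at least 2 vertices to fit a simplex")
  }

  say("bootstrap over clustering + fitting, B = ", B,
      ", m = ", paste(mPerCluster, collapse = ", "))
  bp <- bootstrapPipeline(P, k, mPerCluster, cfg, B = B, seed = seed,
                          nRestarts = nRestarts, refLabels = labels)
  ensembles <- bp$ensembles

  say("merging vertices into a simplicial complex")
  cx <- buildComplex(ensembles)
  say("merged vertex count: ", nrow(cx@vertices))

  # refit F per sample against its own subsimplex's merged vertices;
  # components outside the sample's subsimplex stay exactly 0
  nM <- nrow(cx@vertices)
  Fall <- matrix(0, nM, ncol(M),
                 dimnames = list(paste0("v", seq_len(nM)), colnames(M)))
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    vs <- cx@subsimplices[[c]]
    if (length(vs) >= 2) {
      Fc <- solveFractions(cx@vertices[vs, , drop = FALSE],
                           P[idx, , drop = FALSE])
      Fall[vs, idx] <- Fc
    } else {
      Fall[vs, idx] <- 1
    }
  }

  say("back-projecting components into gene space")
  Cz <- backProject(cx@vertices, R)            # merged x genes (Z units)
  Cgene <- sweep(sweep(Cz, 2, scl, `*`), 2, ctr, `+`)
  rownames(Cgene) <- paste0("v", seq_len(nM))
  colnames(Cgene) <- rownames(Z)

  tree <- mstPhylogeny(cx)

  prov <- list(seed = as.integer(seed), nPcs = nPcs, k = k,
               mPerCluster = mPerCluster, B = B,
               gamma = cfg$gamma, p = cfg$p, penalty = cfg$penalty,
               geneCenter = ctr, geneScale = scl, droppedGenes = dropped,
               clusterCost = cl$cost)

  new("UnmixResult", components = Cgene, fractions = Fall, complex = cx,
      tree = tree, clusterLabels = labels, reduced = R, provenance = prov)
}

#' Write pipeline outputs to a directory
#'
#' Writes `components.tsv` (components x genes), `fractions.tsv`
#' (components x samples), `complex.json` (vertices with coordinates and
#' sd, subsimplex index sets, merge map), `tree.nwk` and `tree.tsv`
#' (Newick and edge-list forms of the phylogeny), and `report.json`
#' (seeds, parameters, vertex counts).
#'
#' @param result an [UnmixResult-class].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeUnmixResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, col.names = NA)
  w(result@components, "components.tsv")
  w(result@fractions, "fractions.tsv")
  cx <- result@complex
  jsonlite::write_json(
    list(vertices = unname(apply(cx@vertices, 1, as.numeric,
                                 simplify = FALSE)),
         vertexSd = cx@vertexSd,
         subsimplices = lapply(cx@subsimplices, as.integer),
         mergeMap = cx@mergeMap),
    file.path(dir, "complex.json"), auto_unbox = FALSE, digits = NA)
  writeNewick(result@tree, file.path(dir, "tree.nwk"))
  utils::write.table(result@tree@edges, file.path(dir, "tree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result@provenance[c("seed", "nPcs", "k",
                                           "mPerCluster", "B", "gamma",
                                           "p", "penalty")],
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
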