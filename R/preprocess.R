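#' Read an expression matrix from TSV/CSV
#'
#' Reads a delimited numeric matrix with a header row of sample ids and a
#' first column of gene ids (or the transpose, with
#' `orientation = "samples_by_genes"`), and returns a genes x samples
#' matrix with identifiers as dimnames.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`; chosen from the file
#'   extension when missing.
#' @param orientation `"genes_by_samples"` (default) or
#'   `"samples_by_genes"`; the on-disk layout. The returned matrix is
#'   always genes x samples.
#' @return numeric matrix, genes x samples, with unique row and column
#'   names.
#' @export
readExpressionMatrix <- function(path,
                                 dialect = c("tsv", "csv"),
                                 orientation = c("genes_by_samples",
                                                 "samples_by_genes")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(dialect)) {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty matrix in ", path)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate identifiers: ", paste(dup, collapse = ", "))
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric cell at row ", ids[bad], ", column ",
           colnames(vals)[j])
    }
  }
  M <- as.matrix(vals)
  rownames(M) <- ids
  cdup <- unique(colnames(M)[duplicated(colnames(M))])
  if (length(cdup)) {
    stop("duplicate identifiers: ", paste(cdup, collapse = ", "))
  }
  if (anyNA(M)) stop("missing values are not supported")
  if (orientation == "samples_by_genes") M <- t(M)
  validateExpressionMatrix(M)
  M
}

#' Validate a genes x samples expression matrix
#'
#' Checks the invariants assumed throughout the package: a finite numeric
#' matrix, at least 2 genes and 3 samples, unique identifiers.
#'
#' @param M numeric matrix, genes x samples.
#' @return `M`, invisibly.
#' @export
validateExpressionMatrix <- function(M) {
  if (!is.matrix(M) || !is.numeric(M)) stop("M must be a numeric matrix")
  if (anyNA(M) || any(!is.finite(M))) stop("M contains missing/non-finite values")
  if (nrow(M) < 2) stop("need at least 2 genes")
  if (ncol(M) < 3) stop("need at least 3 samples")
  if (!is.null(rownames(M)) && anyDuplicated(rownames(M))) {
    stop("duplicate gene ids")
  }
  if (!is.null(colnames(M)) && anyDuplicated(colnames(M))) {
    stop("duplicate sample ids")
  }
  invisible(M)
}

#' Z-score each gene across samples
#'
#' Centers and scales every row to mean 0 and sample standard deviation 1.
#' Constant genes have no defined Z score and are dropped (default) or set
#' to zero, per `constantGenePolicy`.
#'
#' The per-gene center and scale are attached as attributes `"center"` and
#' `"scale"` (and dropped gene names as `"dropped"`) so that quantities
#' estimated in Z-score units can be mapped back to the input units.
#'
#' @param M numeric matrix, genes x samples, `ncol(M) >= 2`.
#' @param constantGenePolicy `"drop"` (default) or `"zero"`.
#' @return numeric matrix of Z scores, genes x samples.
#' @export
zscoreGenes <- function(M, constantGenePolicy = c("drop", "zero")) {
  constantGenePolicy <- match.arg(constantGenePolicy)
  if (!is.matrix(M) || !is.numeric(M)) stop("M must be a numeric matrix")
  if (ncol(M) < 2) stop("need at least 2 samples to compute a Z score")
  ctr <- rowMeans(M)
  scl <- apply(M, 1, stats::sd)
  const <- scl < .Machine$double.eps^0.5 * pmax(1, abs(ctr))
  Z <- (M - ctr) / ifelse(const, 1, scl)
  dropped <- character()
  if (any(const)) {
    if (constantGenePolicy == "drop") {
      dropped <- rownames(M)[const]
      if (is.null(dropped)) dropped <- as.character(which(const))
      Z <- Z[!const, , drop = FALSE]
      ctr <- ctr[!const]
      scl <- scl[!const]
    } else {
      Z[const, ] <- 0
      scl[const] <- 1
    }
  }
  attr(Z, "center") <- ctr
  attr(Z, "scale") <- ifelse(scl < .Machine$double.eps^0.5, 1, scl)
  attr(Z, "dropped") <- dropped
  Z
}

#' Reduce dimension by PCA
#'
#' Treats samples as observations and genes as features, centers by the
#' per-gene mean, and projects onto the top `nComponents` principal axes.
#' The sign of each axis is fixed so its largest-magnitude loading is
#' positive, making runs reproducible.
#'
#' @param Z numeric matrix, genes x samples (typically Z scores).
#' @param nComponents number of components, `<= min(genes, samples - 1)`.
#' @return a [ReducedRepresentation-class].
#' @export
pcaReduce <- function(Z, nComponents) {
  if (!is.matrix(Z) || !is.numeric(Z)) stop("Z must be a numeric matrix")
  g <- nrow(Z)
  s <- ncol(Z)
  if (nComponents < 1 || nComponents > min(g, s - 1)) {
    stop("nComponents must be in [1, min(genes, samples - 1)]")
  }
  X <- t(Z)                               # samples x genes
  offset <- colMeans(X)
  Xc <- sweep(X, 2, offset)
  sv <- svd(Xc, nu = nComponents, nv = nComponents)
  basis <- t(sv$v)                        # nComponents x genes
  # sign convention: largest-|loading| entry of each axis positive
  for (i in seq_len(nComponents)) {
    j <- which.max(abs(basis[i, ]))
    if (basis[i, j] < 0) {
      basis[i, ] <- -basis[i, ]
      sv$u[, i] <- -sv$u[, i]
    }
  }
  coords <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  rownames(coords) <- colnames(Z)
  ev <- sv$d[seq_len(nComponents)]^2 / (s - 1)
  new("ReducedRepresentation", coords = coords, basis = basis,
      offset = offset, explainedVariance = ev)
}

#' Map reduced-space points into gene space
#'
#' Back-projects vertices (or any reduced-space points) through the PCA
#' basis: `point %*% basis + offset`. For points in the span of the
#' retained axes this inverts [pcaReduce()] exactly.
#'
#' @param K numeric matrix, points x reduced dimensions (a vector is taken
#'   as one point).
#' @param R a [ReducedRepresentation-class].
#' @return numeric matrix, points x genes.
#' @export
backProject <- function(K, R) {
  if (is.null(dim(K))) K <- matrix(K, nrow = 1)
  if (ncol(K) != nrow(R@basis)) {
    stop("K must have ", nrow(R@basis), " columns to match the basis")
  }
  sweep(K %*% R@basis, 2, R@offset, `+`)
}

#' Project gene-space points into the reduced space
#'
#' The forward map matching [backProject()]: `(x - offset) %*% t(basis)`.
#' Used to place ground-truth components or new samples into the fitted
#' coordinate system.
#'
#' @param X numeric matrix, points x genes.
#' @param R a [ReducedRepresentation-class].
#' @return numeric matrix, points x reduced dimensions.
#' @export
projectReduced <- function(X, R) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(R@basis)) {
    stop("X must have ", ncol(R@basis), " columns (genes)")
  }
  sweep(X, 2, R@offset) %*% t(R@basis)
}
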