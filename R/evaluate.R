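#' Vertex reconstruction error (RMSD per vertex per dimension)
#'
#' Matches estimated to true vertices by minimum-cost assignment
#' (Euclidean) and reports
#' `sqrt(sum_matched ||c_est - c_true||^2 / (m_matched * g))`. With unequal
#' counts, the smaller set is matched injectively into the larger; surplus
#' vertices are reported but not scored.
#'
#' @param Cest numeric matrix, estimated vertices x dimensions.
#' @param Ctrue numeric matrix, true vertices x dimensions (same space).
#' @return list with `rmsd`, `matching` (integer vector over estimated
#'   vertices; the matched true index or `NA`), `nMatched`,
#'   `nVerticesEst`, `nVerticesTrue`.
#' @export
vertexRMSD <- function(Cest, Ctrue) {
  if (is.null(dim(Cest))) Cest <- matrix(Cest, nrow = 1)
  if (is.null(dim(Ctrue))) Ctrue <- matrix(Ctrue, nrow = 1)
  if (!nrow(Cest) || !nrow(Ctrue)) stop("empty vertex set")
  if (ncol(Cest) != ncol(Ctrue)) stop("vertex sets live in different spaces")
  mE <- nrow(Cest)
  mT <- nrow(Ctrue)
  g <- ncol(Cest)
  C <- matrix(0, mE, mT)
  for (i in seq_len(mE)) {
    C[i, ] <- sqrt(colSums((t(Ctrue) - Cest[i, ])^2))
  }
  matching <- rep(NA_integer_, mE)
  if (mE <= mT) {
    pad <- if (mE < mT) {
      # rectangular: pad with zero-cost dummy rows so every column can
      # absorb one row
      rbind(C, matrix(0, mT - mE, mT))
    } else C
    perm <- .assignmentBB(pad)
    matching <- perm[seq_len(mE)]
  } else {
    # surplus estimated vertices: match true vertices into estimated and
    # invert the permutation
    padT <- rbind(t(C), matrix(0, mE - mT, mE))
    permT <- .assignmentBB(padT)
    for (t in seq_len(mT)) matching[permT[t]] <- t
  }
  matched <- which(!is.na(matching))
  ss <- sum((Cest[matched, , drop = FALSE] -
               Ctrue[matching[matched], , drop = FALSE])^2)
  list(rmsd = sqrt(ss / (length(matched) * g)),
       matching = matching,
       nMatched = length(matched),
       nVerticesEst = mE, nVerticesTrue = mT)
}

#' Mixture-fraction reconstruction error
#'
#' With `mode = "reconstruction"` (default) the error is measured in the
#' data space through the true components:
#' `sqrt(||Ctrue' (Fhat_aligned - Ftrue)||_F^2 / (n * g))`, an RMSD per
#' point per ambient dimension. `mode = "fractions"` scores the fractions
#' directly: `sqrt(||Fhat_aligned - Ftrue||_F^2 / (n * m))`. Estimated
#' components are aligned to true ones via `matching` from
#' [vertexRMSD()]; unmatched estimated components with nonzero usage are
#' scored against zero rows, with a warning.
#'
#' @param Fest numeric matrix, estimated components x samples.
#' @param Ftrue numeric matrix, true components x samples.
#' @param matching integer vector over estimated components (true index or
#'   `NA`), as returned by [vertexRMSD()].
#' @param mode `"reconstruction"` or `"fractions"`.
#' @param Ctrue true components x genes; required for reconstruction mode.
#' @return nonnegative scalar.
#' @export
fractionRMSD <- function(Fest, Ftrue, matching,
                         mode = c("reconstruction", "fractions"),
                         Ctrue = NULL) {
  mode <- match.arg(mode)
  stopifnot(ncol(Fest) == ncol(Ftrue), length(matching) == nrow(Fest))
  n <- ncol(Ftrue)
  mT <- nrow(Ftrue)
  Fa <- matrix(0, mT, n)
  for (i in seq_along(matching)) {
    if (!is.na(matching[i])) {
      Fa[matching[i], ] <- Fa[matching[i], ] + Fest[i, ]
    } else if (any(Fest[i, ] > 1e-12)) {
      warning("unmatched estimated component ", i,
              " has nonzero usage; scored against zero")
    }
  }
  Dlt <- Fa - Ftrue
  if (mode == "fractions") {
    sqrt(sum(Dlt^2) / (n * mT))
  } else {
    if (is.null(Ctrue)) stop("reconstruction mode needs Ctrue")
    stopifnot(nrow(Ctrue) == mT)
    sqrt(sum((t(Dlt) %*% Ctrue)^2) / (n * ncol(Ctrue)))
  }
}

#' Gaussian-mixture baseline
#'
#' Fits a k-component full-covariance Gaussian mixture by EM (mclust,
#' model `"VVV"`, deterministic hierarchical initialization) on the
#' reduced data. Component means play the role of vertices and posterior
#' responsibilities the role of mixture fractions when scoring against
#' ground truth. On a failed or singular fit, retries with a Bayesian
#' regularizing prior (the EM analogue of a diagonal jitter), with a
#' warning.
#'
#' @param X numeric matrix, points x dimensions (reduced space).
#' @param k number of components.
#' @param seed accepted for interface uniformity; the initialization is
#'   deterministic.
#' @return list with `means` (k x dims) and `responsibilities` (points x
#'   k, rows summing to 1).
#' @export
gmmBaseline <- function(X, k, seed = 1L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (k > nrow(X)) stop("k cannot exceed the number of points")
  emFit <- function(prior = NULL) {
    bic <- suppressWarnings(
      mclust::mclustBIC(X, G = k, modelNames = "VVV", verbose = FALSE,
                        prior = prior)
    )
    sm <- suppressWarnings(
      mclust::summaryMclustBIC(bic, X, G = k, modelNames = "VVV")
    )
    if (!length(sm) || is.null(sm$parameters)) return(NULL)
    sm
  }
  fit <- emFit()
  if (is.null(fit)) {
    warning("EM failed without regularization; refitting with a ",
            "covariance-regularizing prior")
    fit <- emFit(prior = mclust::priorControl())
  }
  if (is.null(fit)) stop("Gaussian mixture fit failed")
  means <- t(fit$parameters$mean)
  if (k == 1) means <- matrix(colMeans(X), nrow = 1)
  z <- fit$z
  if (is.null(dim(z))) z <- matrix(rep(1, nrow(X)), ncol = 1)
  list(means = means, responsibilities = z)
}

#' Single-simplex baseline
#'
#' Fits one simplex to the whole point cloud (no clustering, no merging)
#' with the total ground-truth vertex count, reproducing the earlier
#' pure-simplex approach for comparison.
#'
#' @param X numeric matrix, points x dimensions.
#' @param m total vertex count.
#' @param cfg an [objectiveConfig()]; `penalty = "volume"` reproduces the
#'   volume-regularized variant.
#' @return a [SimplexModel-class].
#' @export
singleSimplexBaseline <- function(X, m, cfg = objectiveConfig()) {
  fitSimplex(X, m, cfg)
}

#' Chi-squared test of association between two labelings
#'
#' Pearson chi-squared test of independence (no continuity correction) on
#' the cross-tabulation of two categorical vectors, e.g. subsimplex
#' assignment versus clinical subtype. Categories with zero margin are
#' dropped with a warning.
#'
#' @param labelsA,labelsB vectors of equal length.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
contingencyChiSq <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB)) stop("label vectors differ in length")
  tab <- table(labelsA, labelsB)
  keepR <- rowSums(tab) > 0
  keepC <- colSums(tab) > 0
  if (!all(keepR) || !all(keepC)) {
    warning("dropping zero-margin categories")
    tab <- tab[keepR, keepC, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need at least 2 categories in each labeling after drops")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value)
}
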