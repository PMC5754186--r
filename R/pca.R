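#' Principal component analysis of the dosage matrix
#'
#' Covariance PCA of the genotype-by-SNP dosage matrix (columns centered;
#' unit-scaled only when \code{scale = TRUE}), used to derive population
#' structure covariates for the genome scans. Component signs are fixed
#' by making each component's largest-magnitude loading positive.
#'
#' @param g a fully observed \linkS4class{GenotypeDosage} (or a plain
#'   numeric matrix, genotypes in rows)
#' @param scale unit-scale columns (correlation PCA); requires no
#'   constant columns
#' @param kSelected default number of components to use as covariates
#'   downstream (the study's convention is 7)
#' @return A \linkS4class{GenoPCA}; components are truncated to
#'   min(n - 1, m), the maximum possible rank of the centered matrix.
#' @export
genotypePCA <- function(g, scale = FALSE, kSelected = 7L) {
  M <- if (is(g, "GenotypeDosage")) dosages(g) else as.matrix(g)
  if (anyNA(M)) stop("dosage matrix must be fully observed (impute first)")
  if (nrow(M) < 2 || ncol(M) < 2) stop("need >= 2 genotypes and >= 2 SNPs")
  if (scale) {
    cst <- apply(M, 2, function(v) diff(range(v)) == 0)
    if (any(cst))
      stop("constant column(s) with scale = TRUE: ",
           paste(colnames(M)[cst], collapse = ", "))
  }
  pc <- prcomp(M, center = TRUE, scale. = scale)
  k <- min(nrow(M) - 1L, ncol(M))
  sdev <- pc$sdev[seq_len(k)]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest |loading| positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- sdev^2 / sum(pc$sdev^2)
  new("GenoPCA", scores = scores, loadings = loadings,
      explained = expl, kSelected = as.integer(min(kSelected, k)),
      scaled = scale)
}

#' Select principal components for use as covariates
#'
#' Either the first \code{k} components, or the smallest prefix whose
#' cumulative explained variance reaches \code{cumVar}.
#'
#' @param pc a \linkS4class{GenoPCA}
#' @param k fixed number of components
#' @param cumVar cumulative variance threshold in (0, 1]
#' @return integer vector of component indices
#' @export
selectPCs <- function(pc, k = NULL, cumVar = NULL) {
  stopifnot(is(pc, "GenoPCA"))
  nc <- length(pc@explained)
  if (!is.null(k)) {
    if (k > nc) stop("k = ", k, " exceeds the ", nc, " available components")
    return(seq_len(k))
  }
  if (is.null(cumVar) || cumVar <= 0 || cumVar > 1)
    stop("supply k, or cumVar in (0, 1]")
  seq_len(which(cumsum(pc@explained) >= cumVar - 1e-12)[1])
}
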