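#' Mean-impute missing dosages per SNP
#'
#' Each missing entry is replaced by the mean dosage of its SNP over the
#' non-missing genotypes, so column means are preserved and imputed
#' values stay in [0, 2]. Non-missing entries are never changed.
#'
#' @param g a \linkS4class{GenotypeDosage}, possibly with \code{NA}s
#' @return A fully observed \linkS4class{GenotypeDosage}.
#' @export
imputeMissing <- function(g) {
  stopifnot(is(g, "GenotypeDosage"))
  d <- dosages(g)                       # genotypes x SNPs
  nmiss <- colSums(is.na(d))
  allmiss <- nmiss == nrow(d)
  if (any(allmiss))
    stop("SNP(s) with all dosages missing: ",
         paste(colnames(d)[allmiss], collapse = ", "))
  if (any(nmiss > 0)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  GenotypeDosage(d, snpMap(g), chromosomes = unique(snpMap(g)$chrom))
}

#' Drop monomorphic (constant-dosage) SNPs
#'
#' Constant columns make the single-SNP design singular, so they are
#' removed before scanning; the removal list is returned for logging.
#'
#' @param g a fully observed \linkS4class{GenotypeDosage}
#' @return list with elements \code{genotypes} (filtered
#'   GenotypeDosage, or NULL if no SNP survives) and \code{removed}
#'   (character vector of dropped snp_ids).
#' @export
dropMonomorphic <- function(g) {
  stopifnot(is(g, "GenotypeDosage"))
  d <- dosages(g)
  if (anyNA(d)) stop("impute missing dosages before filtering")
  rng <- apply(d, 2, function(v) diff(range(v)))
  const <- rng == 0
  removed <- colnames(d)[const]
  if (all(const))
    return(list(genotypes = NULL, removed = removed))
  if (any(const)) {
    keep <- !const
    map <- snpMap(g)[!const, , drop = FALSE]
    g <- GenotypeDosage(d[, keep, drop = FALSE], map,
                        chromosomes = unique(map$chrom))
  }
  list(genotypes = g, removed = removed)
}
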