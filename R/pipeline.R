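#' Run the full association pipeline
#'
#' Orchestrates adjust -> pca -> scan for each trait: reads (or accepts)
#' genotypes and phenotypes, imputes and filters dosages, fits the full
#' and reduced mixed models, reports variance components, model
#' comparison and heritability, computes PC covariates, runs the
#' traditional OLS scan and/or the quantile-regression scan, and writes
#' scan TSVs plus a JSON summary into \code{outDir}.
#'
#' @param genotypes a \linkS4class{GenotypeDosage} or path to a wide
#'   genotype CSV
#' @param phenotypes a \linkS4class{PhenotypeRecords} or path to a long
#'   phenotype CSV
#' @param traits traits to analyse (default: all in the phenotypes)
#' @param taus quantile grid for the QR scan
#' @param npc number of PC covariates
#' @param method "both", "qr" or "ols"
#' @param ystarMode adjusted-phenotype mode, see
#'   \code{\link{adjustedPhenotypes}}
#' @param seed seed recorded in outputs and used for any resampling
#' @param outDir output directory (created); NULL to skip writing
#' @param mapPath optional SNP map TSV when \code{genotypes} is a path
#'   without embedded map rows
#' @return (invisibly) list with per-trait model reports, scan results
#'   and the summary written to JSON
#' @export
runPipeline <- function(genotypes, phenotypes, traits = NULL,
                        taus = seq(0.1, 0.9, by = 0.1), npc = 7L,
                        method = c("both", "qr", "ols"),
                        ystarMode = "genotype_blup", seed = 1L,
                        outDir = NULL, mapPath = NULL) {
  method <- match.arg(method)
  if (is.character(genotypes))
    genotypes <- readGenotypes(genotypes, mapPath = mapPath)
  if (is.character(phenotypes))
    phenotypes <- readPhenotypes(phenotypes)
  stopifnot(is(genotypes, "GenotypeDosage"),
            is(phenotypes, "PhenotypeRecords"))
  if (is.null(traits)) traits <- traitNames(phenotypes)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  g <- imputeMissing(genotypes)
  flt <- dropMonomorphic(g)
  if (length(flt$removed))
    message("dropped ", length(flt$removed), " monomorphic SNP(s)")
  g <- flt$genotypes
  if (is.null(g)) stop("no polymorphic SNPs left after filtering")

  pca <- if (npc > 0) genotypePCA(g, kSelected = npc) else NULL

  reports <- list(); scans <- list()
  for (tr in traits) {
    full <- fitPhenoLMM(phenotypes, tr, includeGxE = TRUE)
    reduced <- fitPhenoLMM(phenotypes, tr, includeGxE = FALSE)
    cmp <- lrTestGxE(full, reduced)
    h2 <- heritability(full)
    ystar <- adjustedPhenotypes(full, mode = ystarMode)
    res <- list()
    if (method %in% c("both", "qr"))
      res$qr <- qrScan(ystar, g, pca = pca, npc = npc, taus = taus,
                       seed = seed, trait = tr)
    if (method %in% c("both", "ols"))
      res$ols <- olsScan(ystar, g, pca = pca, npc = npc, trait = tr)
    reports[[tr]] <- list(varComp = as.list(varComp(full)),
                          comparison = cmp, h2 = h2)
    scans[[tr]] <- res
    if (!is.null(outDir)) {
      if (!is.null(res$qr))
        writeScanTable(res$qr, file.path(outDir, paste0("scan_qr_", tr, ".tsv")))
      if (!is.null(res$ols))
        writeScanTable(res$ols, file.path(outDir, paste0("scan_ols_", tr, ".tsv")))
    }
  }

  anyScan <- scans[[1]][[1]]
  summary <- list(
    version = as.character(packageVersion("qrscan")),
    seed = seed, traits = traits, taus = taus, npc = npc,
    n_genotypes = length(genotypeIds(g)), n_snps = nrow(g),
    removed_snps = flt$removed,
    thresholds = list(t05 = unname(thresholds(anyScan)["t05"]),
                      t01 = unname(thresholds(anyScan)["t01"])),
    significant = lapply(scans, function(res)
      lapply(res, function(s) callSignificant(s, 0.05)$snp_id)),
    reports = reports)
  if (!is.null(outDir))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(reports = reports, scans = scans, summary = summary,
                 genotypes = g, pca = pca))
}
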