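#' @include qrscan-package.R
NULL

## Chromosome labels of the Phaseolus vulgaris reference (Pv01..Pv11).
## Simulated and real maps are checked against this set unless the user
## declares another one via the `chromosomes` argument of the constructor.
PV_CHROMOSOMES <- sprintf("Pv%02d", 1:11)

# ---------------------------------------------------------------------------
# GenotypeDosage
# ---------------------------------------------------------------------------

#' SNP dosage matrix with genomic map
#'
#' A \linkS4class{RangedSummarizedExperiment} holding one assay,
#' \code{"dosage"}: rows are SNPs (with chromosome and base-pair position in
#' \code{rowRanges}), columns are genotypes (cultivars). Entries are counts
#' of the alternate allele in \code{[0, 2]} (0/1/2 before imputation,
#' real-valued after mean imputation) or \code{NA} for missing calls.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}.
#' @export
setClass("GenotypeDosage", contains = "RangedSummarizedExperiment")

setValidity("GenotypeDosage", function(object) {
  msg <- character()
  if (!identical(assayNames(object), "dosage"))
    msg <- c(msg, "must carry exactly one assay named 'dosage'")
  d <- assay(object, "dosage")
  if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
    msg <- c(msg, "genotype ids (colnames) must be present and unique")
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    msg <- c(msg, "SNP ids (rownames) must be present and unique")
  if (ncol(d) < 2)
    msg <- c(msg, "at least 2 genotypes are required")
  bad <- !is.na(d) & (d < 0 | d > 2)
  if (any(bad))
    msg <- c(msg, sprintf("dosages must lie in [0, 2] or be NA (%d offending entries)",
                          sum(bad)))
  if (any(start(rowRanges(object)) < 0))
    msg <- c(msg, "positions must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeDosage object
#'
#' @param dosage numeric matrix, genotypes in rows and SNPs in columns
#'   (the orientation of the wide genotype file); rownames are genotype
#'   ids, colnames SNP ids. Entries 0/1/2, real values in \code{[0,2]}, or
#'   \code{NA}.
#' @param map data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp}, one row per SNP, in the column order of \code{dosage}.
#' @param chromosomes character vector of admissible chromosome labels.
#' @return A \linkS4class{GenotypeDosage}.
#' @examples
#' d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' map <- data.frame(snp_id = c("s1", "s2"), chrom = "Pv01",
#'                   pos_bp = c(100L, 2000L))
#' GenotypeDosage(d, map)
#' @export
GenotypeDosage <- function(dosage, map, chromosomes = PV_CHROMOSOMES) {
  dosage <- as.matrix(dosage)
  if (!is.numeric(dosage)) stop("dosage matrix must be numeric")
  stopifnot(is.data.frame(map))
  need <- c("snp_id", "chrom", "pos_bp")
  if (!all(need %in% names(map)))
    stop("map must have columns snp_id, chrom, pos_bp")
  if (nrow(map) != ncol(dosage))
    stop("map rows (", nrow(map), ") != dosage columns (", ncol(dosage), ")")
  if (is.null(colnames(dosage))) colnames(dosage) <- map$snp_id
  if (!identical(colnames(dosage), as.character(map$snp_id)))
    stop("SNP ids of dosage columns and map disagree")
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_id in map: ",
         paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", "))
  if (!all(map$chrom %in% chromosomes))
    stop("chromosome labels outside the declared set: ",
         paste(setdiff(unique(map$chrom), chromosomes), collapse = ", "))
  if (any(map$pos_bp < 0)) stop("pos_bp must be non-negative")
  rr <- GRanges(as.character(map$chrom),
                IRanges(start = pmax(as.integer(map$pos_bp), 1L), width = 1L),
                snp_id = as.character(map$snp_id),
                pos_bp = as.numeric(map$pos_bp))
  names(rr) <- as.character(map$snp_id)
  se <- SummarizedExperiment(assays = list(dosage = t(dosage)), rowRanges = rr)
  new("GenotypeDosage", se)
}

# ---------------------------------------------------------------------------
# PhenotypeRecords
# ---------------------------------------------------------------------------

#' Long-format plot-level phenotype records
#'
#' One row per (genotype, environment, block, trait) combination, holding
#' the observed plot value. Blocks are nested within environments: the
#' same block label in two environments denotes two distinct plots.
#'
#' @slot records data.frame with columns \code{genotype},
#'   \code{environment}, \code{block}, \code{trait}, \code{value}.
#' @export
setClass("PhenotypeRecords", representation(records = "data.frame"))

setValidity("PhenotypeRecords", function(object) {
  r <- object@records
  need <- c("genotype", "environment", "block", "trait", "value")
  if (!all(need %in% names(r)))
    return("records must have columns genotype, environment, block, trait, value")
  if (!is.numeric(r$value)) return("value must be numeric")
  key <- paste(r$genotype, r$environment, r$block, r$trait, sep = "\r")
  if (anyDuplicated(key))
    return(sprintf("duplicated (genotype, environment, block, trait) rows: %s",
                   paste(utils::head(unique(gsub("\r", "/", key[duplicated(key)])), 3),
                         collapse = "; ")))
  TRUE
})

#' Construct PhenotypeRecords from a long-format data.frame
#'
#' @param records data.frame with columns \code{genotype},
#'   \code{environment}, \code{block}, \code{trait}, \code{value}.
#' @return A \linkS4class{PhenotypeRecords}.
#' @export
PhenotypeRecords <- function(records) {
  records <- as.data.frame(records)
  for (cc in c("genotype", "environment", "block", "trait"))
    if (cc %in% names(records)) records[[cc]] <- as.character(records[[cc]])
  new("PhenotypeRecords", records = records)
}

# ---------------------------------------------------------------------------
# LmmFit
# ---------------------------------------------------------------------------

#' REML mixed-model fit of a plot-level trait
#'
#' Result of \code{\link{fitPhenoLMM}}: the phenotypic model
#' \eqn{y_{ijk} = \mu + g_i + a_j + ga_{ij} + b_{k(j)} + e_{ijk}} with
#' fixed environment effects and random genotype, interaction and block
#' terms, fitted by REML.
#'
#' @slot trait trait name.
#' @slot includeGxE whether the genotype-by-environment term was fitted.
#' @slot varComp named variance components (sigma2_g, sigma2_ga, sigma2_b,
#'   sigma2_e); sigma2_ga absent for the reduced model.
#' @slot fixef fixed-effect estimates (intercept and environment contrasts).
#' @slot blups list of per-level BLUPs for each random term.
#' @slot frame per-plot data with fitted values and residuals.
#' @slot remlLogLik restricted log-likelihood at the optimum.
#' @slot nObs,nEnv,nRep design dimensions.
#' @slot converged logical.
#' @slot fingerprint data fingerprint used to guard model comparisons.
#' @export
setClass("LmmFit", representation(
  trait = "character", includeGxE = "logical", varComp = "numeric",
  fixef = "numeric", blups = "list", frame = "data.frame",
  remlLogLik = "numeric", nObs = "integer", nEnv = "integer",
  nRep = "numeric", converged = "logical", fingerprint = "numeric"))

setValidity("LmmFit", function(object) {
  if (any(object@varComp < 0)) return("variance components must be >= 0")
  TRUE
})

# ---------------------------------------------------------------------------
# GenoPCA
# ---------------------------------------------------------------------------

#' Principal components of the dosage matrix
#'
#' @slot scores n x k matrix of genotype coordinates (all retained
#'   components).
#' @slot loadings m x k matrix of SNP loadings.
#' @slot explained proportion of variance per component (sums to 1).
#' @slot kSelected default number of components used as scan covariates.
#' @slot scaled whether columns were unit-scaled (correlation PCA).
#' @export
setClass("GenoPCA", representation(
  scores = "matrix", loadings = "matrix", explained = "numeric",
  kSelected = "integer", scaled = "logical"))

setValidity("GenoPCA", function(object) {
  e <- object@explained
  if (abs(sum(e) - 1) > 1e-9) return("explained proportions must sum to 1")
  if (any(diff(e) > 1e-12)) return("explained proportions must be non-increasing")
  if (ncol(object@scores) != length(e)) return("scores/explained mismatch")
  TRUE
})

# ---------------------------------------------------------------------------
# QRFit
# ---------------------------------------------------------------------------

#' Check-loss quantile regression fit at one quantile
#'
#' @slot tau the quantile in (0, 1).
#' @slot coef coefficient vector (a vertex solution of the check-loss LP).
#' @slot objective minimized check loss \eqn{\sum_i \rho_\tau(r_i)}.
#' @slot residuals fitted residuals; exactly zero on the basis rows.
#' @slot dual regression rank scores (dual values) in [tau-1, tau].
#' @slot basis indices of the interpolated observations.
#' @slot iter simplex iterations used.
#' @export
setClass("QRFit", representation(
  tau = "numeric", coef = "numeric", objective = "numeric",
  residuals = "numeric", dual = "numeric", basis = "integer",
  iter = "integer"))

setValidity("QRFit", function(object) {
  if (object@tau <= 0 || object@tau >= 1) return("tau must lie in (0, 1)")
  if (object@objective < 0) return("objective must be >= 0")
  ob <- sum(checkLoss(object@residuals, object@tau))
  if (abs(ob - object@objective) > 1e-8 * (1 + ob))
    return("objective does not equal the summed check loss of the residuals")
  TRUE
})

# ---------------------------------------------------------------------------
# ScanResult
# ---------------------------------------------------------------------------

#' Genome-scan result table
#'
#' One record per SNP and model (the mean model of the traditional OLS
#' scan, or one quantile of the QR scan), with Bonferroni thresholds and
#' scan metadata.
#'
#' @slot records data.frame with columns snp_id, chrom, pos_bp, model,
#'   tau, beta_snp, se, p_value, minus_log10_p, r2_pct.
#' @slot thresholds named numeric, \code{t05} and \code{t01}, in -log10
#'   units (full precision).
#' @slot metadata list: trait, method, taus, n, m, npc, seed, skipped.
#' @export
setClass("ScanResult", representation(
  records = "data.frame", thresholds = "numeric", metadata = "list"))

setValidity("ScanResult", function(object) {
  r <- object@records
  need <- c("snp_id", "chrom", "pos_bp", "model", "tau", "beta_snp",
            "p_value", "minus_log10_p", "r2_pct")
  if (!all(need %in% names(r))) return("records are missing required columns")
  if (!all(c("t05", "t01") %in% names(object@thresholds)))
    return("thresholds must be named t05, t01")
  if (anyDuplicated(paste(r$snp_id, r$model)))
    return("one record per (SNP, model) required")
  ok <- is.finite(r$p_value)
  if (any(r$p_value[ok] < 0 | r$p_value[ok] > 1)) return("p values outside [0, 1]")
  if (any(abs(r$minus_log10_p[ok] + log10(pmax(r$p_value[ok], 1e-320))) > 1e-9))
    return("minus_log10_p inconsistent with p_value")
  TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "PhenotypeRecords", function(object) {
  r <- object@records
  cat("PhenotypeRecords:", nrow(r), "plot records;",
      length(unique(r$genotype)), "genotypes x",
      length(unique(r$environment)), "environments;",
      "traits:", paste(unique(r$trait), collapse = ", "), "\n")
})

setMethod("show", "LmmFit", function(object) {
  cat("LmmFit for trait '", object@trait, "' (",
      if (object@includeGxE) "full, with GxE" else "reduced, no GxE",
      "); n = ", object@nObs, "\n", sep = "")
  print(round(object@varComp, 4))
  cat("REML log-likelihood:", format(object@remlLogLik), "\n")
})

setMethod("show", "GenoPCA", function(object) {
  cat("GenoPCA:", nrow(object@scores), "genotypes,",
      ncol(object@scores), "components;",
      "first", object@kSelected, "selected (",
      sprintf("%.1f%%", 100 * sum(object@explained[seq_len(object@kSelected)])),
      "of variance )\n")
})

setMethod("show", "QRFit", function(object) {
  cat("QRFit at tau =", object@tau, "; objective =",
      format(object@objective), "\n")
  print(object@coef)
})

setMethod("show", "ScanResult", function(object) {
  m <- object@metadata
  cat("ScanResult (", m$method, ") for trait '", m$trait, "': ",
      nrow(object@records), " records over ", m$m, " SNPs",
      if (length(m$taus)) paste0(", taus = ", paste(m$taus, collapse = " ")),
      "\n", sep = "")
  cat(sprintf("thresholds (-log10 P): %.2f (5%%), %.2f (1%%)\n",
              trunc(object@thresholds["t05"] * 100) / 100,
              trunc(object@thresholds["t01"] * 100) / 100))
})

# ---------------------------------------------------------------------------
# accessors
# ---------------------------------------------------------------------------

#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Dosage matrix, genotypes in rows
#' @param x a GenotypeDosage
#' @export
setMethod("dosages", "GenotypeDosage", function(x) t(assay(x, "dosage")))

#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' SNP map (snp_id, chrom, pos_bp)
#' @param x a GenotypeDosage or ScanResult
#' @export
setMethod("snpMap", "GenotypeDosage", function(x) {
  rr <- rowRanges(x)
  data.frame(snp_id = rr$snp_id, chrom = as.character(seqnames(rr)),
             pos_bp = rr$pos_bp, row.names = NULL)
})

#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))

#' @describeIn GenotypeDosage genotype (cultivar) identifiers
#' @param x a GenotypeDosage
#' @export
setMethod("genotypeIds", "GenotypeDosage", function(x) colnames(x))

#' @export
setGeneric("phenoRecords", function(x) standardGeneric("phenoRecords"))

#' @describeIn PhenotypeRecords the underlying long-format data.frame
#' @param x a PhenotypeRecords
#' @export
setMethod("phenoRecords", "PhenotypeRecords", function(x) x@records)

#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @describeIn PhenotypeRecords trait names present
#' @export
setMethod("traitNames", "PhenotypeRecords", function(x) unique(x@records$trait))

#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))

#' @describeIn LmmFit REML variance components
#' @export
setMethod("varComp", "LmmFit", function(x) x@varComp)

#' @export
setGeneric("blups", function(x, term = "genotype") standardGeneric("blups"))

#' @describeIn LmmFit per-level BLUPs of a random term
#' @param term one of "genotype", "gxe", "block"
#' @export
setMethod("blups", "LmmFit", function(x, term = "genotype") x@blups[[term]])

#' @export
setGeneric("remlLogLik", function(x) standardGeneric("remlLogLik"))

#' @describeIn LmmFit restricted log-likelihood
#' @export
setMethod("remlLogLik", "LmmFit", function(x) x@remlLogLik)

#' @export
setGeneric("pcScores", function(x, k = NULL) standardGeneric("pcScores"))

#' @describeIn GenoPCA score matrix, optionally truncated to k components
#' @param k number of leading components (default: all)
#' @export
setMethod("pcScores", "GenoPCA", function(x, k = NULL) {
  if (is.null(k)) x@scores else x@scores[, seq_len(k), drop = FALSE]
})

#' @export
setGeneric("explainedVar", function(x) standardGeneric("explainedVar"))

#' @describeIn GenoPCA proportion of variance per component
#' @export
setMethod("explainedVar", "GenoPCA", function(x) x@explained)

#' @export
setGeneric("scanRecords", function(x) standardGeneric("scanRecords"))

#' @describeIn ScanResult the per-SNP record table
#' @export
setMethod("scanRecords", "ScanResult", function(x) x@records)

#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @describeIn ScanResult Bonferroni thresholds in -log10 units
#' @export
setMethod("thresholds", "ScanResult", function(x) x@thresholds)
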