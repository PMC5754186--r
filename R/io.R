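## File I/O for the wide genotype CSV and the long phenotype CSV.
##
## Genotype dialect: first column = genotype id, remaining columns = SNP
## ids. The chromosome/position map either rides along as two extra rows
## directly under the header (ids "chrom" and "pos_bp"), or lives in a
## separate 3-column TSV (snp_id, chrom, pos_bp).

#' Read a wide genotype dosage CSV
#'
#' @param path CSV file: header of SNP ids, first column genotype ids.
#'   Two optional map rows with ids \code{chrom} and \code{pos_bp} may
#'   follow the header.
#' @param mapPath optional TSV with columns snp_id, chrom, pos_bp;
#'   required when the map rows are not embedded.
#' @param missingCodes values treated as missing besides empty cells.
#' @param chromosomes admissible chromosome labels.
#' @return A \linkS4class{GenotypeDosage} with missing entries kept as
#'   \code{NA} (no silent imputation).
#' @export
readGenotypes <- function(path, mapPath = NULL,
                          missingCodes = c("NA", "", "."),
                          chromosomes = PV_CHROMOSOMES) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("genotype file needs an id column and >= 1 SNP")
  ids <- raw[[1]]
  snps <- colnames(raw)[-1]

  embedded <- nrow(raw) >= 2 && identical(ids[1:2], c("chrom", "pos_bp"))
  if (embedded) {
    map <- data.frame(snp_id = snps,
                      chrom = as.character(raw[1, -1]),
                      pos_bp = as.numeric(raw[2, -1]))
    raw <- raw[-(1:2), , drop = FALSE]
    ids <- raw[[1]]
  } else {
    if (is.null(mapPath))
      stop("no embedded map rows ('chrom'/'pos_bp'); supply mapPath")
    if (!file.exists(mapPath)) stop("map file not found: ", mapPath)
    map <- read.delim(mapPath, colClasses = c("character", "character", "numeric"))
    names(map) <- c("snp_id", "chrom", "pos_bp")
    map <- map[match(snps, map$snp_id), ]
    if (anyNA(map$snp_id))
      stop("map file is missing SNPs: ",
           paste(utils::head(snps[is.na(map$snp_id)], 5), collapse = ", "))
  }

  if (anyDuplicated(ids))
    stop("duplicate genotype ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals[vals %in% missingCodes] <- NA
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which((!is.na(vals)) & (is.na(num) | !(num %in% c(0, 1, 2))),
               arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("invalid dosage '%s' at genotype '%s', SNP '%s' (expected 0/1/2 or missing)",
                 vals[i, j], ids[i], snps[j]))
  }
  dimnames(num) <- list(ids, snps)
  GenotypeDosage(num, map, chromosomes = chromosomes)
}

#' Write a GenotypeDosage as a wide CSV with embedded map rows
#'
#' Inverse of \code{\link{readGenotypes}}; a write/read round trip
#' reproduces dosages and map exactly.
#'
#' @param g a GenotypeDosage
#' @param path output CSV path
#' @export
writeGenotypes <- function(g, path) {
  d <- dosages(g)
  map <- snpMap(g)
  body <- rbind(map$chrom,
                format(map$pos_bp, scientific = FALSE, trim = TRUE),
                matrix(ifelse(is.na(d), "NA",
                              format(d, scientific = FALSE, trim = TRUE,
                                     digits = 15)),
                       nrow(d), ncol(d)))
  out <- data.frame(genotype = c("chrom", "pos_bp", rownames(d)), body,
                    check.names = FALSE)
  colnames(out) <- c("genotype", colnames(d))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long phenotype CSV
#'
#' Expected columns: \code{genotype}, \code{environment}, \code{block},
#' then one numeric column per trait. Blocks are interpreted as nested
#' within environment.
#'
#' @param path CSV path
#' @return A \linkS4class{PhenotypeRecords}.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  raw <- read.csv(path, check.names = FALSE)
  need <- c("genotype", "environment", "block")
  if (!all(need %in% names(raw)))
    stop("phenotype file must have columns genotype, environment, block")
  traits <- setdiff(names(raw), need)
  if (!length(traits)) stop("phenotype file has no trait columns")
  for (tr in traits) {
    v <- raw[[tr]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(as.character(v)))
      off <- which(!is.na(as.character(v)) & is.na(conv))
      if (length(off))
        stop(sprintf("non-numeric value '%s' for trait '%s' at row %d",
                     as.character(v)[off[1]], tr, off[1]))
      raw[[tr]] <- conv
    }
  }
  long <- do.call(rbind, lapply(traits, function(tr) {
    data.frame(genotype = as.character(raw$genotype),
               environment = as.character(raw$environment),
               block = as.character(raw$block),
               trait = tr, value = raw[[tr]])
  }))
  long <- long[!is.na(long$value), , drop = FALSE]
  PhenotypeRecords(long)
}

#' Write PhenotypeRecords as a long (wide-by-trait) CSV
#'
#' @param p a PhenotypeRecords
#' @param path output CSV path
#' @export
writePhenotypes <- function(p, path) {
  r <- phenoRecords(p)
  wide <- stats::reshape(r, idvar = c("genotype", "environment", "block"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
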