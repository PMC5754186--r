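# Small deterministic fixtures built in code.

toy_map <- function(m, chrom = "Pv01") {
  data.frame(snp_id = sprintf("s%02d", seq_len(m)),
             chrom = rep_len(chrom, m),
             pos_bp = seq_len(m) * 1000L)
}

toy_genotypes <- function(dosage, chrom = "Pv01") {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("g%02d", seq_len(nrow(dosage)))
  map <- toy_map(ncol(dosage), chrom)
  colnames(dosage) <- map$snp_id
  GenotypeDosage(dosage, map)
}

write_genotype_csv <- function(path, mat, chrom = NULL, pos = NULL,
                               ids = NULL) {
  m <- ncol(mat)
  if (is.null(chrom)) chrom <- rep("Pv01", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(nrow(mat)))
  snps <- sprintf("s%02d", seq_len(m))
  lines <- c(paste(c("genotype", snps), collapse = ","),
             paste(c("chrom", chrom), collapse = ","),
             paste(c("pos_bp", pos), collapse = ","),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(ids[i], mat[i, ]), collapse = ","), ""))
  writeLines(lines, path)
  path
}

# balanced trial phenotypes from explicit effects (no package RNG)
balanced_records <- function(nG, nE, nR, mu = 40, g = NULL, a = NULL,
                             ga = NULL, b = NULL, e = NULL,
                             trait = "DTF") {
  ids <- sprintf("g%02d", seq_len(nG))
  df <- expand.grid(genotype = ids,
                    environment = sprintf("E%d", seq_len(nE)),
                    block = sprintf("B%d", seq_len(nR)),
                    stringsAsFactors = FALSE)
  if (is.null(g)) g <- rep(0, nG)
  if (is.null(a)) a <- rep(0, nE)
  if (is.null(ga)) ga <- matrix(0, nG, nE)
  if (is.null(b)) b <- matrix(0, nE, nR)
  if (is.null(e)) e <- rep(0, nrow(df))
  iG <- match(df$genotype, ids)
  iE <- as.integer(sub("E", "", df$environment))
  iB <- as.integer(sub("B", "", df$block))
  df$trait <- trait
  df$value <- mu + g[iG] + a[iE] + ga[cbind(iG, iE)] + b[cbind(iE, iB)] + e
  PhenotypeRecords(df[, c("genotype", "environment", "block", "trait", "value")])
}

# random balanced trial with known components
random_trial <- function(nG, nE, nR, sg, sga, sb, se, mu = 40, seed = 1,
                         trait = "DTF") {
  set.seed(seed)
  balanced_records(nG, nE, nR, mu = mu,
                   g = rnorm(nG, 0, sqrt(sg)),
                   a = seq(-2, 2, length.out = nE),
                   ga = matrix(rnorm(nG * nE, 0, sqrt(sga)), nG, nE),
                   b = matrix(rnorm(nE * nR, 0, sqrt(sb)), nE, nR),
                   e = rnorm(nG * nE * nR, 0, sqrt(se)),
                   trait = trait)
}
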