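## Stage two: genome-wide single-marker scans of the adjusted phenotypes.

.alignYstar <- function(ystar, g) {
  if (is.data.frame(ystar)) {
    stopifnot(all(c("genotype", "y_star") %in% names(ystar)))
    ystar <- setNames(ystar$y_star, ystar$genotype)
  }
  if (is.null(names(ystar))) stop("adjusted phenotypes must carry genotype ids")
  ids <- genotypeIds(g)
  missing_y <- setdiff(ids, names(ystar))
  extra_y <- setdiff(names(ystar), ids)
  if (length(missing_y) || length(extra_y))
    stop("genotype ids of phenotypes and genotypes are misaligned; ",
         if (length(missing_y)) paste0("missing phenotype for: ",
           paste(utils::head(missing_y, 5), collapse = ", "), ". "),
         if (length(extra_y)) paste0("no genotypes for: ",
           paste(utils::head(extra_y, 5), collapse = ", ")))
  ystar[ids]
}

.pcCovariates <- function(g, pca, npc) {
  if (npc == 0) return(NULL)
  if (is.null(pca)) pca <- genotypePCA(g, kSelected = npc)
  sc <- pcScores(pca, min(npc, ncol(pcScores(pca))))
  rownames(sc) <- genotypeIds(g)
  sc
}

.mlog10 <- function(p) -log10(pmax(p, 1e-320))

#' Bonferroni genome-wide threshold on the -log10 scale
#'
#' -log10(alpha / m) for m tested SNPs. Display conventionally truncates
#' to two decimals (e.g. 3.8853 is printed 3.88); comparisons in
#' \code{\link{callSignificant}} use full precision.
#'
#' @param m number of tested SNPs (>= 1)
#' @param alpha genome-wide error rate in (0, 1)
#' @return threshold in -log10 units (full precision)
#' @examples
#' bonferroniThreshold(384, 0.05)  # 3.8853, printed as 3.88
#' bonferroniThreshold(384, 0.01)  # 4.5843, printed as 4.58
#' @export
bonferroniThreshold <- function(m, alpha) {
  if (!is.numeric(m) || m < 1 || m != round(m)) stop("m must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  -log10(alpha / m)
}

#' Truncate a -log10 threshold for display
#' @param x numeric
#' @return x truncated (not rounded) to 2 decimals
#' @export
truncThreshold <- function(x) trunc(x * 100) / 100

.newScanResult <- function(records, m, meta) {
  new("ScanResult", records = records,
      thresholds = c(t05 = bonferroniThreshold(m, 0.05),
                     t01 = bonferroniThreshold(m, 0.01)),
      metadata = meta)
}

#' Traditional single-SNP least-squares scan
#'
#' For each SNP, ordinary least squares of the adjusted phenotype on
#' intercept + dosage + the selected principal components, with a
#' two-sided t test on the dosage (allele-substitution) coefficient.
#'
#' @param ystar adjusted phenotypes: a named numeric vector or the
#'   data.frame from \code{\link{adjustedPhenotypes}}
#' @param g a fully observed, polymorphic \linkS4class{GenotypeDosage}
#' @param pca optional \linkS4class{GenoPCA} of \code{g} (computed if
#'   NULL and \code{npc > 0})
#' @param npc number of PC covariates (0 for none)
#' @param trait trait label recorded in the metadata
#' @return A \linkS4class{ScanResult} with one record per SNP
#'   (model "mean").
#' @export
olsScan <- function(ystar, g, pca = NULL, npc = 7L, trait = "trait") {
  y <- .alignYstar(ystar, g)
  D <- dosages(g)
  pcs <- .pcCovariates(g, pca, npc)
  n <- length(y); m <- ncol(D)
  X0 <- cbind(`(Intercept)` = rep(1, n), pcs)
  p <- ncol(X0) + 1L
  if (n <= p) stop("more model parameters than genotypes")
  beta <- se <- pv <- rep(NA_real_, m)
  skipped <- character()
  for (j in seq_len(m)) {
    X <- cbind(X0[, 1, drop = FALSE], snp = D[, j],
               X0[, -1, drop = FALSE])
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) { skipped <- c(skipped, colnames(D)[j]); next }
    cf <- qr.coef(qrX, y)
    res <- y - X %*% cf
    rdf <- n - ncol(X)
    s2 <- sum(res^2) / rdf
    XtXi <- chol2inv(qr.R(qrX))
    beta[j] <- cf[2]
    se[j] <- sqrt(s2 * XtXi[2, 2])
    pv[j] <- if (se[j] == 0) 0 else 2 * pt(-abs(beta[j] / se[j]), rdf)
  }
  map <- snpMap(g)
  keep <- !map$snp_id %in% skipped
  rec <- data.frame(snp_id = map$snp_id, chrom = map$chrom,
                    pos_bp = map$pos_bp, model = "mean", tau = NA_real_,
                    beta_snp = beta, se = se, p_value = pv,
                    minus_log10_p = .mlog10(pv), r2_pct = NA_real_)[keep, ]
  rownames(rec) <- NULL
  .newScanResult(rec, sum(keep),
                 list(trait = trait, method = "ols", taus = numeric(),
                      n = n, m = sum(keep), npc = if (is.null(pcs)) 0L else ncol(pcs),
                      seed = NA_integer_, skipped = skipped))
}

#' Quantile-regression genome scan over a grid of quantiles
#'
#' For each SNP and each quantile tau, fits the check-loss quantile
#' regression of the adjusted phenotype on intercept + dosage + PC
#' covariates, tests the dosage coefficient, and reports the
#' Koenker-Machado R1 against the null model (intercept + PCs at the
#' same tau) as a percentage.
#'
#' @inheritParams olsScan
#' @param taus quantile grid (default 0.1 to 0.9 by 0.1, the standard
#'   nine-quantile scan)
#' @param method "score" (rank-score test, default) or "wald_nid"
#' @param seed recorded in metadata; the scan itself is deterministic
#' @return A \linkS4class{ScanResult} with one record per (SNP, tau).
#' @export
qrScan <- function(ystar, g, pca = NULL, npc = 7L,
                   taus = seq(0.1, 0.9, by = 0.1),
                   method = c("score", "wald_nid"), seed = 1L,
                   trait = "trait") {
  method <- match.arg(method)
  if (any(taus <= 0 | taus >= 1)) stop("all taus must lie in (0, 1)")
  y <- .alignYstar(ystar, g)
  D <- dosages(g)
  pcs <- .pcCovariates(g, pca, npc)
  n <- length(y); m <- ncol(D)
  X0 <- cbind(`(Intercept)` = rep(1, n), pcs)
  if (n <= ncol(X0) + 1L) stop("more model parameters than genotypes")

  # residualize dosages on the null design once (for the score test and
  # to detect SNPs collinear with the covariates)
  qrX0 <- qr(X0)
  Dt <- D - X0 %*% qr.coef(qrX0, D)
  ssx <- colSums(Dt^2)
  usable <- ssx > 1e-8 * (colSums(D^2) + 1)
  skipped <- colnames(D)[!usable]

  map <- snpMap(g)
  out <- vector("list", length(taus))
  for (ti in seq_along(taus)) {
    tau <- taus[ti]
    null_fit <- fitQuantile(X0, y, tau)
    psi <- null_fit@dual
    beta <- se <- pv <- r2 <- rep(NA_real_, m)
    if (method == "score") {
      S <- as.numeric(crossprod(Dt, psi))
      V <- tau * (1 - tau) * ssx
      pv[usable] <- 2 * pnorm(-abs(S[usable] / sqrt(V[usable])))
      se[usable] <- (sqrt(V) / ssx)[usable]
    }
    for (j in which(usable)) {
      X <- cbind(X0[, 1, drop = FALSE], snp = D[, j], X0[, -1, drop = FALSE])
      fit <- fitQuantile(X, y, tau)
      beta[j] <- fit@coef[2]
      r2[j] <- 100 * pseudoR1(fit@objective, null_fit@objective)
      if (method == "wald_nid") {
        w <- .waldNid(X, y, fit)
        se[j] <- w$se[2]; pv[j] <- w$p_value[2]
      }
    }
    out[[ti]] <- data.frame(
      snp_id = map$snp_id, chrom = map$chrom, pos_bp = map$pos_bp,
      model = sprintf("tau=%g", tau), tau = tau, beta_snp = beta,
      se = se, p_value = pv, minus_log10_p = .mlog10(pv),
      r2_pct = r2)[usable, ]
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  .newScanResult(rec, sum(usable),
                 list(trait = trait, method = paste0("qr_", method),
                      taus = taus, n = n, m = sum(usable),
                      npc = if (is.null(pcs)) 0L else ncol(pcs),
                      seed = seed, skipped = skipped))
}

#' Records exceeding the genome-wide threshold
#'
#' Returns the scan records whose -log10 p meets or exceeds the
#' Bonferroni threshold at the chosen level (ties at the threshold are
#' included), sorted by chromosome then position.
#'
#' @param res a \linkS4class{ScanResult}
#' @param level 0.05 or 0.01
#' @return data.frame of significant records (possibly empty)
#' @export
callSignificant <- function(res, level = c(0.05, 0.01)) {
  level <- match.arg(as.character(level[1]), c("0.05", "0.01"))
  thr <- res@thresholds[if (level == "0.05") "t05" else "t01"]
  r <- res@records
  hit <- !is.na(r$minus_log10_p) & r$minus_log10_p >= thr
  out <- r[hit, , drop = FALSE]
  out[order(out$chrom, out$pos_bp), , drop = FALSE]
}

#' Plot-ready Manhattan table
#'
#' Concatenates chromosomes in label order on a cumulative genome
#' coordinate (each chromosome offset by the summed lengths of the
#' preceding ones, length = largest SNP position observed), with a
#' parity index for the alternating color scheme.
#'
#' @param res a \linkS4class{ScanResult}
#' @param model which records to plot: "mean" or a tau value (default:
#'   all records)
#' @return data.frame(snp_id, chrom, pos_bp, cum_pos, minus_log10_p,
#'   parity) with attributes \code{t05} and \code{t01}.
#' @export
manhattanTable <- function(res, model = NULL) {
  r <- res@records
  if (!is.null(model)) {
    r <- if (identical(model, "mean")) r[r$model == "mean", ]
         else r[!is.na(r$tau) & abs(r$tau - as.numeric(model)) < 1e-9, ]
  }
  if (!nrow(r)) stop("no records for the requested model")
  chroms <- sort(unique(r$chrom))
  len <- vapply(chroms, function(cc) max(r$pos_bp[r$chrom == cc]), 0)
  offset <- setNames(cumsum(c(0, len[-length(len)])), chroms)
  out <- data.frame(snp_id = r$snp_id, chrom = r$chrom, pos_bp = r$pos_bp,
                    model = r$model,
                    cum_pos = r$pos_bp + offset[r$chrom],
                    minus_log10_p = r$minus_log10_p,
                    parity = (match(r$chrom, chroms) - 1) %% 2)
  rownames(out) <- NULL
  attr(out, "t05") <- unname(res@thresholds["t05"])
  attr(out, "t01") <- unname(res@thresholds["t01"])
  out
}

#' Write a scan result as a TSV
#'
#' Output is deterministic (fixed formatting); positions are also given
#' in Mb with two decimals, the reporting convention for this genome.
#'
#' @param res a \linkS4class{ScanResult}
#' @param path output path
#' @param header write metadata header comments
#' @export
writeScanTable <- function(res, path, header = TRUE) {
  r <- res@records
  m <- res@metadata
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(sprintf("# qrscan %s", as.character(packageVersion("qrscan"))), con)
    writeLines(sprintf("# trait=%s method=%s n=%d m=%d npc=%d seed=%s",
                       m$trait, m$method, m$n, m$m, m$npc,
                       as.character(m$seed)), con)
    writeLines(sprintf("# thresholds -log10P: %.2f (5%%) %.2f (1%%)",
                       truncThreshold(res@thresholds["t05"]),
                       truncThreshold(res@thresholds["t01"])), con)
  }
  tab <- data.frame(snp = r$snp_id, chrom = r$chrom,
                    pos_mb = sprintf("%.2f", r$pos_bp / 1e6),
                    model = r$model,
                    beta = sprintf("%.6g", r$beta_snp),
                    p = sprintf("%.6g", r$p_value),
                    mlog10p = sprintf("%.4f", r$minus_log10_p),
                    r2_pct = ifelse(is.na(r$r2_pct), "NA",
                                    sprintf("%.4f", r$r2_pct)))
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  writeLines(do.call(paste, c(tab, sep = "\t")), con)
  invisible(path)
}
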