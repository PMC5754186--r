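test_that("REML optimum beats every point of a surrounding component grid", {
  ph <- random_trial(15, 3, 2, sg = 4, sga = 1, sb = 0.5, se = 1, seed = 2)
  fit <- fitPhenoLMM(ph, "DTF")
  df <- lmm_frame(ph, "DTF")
  v <- varComp(fit)

  # the package's reported log-likelihood equals the dense-matrix REML
  # log-likelihood evaluated at its own estimates
  l_hat <- reml_loglik_dense(df, v["sigma2_g"], v["sigma2_ga"],
                             v["sigma2_b"], v["sigma2_e"])
  expect_equal(remlLogLik(fit), l_hat, tolerance = 1e-5)

  # no point of a coarse multiplicative grid around the estimate does better
  for (fg in c(0.6, 1, 1.6)) for (fga in c(0.6, 1.6)) for (fe in c(0.6, 1, 1.6)) {
    l <- reml_loglik_dense(df, max(v["sigma2_g"] * fg, 1e-6),
                           max(v["sigma2_ga"] * fga, 1e-6),
                           max(v["sigma2_b"], 1e-6),
                           v["sigma2_e"] * fe)
    expect_lte(l, l_hat + 1e-6)
  }
})

test_that("variance components are recovered within simulation error", {
  ph <- random_trial(80, 4, 3, sg = 4, sga = 1, sb = 0.5, se = 1, seed = 7)
  fit <- fitPhenoLMM(ph, "DTF")
  v <- varComp(fit)
  expect_equal(unname(v["sigma2_g"]), 4, tolerance = 0.5)
  expect_equal(unname(v["sigma2_ga"]), 1, tolerance = 0.35)
  expect_equal(unname(v["sigma2_e"]), 1, tolerance = 0.15)
  expect_true(all(v >= 0))
})

test_that("a constant response yields zero components and the constant mean", {
  ph <- balanced_records(5, 2, 2, mu = 41)
  fit <- fitPhenoLMM(ph, "DTF")
  expect_true(all(varComp(fit) <= 1e-8))
  expect_equal(unname(fit@fixef["(Intercept)"]), 41)
})

test_that("single-level random terms are rejected", {
  ph <- balanced_records(1, 2, 2, mu = 40)
  expect_error(fitPhenoLMM(ph, "DTF"), "single level")
  expect_error(fitPhenoLMM(balanced_records(3, 2, 2), "DEF"), "not present")
})

test_that("information criteria follow the REML formulas", {
  fit <- fitPhenoLMM(random_trial(10, 3, 2, 2, 1, 0.5, 1, seed = 3), "DTF")
  ic <- informationCriteria(fit)
  q <- length(varComp(fit))
  expect_equal(q, 4L)
  expect_equal(unname(ic["AIC"]), -2 * remlLogLik(fit) + 2 * q)
  expect_equal(unname(ic["BIC"]), -2 * remlLogLik(fit) + q * log(fit@nObs))
  # worked arithmetic: l = -1100, q = 3, n = 960
  expect_equal(-2 * -1100 + 2 * 3, 2206)
  expect_equal(-2 * -1100 + 3 * log(960), 2220.60, tolerance = 1e-2)
})

test_that("the GxE likelihood-ratio test behaves across effect sizes", {
  # strong interaction: decisively rejected, full model preferred by AIC/BIC
  ph <- random_trial(60, 4, 3, sg = 2, sga = 2, sb = 0.5, se = 1, seed = 11)
  full <- fitPhenoLMM(ph, "DTF", includeGxE = TRUE)
  red <- fitPhenoLMM(ph, "DTF", includeGxE = FALSE)
  cmp <- lrTestGxE(full, red)
  expect_gte(remlLogLik(full), remlLogLik(red) - 1e-6)
  expect_equal(cmp$lrt_stat, 2 * (remlLogLik(full) - remlLogLik(red)),
               tolerance = 1e-9)
  expect_lt(cmp$lrt_pvalue, 0.01)
  expect_lt(cmp$aic_full, cmp$aic_reduced)
  expect_lt(cmp$bic_full, cmp$bic_reduced)

  # no interaction simulated: full and reduced likelihoods nearly equal
  ph0 <- random_trial(60, 4, 3, sg = 2, sga = 0, sb = 0.5, se = 1, seed = 12)
  full0 <- fitPhenoLMM(ph0, "DTF", TRUE)
  red0 <- fitPhenoLMM(ph0, "DTF", FALSE)
  cmp0 <- lrTestGxE(full0, red0)
  expect_lt(cmp0$lrt_stat, 4)
  expect_lt(unname(varComp(full0)["sigma2_ga"]), 0.15)

  # boundary mixture halves the p-value; zero statistic gives p = 1
  cmpb <- lrTestGxE(full0, red0, boundary = TRUE)
  if (cmp0$lrt_stat > 0)
    expect_equal(cmpb$lrt_pvalue, cmp0$lrt_pvalue / 2)

  # different data are refused
  expect_error(lrTestGxE(full, red0), "same data")
  expect_error(lrTestGxE(red, full), "must include")
})

test_that("entry-mean heritability follows the formula and its monotonicity", {
  expect_equal(heritability(c(sigma2_g = 2, sigma2_ga = 1, sigma2_e = 1),
                            nEnv = 4, nRep = 3),
               2 / (2 + 0.25 + 1 / 12), tolerance = 1e-12)
  expect_equal(heritability(c(sigma2_g = 0, sigma2_ga = 1, sigma2_e = 1),
                            nEnv = 4, nRep = 3), 0)
  expect_equal(heritability(c(sigma2_g = 3, sigma2_ga = 0, sigma2_e = 0),
                            nEnv = 2, nRep = 2), 1)
  expect_error(heritability(c(sigma2_g = 0, sigma2_ga = 0, sigma2_e = 0),
                            nEnv = 4, nRep = 3), "undefined")
  h <- vapply(seq(0.5, 5, by = 0.5), function(sg)
    heritability(c(sigma2_g = sg, sigma2_ga = 1, sigma2_e = 1), 4, 3), 0)
  expect_true(all(diff(h) > 0))
  h2 <- vapply(seq(0.5, 5, by = 0.5), function(se)
    heritability(c(sigma2_g = 2, sigma2_ga = 1, sigma2_e = se), 4, 3), 0)
  expect_true(all(diff(h2) < 0))
})

test_that("adjusted phenotypes are one value per genotype, centered, monotone in the raw means", {
  ph <- random_trial(25, 3, 2, sg = 4, sga = 0.5, sb = 0.5, se = 1, seed = 4)
  fit <- fitPhenoLMM(ph, "DTF")
  ys <- adjustedPhenotypes(fit)
  r <- phenoRecords(ph)
  expect_setequal(ys$genotype, unique(r$genotype))
  expect_equal(nrow(ys), 25L)
  expect_equal(mean(ys$y_star), 0, tolerance = 1e-6)

  raw <- tapply(r$value, r$genotype, mean)
  expect_equal(order(raw[ys$genotype]), order(ys$y_star))

  ys2 <- adjustedPhenotypes(fit, mode = "plot_sum")
  expect_equal(nrow(ys2), 25L)
  expect_equal(attr(ys2, "mode"), "plot_sum")
  # both modes rank genotypes identically under balance
  expect_equal(order(ys$y_star), order(ys2$y_star))
})

test_that("genetic parameters: identical traits give unit correlations", {
  ph1 <- random_trial(20, 3, 2, 3, 0.5, 0.5, 1, seed = 6, trait = "DTF")
  r <- phenoRecords(ph1)
  r2 <- r; r2$trait <- "DFF"
  both <- PhenotypeRecords(rbind(r, r2))
  f1 <- fitPhenoLMM(both, "DTF")
  f2 <- fitPhenoLMM(both, "DFF")
  gp <- geneticParameters(list(f1, f2))
  expect_equal(unname(gp$geneticCor["DTF", "DFF"]), 1, tolerance = 1e-9)
  expect_equal(unname(gp$phenotypicCor["DTF", "DFF"]), 1, tolerance = 1e-9)
  expect_equal(diag(gp$geneticCor), c(DTF = 1, DFF = 1))
  expect_equal(unname(gp$h2["DTF"]), unname(gp$h2["DFF"]))
})

test_that("genetic correlation of BLUPs tracks the simulated correlation", {
  set.seed(88)
  nG <- 60
  reps <- 25
  est <- est0 <- numeric(reps)
  for (i in seq_len(reps)) {
    g1 <- rnorm(nG)
    g2 <- 0.9 * g1 + sqrt(1 - 0.81) * rnorm(nG)   # cor 0.9
    g3 <- rnorm(nG)                                # independent
    mk <- function(g, tr) balanced_records(
      nG, 3, 2, g = 2 * g, a = c(-1, 0, 1),
      e = rnorm(nG * 6), trait = tr)
    recs <- rbind(phenoRecords(mk(g1, "A")), phenoRecords(mk(g2, "B")),
                  phenoRecords(mk(g3, "C")))
    ph <- PhenotypeRecords(recs)
    fits <- list(fitPhenoLMM(ph, "A"), fitPhenoLMM(ph, "B"),
                 fitPhenoLMM(ph, "C"))
    gp <- geneticParameters(fits)
    est[i] <- gp$geneticCor["A", "B"]
    est0[i] <- gp$geneticCor["A", "C"]
  }
  expect_equal(mean(est), 0.9, tolerance = 0.05)
  expect_lt(abs(mean(est0)), 0.1)
})

test_that("zero-variance BLUPs are reported by trait name", {
  ph1 <- random_trial(10, 2, 2, 2, 0.5, 0.5, 1, seed = 9, trait = "A")
  r <- phenoRecords(ph1)
  rconst <- r; rconst$trait <- "B"; rconst$value <- 40
  ph <- PhenotypeRecords(rbind(r, rconst))
  fa <- fitPhenoLMM(ph, "A"); fb <- fitPhenoLMM(ph, "B")
  expect_error(geneticParameters(list(fa, fb)), "zero-variance.*'B'")
})
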