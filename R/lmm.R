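## Stage one: REML mixed model for plot-level phenotypes.
##
## Model: y_ijk = mu + g_i + a_j + ga_ij + b_k(j) + e_ijk, with fixed
## environment effects a_j and independent normal random effects
## g_i ~ (0, sigma2_g), ga_ij ~ (0, sigma2_ga), b_k(j) ~ (0, sigma2_b),
## e_ijk ~ (0, sigma2_e). The reduced model drops exactly the ga term.

.lmmFrame <- function(records, trait) {
  r <- phenoRecords(records)
  r <- r[r$trait == trait, , drop = FALSE]
  if (!nrow(r)) stop("trait '", trait, "' not present in records")
  data.frame(genotype = factor(r$genotype),
             environment = factor(r$environment),
             block = factor(paste(r$environment, r$block, sep = ":")),
             gxe = factor(paste(r$genotype, r$environment, sep = ":")),
             y = r$value)
}

.fingerprint <- function(df) {
  c(n = nrow(df), s1 = sum(df$y), s2 = sum(df$y^2),
    ng = nlevels(df$genotype), ne = nlevels(df$environment))
}

#' Fit the plot-level phenotypic mixed model by REML
#'
#' @param records a \linkS4class{PhenotypeRecords}
#' @param trait trait name to fit
#' @param includeGxE fit the genotype-by-environment random term (full
#'   model); \code{FALSE} drops exactly that term (reduced model)
#' @return An \linkS4class{LmmFit}.
#' @examples
#' cfg <- simConfig(nGeno = 12, nSnp = 20, seed = 1)
#' sim <- simulateGenotypes(cfg)
#' ph <- simulatePhenotypes(sim$genotypes, cfg)
#' fit <- fitPhenoLMM(ph$records, "DTF")
#' varComp(fit)
#' @export
fitPhenoLMM <- function(records, trait, includeGxE = TRUE) {
  stopifnot(is(records, "PhenotypeRecords"))
  df <- .lmmFrame(records, trait)
  if (nlevels(df$genotype) < 2) stop("random term 'genotype' has a single level")
  nEnv <- nlevels(df$environment)
  nRep <- nlevels(df$block) / nEnv
  if (nlevels(df$block) < 2) stop("random term 'block' has a single level")

  vnames <- if (includeGxE) c("sigma2_g", "sigma2_ga", "sigma2_b", "sigma2_e")
            else c("sigma2_g", "sigma2_b", "sigma2_e")

  if (var(df$y) < 1e-24) {
    # degenerate: constant response, all components zero
    blup0 <- setNames(rep(0, nlevels(df$genotype)), levels(df$genotype))
    fr <- df; fr$fitted <- df$y; fr$resid <- 0
    return(new("LmmFit", trait = trait, includeGxE = includeGxE,
               varComp = setNames(rep(0, length(vnames)), vnames),
               fixef = c("(Intercept)" = df$y[1]),
               blups = list(genotype = blup0),
               frame = fr, remlLogLik = NA_real_, nObs = nrow(df),
               nEnv = as.integer(nEnv), nRep = nRep, converged = TRUE,
               fingerprint = .fingerprint(df)))
  }

  form <- if (includeGxE)
    y ~ environment + (1 | genotype) + (1 | gxe) + (1 | block)
  else
    y ~ environment + (1 | genotype) + (1 | block)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fm <- tryCatch(
    suppressMessages(lme4::lmer(form, data = df, REML = TRUE, control = ctrl)),
    error = function(e) stop("REML fit failed for trait '", trait, "': ",
                             conditionMessage(e)))

  vc <- as.data.frame(lme4::VarCorr(fm))
  v <- setNames(vc$vcov, vc$grp)
  varComp <- c(sigma2_g = unname(v["genotype"]),
               if (includeGxE) c(sigma2_ga = unname(v["gxe"])),
               sigma2_b = unname(v["block"]),
               sigma2_e = unname(v["Residual"]))

  re <- lme4::ranef(fm)
  blp <- list(genotype = setNames(re$genotype[[1]], rownames(re$genotype)),
              block = setNames(re$block[[1]], rownames(re$block)))
  if (includeGxE)
    blp$gxe <- setNames(re$gxe[[1]], rownames(re$gxe))

  fr <- df
  fr$fitted <- fitted(fm)
  fr$resid <- residuals(fm)

  new("LmmFit", trait = trait, includeGxE = includeGxE,
      varComp = varComp, fixef = lme4::fixef(fm), blups = blp, frame = fr,
      remlLogLik = as.numeric(logLik(fm)), nObs = nrow(df),
      nEnv = as.integer(nEnv), nRep = nRep, converged = TRUE,
      fingerprint = .fingerprint(df))
}

#' AIC and BIC of a REML fit
#'
#' Under REML the parameter count q is the number of estimated variance
#' components (fixed effects are profiled out): AIC = -2l + 2q,
#' BIC = -2l + q log(n).
#'
#' @param fit an \linkS4class{LmmFit}
#' @return named numeric c(AIC, BIC)
#' @export
informationCriteria <- function(fit) {
  stopifnot(is(fit, "LmmFit"))
  q <- length(fit@varComp)
  l <- fit@remlLogLik
  c(AIC = -2 * l + 2 * q, BIC = -2 * l + q * log(fit@nObs))
}

#' Likelihood-ratio test for the genotype-by-environment term
#'
#' Compares the full model (with GxE) to the reduced model (without) on
#' the same data: LRT = 2(l_full - l_reduced), clipped at zero. The
#' default reference distribution is chi-square with 1 df, mirroring the
#' usual reporting convention; \code{boundary = TRUE} uses the
#' 0.5*chi2(0) + 0.5*chi2(1) mixture appropriate for a variance tested at
#' the boundary.
#'
#' @param full,reduced \linkS4class{LmmFit} objects fitted to the same
#'   records (full with GxE, reduced without)
#' @param boundary use the boundary mixture reference distribution
#' @return list: aic_full, bic_full, aic_reduced, bic_reduced, lrt_stat,
#'   lrt_pvalue
#' @export
lrTestGxE <- function(full, reduced, boundary = FALSE) {
  stopifnot(is(full, "LmmFit"), is(reduced, "LmmFit"))
  if (!full@includeGxE || reduced@includeGxE)
    stop("'full' must include the GxE term and 'reduced' must not")
  if (!isTRUE(all.equal(full@fingerprint, reduced@fingerprint,
                        tolerance = 1e-8)))
    stop("full and reduced fits were not made on the same data")
  stat <- max(0, 2 * (full@remlLogLik - reduced@remlLogLik))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary) p <- 0.5 * p + 0.5 * as.numeric(stat <= 0)
  icf <- informationCriteria(full)
  icr <- informationCriteria(reduced)
  list(aic_full = unname(icf["AIC"]), bic_full = unname(icf["BIC"]),
       aic_reduced = unname(icr["AIC"]), bic_reduced = unname(icr["BIC"]),
       lrt_stat = stat, lrt_pvalue = p)
}

#' Entry-mean heritability
#'
#' h2 = sigma2_g / (sigma2_g + sigma2_ga/J + sigma2_e/(J K)) for a trial
#' with J environments and K replicates: the repeatability of a
#' genotype's mean over the whole trial.
#'
#' @param x an \linkS4class{LmmFit} or a named variance-component vector
#'   (sigma2_g, optionally sigma2_ga, sigma2_e)
#' @param nEnv,nRep trial dimensions J and K; taken from the fit when
#'   \code{x} is an LmmFit
#' @return heritability in [0, 1]
#' @examples
#' heritability(c(sigma2_g = 2, sigma2_ga = 1, sigma2_e = 1),
#'              nEnv = 4, nRep = 3)
#' @export
heritability <- function(x, nEnv = NULL, nRep = NULL) {
  if (is(x, "LmmFit")) {
    if (is.null(nEnv)) nEnv <- x@nEnv
    if (is.null(nRep)) nRep <- x@nRep
    x <- x@varComp
  }
  stopifnot(nEnv >= 1, nRep >= 1)
  g <- x[["sigma2_g"]]
  ga <- if ("sigma2_ga" %in% names(x)) x[["sigma2_ga"]] else 0
  e <- x[["sigma2_e"]]
  denom <- g + ga / nEnv + e / (nEnv * nRep)
  if (denom <= 0) stop("all variance components are zero; heritability undefined")
  g / denom
}

#' Adjusted phenotypes Y* from a mixed-model fit
#'
#' The default mode returns the genotype BLUP g_i, one value per
#' genotype, which is what the genome scan consumes. Mode
#' \code{plot_sum} instead sums all random-effect predictions and the
#' residual per plot (i.e. the observation minus the fixed part) and
#' averages these per genotype.
#'
#' @param fit an \linkS4class{LmmFit}
#' @param mode "genotype_blup" (default) or "plot_sum"
#' @return data.frame(genotype, trait, y_star), one row per genotype,
#'   with the mode stored as attribute \code{"mode"}
#' @export
adjustedPhenotypes <- function(fit, mode = c("genotype_blup", "plot_sum")) {
  stopifnot(is(fit, "LmmFit"))
  mode <- match.arg(mode)
  if (mode == "genotype_blup") {
    g <- blups(fit, "genotype")
    out <- data.frame(genotype = names(g), trait = fit@trait,
                      y_star = unname(g))
  } else {
    fr <- fit@frame
    ghat <- blups(fit, "genotype")[as.character(fr$genotype)]
    bhat <- blups(fit, "block")[as.character(fr$block)]
    gahat <- if (fit@includeGxE)
      blups(fit, "gxe")[as.character(fr$gxe)] else 0
    plotsum <- ghat + gahat + bhat + fr$resid
    agg <- tapply(plotsum, as.character(fr$genotype), mean)
    out <- data.frame(genotype = names(agg), trait = fit@trait,
                      y_star = unname(agg))
  }
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Heritabilities and genetic/phenotypic correlations across traits
#'
#' Genetic correlations are Pearson correlations of the per-genotype
#' BLUPs between traits (an approximation to the bivariate REML genetic
#' correlation); phenotypic correlations are Pearson correlations of the
#' plot-level observations matched on (genotype, environment, block).
#'
#' @param fits named list of \linkS4class{LmmFit} objects, one per trait,
#'   fitted on the same plot structure
#' @return list: h2 (named numeric), geneticCor and phenotypicCor
#'   (symmetric matrices, unit diagonal)
#' @export
geneticParameters <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2,
            all(vapply(fits, is, TRUE, "LmmFit")))
  traits <- vapply(fits, function(f) f@trait, "")
  names(fits) <- traits

  gmat <- vapply(fits, function(f) {
    b <- blups(f, "genotype")
    if (sd(b) == 0)
      stop("zero-variance genotype BLUPs for trait '", f@trait, "'")
    b[sort(names(b))]
  }, numeric(length(blups(fits[[1]], "genotype"))))
  geneticCor <- stats::cor(gmat)
  h2 <- vapply(fits, heritability, 0)

  plots <- lapply(fits, function(f) {
    fr <- f@frame
    setNames(fr$y, paste(fr$genotype, fr$block, sep = "/"))
  })
  keys <- Reduce(intersect, lapply(plots, names))
  pmat <- vapply(plots, function(v) v[keys], numeric(length(keys)))
  phenotypicCor <- stats::cor(pmat)

  dimnames(geneticCor) <- dimnames(phenotypicCor) <- list(traits, traits)
  list(h2 = h2, geneticCor = geneticCor, phenotypicCor = phenotypicCor)
}
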