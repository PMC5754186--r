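## Synthetic data with the statistical structure the pipeline assumes:
## Balding-Nichols dosages with optional subpopulation structure, and
## plot-level phenotypes from the same mixed model the adjustment stage
## fits, with causal SNPs acting on the mean (beta) and/or the scale
## (gamma) of the trait distribution.

#' Simulation configuration
#'
#' Defaults mirror a common-bean phenology trial: 80 cultivars x 384
#' SNPs, 4 environments x 3 blocks, trait on the days-to-flowering scale
#' (mean 42.3, plot-level SD about 5.6, entry-mean heritability about
#' 0.54).
#'
#' @param nGeno,nSnp panel dimensions
#' @param mafRange ancestral allele-frequency range, subset of (0, 0.5]
#' @param nSubpop number of subpopulations (genotypes split in equal
#'   blocks)
#' @param fst Balding-Nichols differentiation in [0, 1); 0 = panmictic
#' @param causal data.frame(snp, beta, gamma): column index of each
#'   causal SNP, its additive mean effect (trait units per allele) and
#'   its multiplicative scale effect per allele on the residual SD
#' @param mu trait mean
#' @param sigma2GPoly polygenic genotype variance
#' @param sigma2GA genotype-by-environment variance
#' @param sigma2B block-within-environment variance
#' @param sigma2E residual plot variance
#' @param nEnv,nRep environments and blocks per environment
#' @param envSpan range of the fixed environment effects (equally
#'   spaced, centered on zero)
#' @param trait trait label
#' @param seed RNG seed; every simulation is reproducible given the
#'   config
#' @return list of class \code{SimConfig}
#' @export
simConfig <- function(nGeno = 80L, nSnp = 384L, mafRange = c(0.05, 0.5),
                      nSubpop = 2L, fst = 0.05, causal = NULL, mu = 42.3,
                      sigma2GPoly = 4, sigma2GA = 8, sigma2B = 2,
                      sigma2E = 17, nEnv = 4L, nRep = 3L, envSpan = 6,
                      trait = "DTF", seed = 1L) {
  if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
    stop("mafRange must lie within (0, 0.5]")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (!is.null(causal)) {
    stopifnot(is.data.frame(causal),
              all(c("snp", "beta", "gamma") %in% names(causal)))
    if (any(causal$snp < 1 | causal$snp > nSnp))
      stop("causal snp indices must lie in 1..nSnp")
  }
  vs <- c(sigma2GPoly, sigma2GA, sigma2B, sigma2E)
  if (any(vs < 0)) stop("variances must be >= 0")
  structure(list(nGeno = as.integer(nGeno), nSnp = as.integer(nSnp),
                 mafRange = mafRange, nSubpop = as.integer(nSubpop),
                 fst = fst, causal = causal, mu = mu,
                 sigma2GPoly = sigma2GPoly, sigma2GA = sigma2GA,
                 sigma2B = sigma2B, sigma2E = sigma2E,
                 nEnv = as.integer(nEnv), nRep = as.integer(nRep),
                 envSpan = envSpan, trait = trait, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a SNP dosage panel (Balding-Nichols)
#'
#' Per SNP, an ancestral frequency p is drawn uniformly from
#' \code{mafRange}; with \code{fst > 0} each subpopulation draws its own
#' frequency from Beta(p(1-F)/F, (1-p)(1-F)/F), and dosages are
#' Binomial(2, subpopulation frequency). Genotypes are assigned to
#' subpopulations in equal blocks. SNPs are spread over the Pv01..Pv11
#' chromosomes with uniform positions.
#'
#' @param cfg a \code{\link{simConfig}}
#' @return list: \code{genotypes} (\linkS4class{GenotypeDosage}) and
#'   \code{truth} (subpopulation labels, ancestral and subpopulation
#'   frequencies)
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$nGeno; m <- cfg$nSnp
  p0 <- runif(m, cfg$mafRange[1], cfg$mafRange[2])
  subpop <- rep(seq_len(cfg$nSubpop), length.out = n)
  subpop <- sort(subpop)                      # equal consecutive blocks
  if (cfg$fst > 0 && cfg$nSubpop > 1) {
    Fst <- cfg$fst
    pk <- matrix(rbeta(cfg$nSubpop * m,
                       rep(p0, each = cfg$nSubpop) * (1 - Fst) / Fst,
                       rep(1 - p0, each = cfg$nSubpop) * (1 - Fst) / Fst),
                 nrow = cfg$nSubpop)
    pk <- pmin(pmax(pk, 1e-6), 1 - 1e-6)
  } else {
    pk <- matrix(rep(p0, each = cfg$nSubpop), nrow = max(1L, cfg$nSubpop))
  }
  D <- matrix(rbinom(n * m, 2L, pk[subpop, ]), nrow = n)
  dimnames(D) <- list(sprintf("G%03d", seq_len(n)),
                      sprintf("snp%04d", seq_len(m)))
  chrom <- PV_CHROMOSOMES[1 + (seq_len(m) - 1) %% length(PV_CHROMOSOMES)]
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(5e7, length(ix)))), use.names = FALSE)
  map <- data.frame(snp_id = colnames(D), chrom = chrom, pos_bp = pos)
  list(genotypes = GenotypeDosage(D, map),
       truth = list(subpop = setNames(subpop, rownames(D)),
                    ancestralFreq = p0, subpopFreq = pk))
}

.causalEffects <- function(D, cfg) {
  n <- nrow(D)
  betaSum <- numeric(n); gammaSum <- numeric(n)
  if (!is.null(cfg$causal)) {
    for (r in seq_len(nrow(cfg$causal))) {
      x <- D[, cfg$causal$snp[r]]
      betaSum <- betaSum + x * cfg$causal$beta[r]
      gammaSum <- gammaSum + x * cfg$causal$gamma[r]
    }
  }
  list(betaSum = betaSum, gammaSum = gammaSum)
}

#' Simulate plot-level phenotypes from a dosage panel
#'
#' y_ijk = mu + g_i + a_j + ga_ij + b_k(j) + e_ijk with fixed equally
#' spaced environment effects a_j, genotype values
#' g_i = sum_c x_ic beta_c + u_i (u polygenic), and heteroscedastic
#' residuals e_ijk ~ N(0, [sd_e (1 + sum_c x_ic gamma_c)]^2); the scale
#' factor is floored at 0.1 to stay positive (a warning names the
#' fraction of floored plots when it exceeds 1 percent).
#'
#' @param g a \linkS4class{GenotypeDosage} (typically from
#'   \code{\link{simulateGenotypes}})
#' @param cfg the same \code{\link{simConfig}}
#' @param geneticValues optional named vector overriding the simulated
#'   genotype values g_i (used e.g. to induce genetic correlation
#'   between two traits)
#' @return list: \code{records} (\linkS4class{PhenotypeRecords}) and
#'   \code{truth} (genetic values, causal table, environment effects,
#'   realized components)
#' @export
simulatePhenotypes <- function(g, cfg, geneticValues = NULL) {
  stopifnot(is(g, "GenotypeDosage"), inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 1L)
  D <- dosages(g)
  n <- nrow(D)
  ids <- rownames(D)
  eff <- .causalEffects(D, cfg)
  u <- rnorm(n, 0, sqrt(cfg$sigma2GPoly))
  gi <- if (is.null(geneticValues)) eff$betaSum + u
        else unname(geneticValues[ids])
  aEnv <- if (cfg$nEnv == 1) 0 else
    seq(-cfg$envSpan / 2, cfg$envSpan / 2, length.out = cfg$nEnv)
  scl <- 1 + eff$gammaSum
  floored <- scl < 0.1
  if (mean(floored) > 0.01)
    warning(sprintf("scale factor floored at 0.1 for %.1f%% of genotypes",
                    100 * mean(floored)))
  scl <- pmax(scl, 0.1)

  df <- expand.grid(genotype = ids, environment = sprintf("E%d", seq_len(cfg$nEnv)),
                    block = sprintf("B%d", seq_len(cfg$nRep)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  iG <- match(df$genotype, ids)
  iE <- match(df$environment, sprintf("E%d", seq_len(cfg$nEnv)))
  ga <- matrix(rnorm(n * cfg$nEnv, 0, sqrt(cfg$sigma2GA)), n, cfg$nEnv)
  bb <- matrix(rnorm(cfg$nEnv * cfg$nRep, 0, sqrt(cfg$sigma2B)),
               cfg$nEnv, cfg$nRep)
  iB <- match(df$block, sprintf("B%d", seq_len(cfg$nRep)))
  e <- rnorm(nrow(df), 0, sqrt(cfg$sigma2E) * scl[iG])
  df$trait <- cfg$trait
  df$value <- cfg$mu + gi[iG] + aEnv[iE] + ga[cbind(iG, iE)] +
    bb[cbind(iE, iB)] + e
  rec <- PhenotypeRecords(df[, c("genotype", "environment", "block",
                                 "trait", "value")])
  list(records = rec,
       truth = list(geneticValues = setNames(gi, ids),
                    polygenic = setNames(u, ids), causal = cfg$causal,
                    envEffects = aEnv, scaleFactor = setNames(scl, ids),
                    gxe = ga, blockEffects = bb))
}

#' Simulate a genotype-level trait (no trial structure)
#'
#' One value per genotype: y_i = mu + sum_c x_ic beta_c + u_i +
#' sd_e (1 + sum_c x_ic gamma_c) z_i with z standard normal. This is the
#' reduced form of the plot model used for estimator studies: for a
#' single causal SNP with mean effect beta and scale effect gamma (and
#' no polygenic term), the population quantile-regression slope at tau
#' is beta + gamma * sd_e * qnorm(tau).
#'
#' @inheritParams simulatePhenotypes
#' @return list: \code{y} (named vector) and \code{truth}
#' @export
simulateTrait <- function(g, cfg) {
  stopifnot(is(g, "GenotypeDosage"), inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 2L)
  D <- dosages(g)
  n <- nrow(D)
  eff <- .causalEffects(D, cfg)
  u <- rnorm(n, 0, sqrt(cfg$sigma2GPoly))
  scl <- pmax(1 + eff$gammaSum, 0.1)
  y <- cfg$mu + eff$betaSum + u + sqrt(cfg$sigma2E) * scl * rnorm(n)
  list(y = setNames(y, rownames(D)),
       truth = list(betaSum = eff$betaSum, polygenic = u,
                    scaleFactor = scl))
}
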