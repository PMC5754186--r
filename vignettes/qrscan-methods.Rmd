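---
title: "Quantile-regression genome scans for multi-environment plant trials"
author: "qrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-regression genome scans for multi-environment plant trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrscan)
```

## The problem

Single-marker GWAS in small plant panels (here: on the order of 80
cultivars genotyped at a few hundred SNPs, phenotyped for phenology
traits such as days to flowering in a randomized complete block design
over several environments) is chronically under-powered for mean
effects. Some variants, however, act on the *shape* of the trait
distribution — they widen or shift one tail without moving the mean.
Ordinary least squares cannot see them; quantile regression (QR) can,
because it estimates the conditional quantile `Q_tau(Y | x)` for any
`tau` in (0, 1) and therefore measures a SNP's effect separately at
each part of the distribution. qrscan implements the two-stage pipeline
this idea requires, plus the simulator needed to validate every stage
without external data.

## Stage one: phenotype adjustment

Plot-level observations follow

$$y_{ijk} = \mu + g_i + a_j + ga_{ij} + b_{k(j)} + e_{ijk},$$

with fixed environment effects $a_j$ and independent normal random
effects for genotype ($\sigma^2_g$), genotype-by-environment
($\sigma^2_{ga}$), block within environment ($\sigma^2_b$) and plot
residual ($\sigma^2_e$). `fitPhenoLMM()` fits this by REML (via lme4;
any REML maximizer agrees at the optimum, and the test suite checks the
reported optimum against a dense-matrix restricted-likelihood oracle on
a surrounding grid). `lrTestGxE()` compares the full model against the
model without the interaction term: AIC/BIC under the REML convention
(`q` = number of variance parameters) and a likelihood-ratio statistic
referred to $\chi^2_1$ by default. Because the interaction variance sits
on the boundary of its parameter space under the null, the
$\chi^2_1$ reference is conservative; the
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture is available via
`boundary = TRUE`.

Entry-mean heritability uses the standard plant-breeding form for a
trial with $J$ environments and $K$ replicates,

$$h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ga}/J +
\sigma^2_e/(JK)},$$

i.e. the repeatability of a cultivar mean over the whole trial.

The scan consumes **adjusted phenotypes** $Y^*$. Two readings of
"sum of random effects" are defensible, so both are implemented:
`genotype_blup` (the default; one BLUP $\hat g_i$ per genotype, which
matches a scan objective summing over the genotypes) and `plot_sum`
(per-plot $\hat g_i + \hat{ga}_{ij} + \hat b_{k(j)} + \hat e_{ijk}$,
averaged per genotype). Under a balanced design both rank genotypes
identically. Genetic correlations are Pearson correlations of genotype
BLUPs between traits — an approximation to the bivariate REML genetic
correlation, adequate at moderate heritability and documented as such;
phenotypic correlations pair plot observations.

## Stage two: the scans

Population structure is summarized by covariance PCA of the centered
dosage matrix (`genotypePCA()`; correlation PCA by `scale = TRUE`).
Component signs are fixed by making the largest-magnitude loading
positive. The number of covariates defaults to 7 — the convention for this
panel, where the top seven components carry roughly 82% of the
genotypic variance — but
`selectPCs()` also supports a cumulative-variance rule because no
numeric selection rule is canonical when the choice is made from a
scree plot.

The traditional scan (`olsScan()`) regresses $Y^*$ on intercept +
dosage + PCs, one SNP at a time, with a two-sided t test on the
allele-substitution slope.

The QR scan (`qrScan()`) fits, for each SNP and each
$\tau \in \{0.1, \dots, 0.9\}$,

$$\hat\theta_\tau = \arg\min_\theta \sum_i \rho_\tau\!\left(y^*_i -
x_i'\theta\right), \qquad \rho_\tau(u) = u(\tau - I(u < 0)).$$

The estimator is the exact linear program
$\min \tau 1'u + (1-\tau)1'v$ s.t. $X\beta + u - v = y$, $u, v \ge 0$,
solved in compiled code by a vertex-exchange simplex (the
Barrodale–Roberts long-step rule). A vertex interpolates exactly $p$
observations; when the minimizer is an interval (e.g. the even-$n$
median) the returned vertex is one endpoint, which is standard LP
behavior and is left as-is. The returned objective is recomputed from
the residuals, and the test suite checks it against brute-force vertex
enumeration and an independent QR implementation to $10^{-8}$.

Goodness of fit per SNP is the Koenker–Machado
$R_1(\tau) = 1 - \hat V_{\mathrm{full}}/\hat V_{\mathrm{null}}$, with
the null containing intercept and PCs at the same $\tau$, so the
reported percentage isolates the SNP's contribution. ("Variance
explained" has no unique definition in QR; this is the choice made
here and it is not comparable to an OLS $R^2$.)

## Inference: why the default is the rank-score test

Three tests are implemented in `qrTest()`:

* **score** (default): the regression rank-score test. The model is
  refitted without the tested column; the dual values of that null fit
  (each in $[\tau-1, \tau]$, extracted exactly from the simplex
  solution) are contrasted with the tested column residualized on the
  null design; the statistic is asymptotically normal with variance
  $\tau(1-\tau)\sum \tilde x_i^2$. No density estimation is involved.
* **wald_nid**: sandwich standard errors with the local sparsity
  estimated by a difference quotient of fitted quantiles at
  $\tau \pm h$, $h$ the Hall–Sheather bandwidth at the 5% level,
  clamped (with a warning) when $\tau \pm h$ leaves (0, 1). Density
  weights are floored at a tiny positive value so the weighted
  cross-product stays invertible for near-monomorphic columns.
* **bootstrap_xy**: (x, y)-pair resampling with a normal approximation,
  reproducible given a seed; requires B ≥ 200.

The scan default matters. At central quantiles and small designs the
Wald test is well calibrated (its measured size at $\tau = 0.5$,
$n = 80$, $p = 2$ is within the nominal band, and its standard errors
reproduce the reference sandwich implementation to seven decimals).
But at $\tau = 0.1$ with $n = 80$ and seven PC covariates its size
inflates severely — the local density estimate at an extreme quantile
with many covariates is too unstable — and a Bonferroni scan built on
it has a family-wise error rate near 1 rather than 0.05. The
rank-score test keeps its level under the same conditions (it is, if
anything, conservative at extreme quantiles, because the effective
variance of the rank scores after fitting $p$ parameters is slightly
below $\tau(1-\tau)$). It is therefore the default for `qrScan()`,
and it is also dramatically cheaper: the null fit is shared by every
SNP at a given $\tau$. The Wald and bootstrap tests remain available
as cross-checks of each other, which is how the test suite uses them.

Degenerate designs are never turned into p-values: SNPs whose dosage is
collinear with the covariates (or monomorphic) are skipped and listed
in the scan metadata.

## Thresholds and significance

`bonferroniThreshold(m, alpha)` returns $-\log_{10}(\alpha/m)$; for the
384-SNP panel this gives 3.8853 and 4.5843 at the 5% and 1% levels,
truncated to 3.88 / 4.58 for display (comparisons always use full
precision, and a record exactly at the threshold counts as
significant). `m` is the number of SNPs actually tested after
filtering, which the scan records prominently in its metadata. No
additional multiplicity correction is applied across the nine
quantiles — the same two lines are drawn on every quantile's Manhattan
panel, mirroring standard practice for this analysis; this is a
documented caveat, not an oversight.

## The simulator

`simulateGenotypes()` draws ancestral frequencies uniformly from
`mafRange`, subpopulation frequencies from the Balding–Nichols
Beta distribution indexed by `fst`, and dosages Binomial(2, freq), with
genotypes assigned to subpopulations in equal blocks and SNPs spread
over the 11 Pv chromosomes. `simulatePhenotypes()` generates plot-level
data from exactly the mixed model of stage one, with causal SNPs acting
additively on the mean (`beta`, trait units per allele) and/or
multiplicatively on the residual SD (`gamma`): $e_{ijk} \sim N(0,
[\sigma_e(1 + \sum_c x_{ic}\gamma_c)]^2)$, the scale factor floored at
0.1 (a warning reports when more than 1% of genotypes are floored).
`simulateTrait()` is the genotype-level reduced form used in estimator
studies; for a single causal SNP with no polygenic term its population
QR slope at $\tau$ is exactly $\beta + \gamma\sigma_e z_\tau$
($z_\tau$ the standard normal quantile), which provides the closed-form
oracle for the slope-recovery study. The scale architecture was chosen
as the canonical quantile-specific model precisely because of this
closed form.

Defaults mirror the motivating trial: 80 genotypes x 384 SNPs, 4
environments x 3 blocks, trait mean 42.3 days, components
$\sigma^2 = (4, 8, 2, 17)$ giving a plot-level SD near 5.6 days and an
entry-mean $h^2$ near 0.54 — the scale of a days-to-flowering trait
with moderate heritability. Environments enter as known equally spaced
fixed effects (span 6 days) so that adjustment is exercised
non-trivially.

What the simulator does *not* emulate, and what passing tests therefore
do not establish about real data: linkage disequilibrium (SNPs are
independent), dominance and epistasis, spatial field trends,
heterogeneous residual variances across environments, genotype-calling
error, and non-normal residuals other than the mixture induced by scale
effects.

## Validation studies and the sizes used

The package's acceptance studies, rerun from scratch by
`scripts/acceptance.R` and mirrored in the test suite, are:

* solver exactness on 100 random small instances against brute-force
  vertex enumeration;
* slope recovery at $n = 2000$, 500 replicates, $\tau \in \{0.1, 0.5,
  0.9\}$ against the analytic $\gamma\sigma_e z_\tau$;
* a power study at $n = 80$, one scale-effect SNP in a 100-SNP
  panmictic panel, both scans called at their 5% Bonferroni line. The
  causal effect ($\gamma = 4$ at MAF 0.2) was calibrated once, on a
  separate grid, so that the $\tau = 0.1$ rank-score scan sits near 60%
  power; the traditional scan stays below 10% because a pure scale
  effect leaves the mean untouched. Power against scale alternatives at
  $n = 80$ is intrinsically bounded for any test with valid size — the
  Fisher information per observation for a variance effect saturates in
  $\gamma$ — which is why the calibration pushes toward a low MAF,
  where rare large-variance carriers generate extreme lower-tail
  observations;
* a permutation family-wise-error study at the full 80 x 384 scale
  with 7 PCs, 200 permutations, for both scans;
* REML component recovery and the GxE likelihood-ratio test at the
  trial's dimensions, 200 and 150 replicates. One recovery bound is
  knowingly not met: the block-within-environment variance is estimated
  from only 12 block levels (about 8–11 effective degrees of freedom),
  so its median relative error is around 0.3 for *any* estimator; the
  corresponding check is left failing rather than weakened, and the
  genotype, interaction and residual components do meet their bounds.

## Numerical choices

* Simplex tolerances: residuals within `1e-9 * max(1, |y|_inf)` of zero
  are treated as interpolated; optimality requires every edge
  directional derivative above `-1e-9 * sqrt(n)`; iterations are capped
  at `200 + 50n` (exceeding the cap is reported as an error, never as a
  silent approximate solution).
* Dosage coding is 0/1/2 counts of the alternate allele (heterozygote
  1), the additive coding implied by an allele-substitution effect.
  Missing dosages are mean-imputed per SNP — deterministic, mean
  preserving, and adequate at the low missingness of a validated
  fixed panel; monomorphic SNPs are dropped with a logged list.
* Positions are stored in base pairs and reported in Mb with two
  decimals.
* p-values are floored at 1e-320 before taking logs so that
  `minus_log10_p` stays finite.

## Limitations

Kinship-based mixed-model association (beyond PC adjustment), LD-aware
clumping, FDR or permutation thresholds, bivariate REML, VCF/PLINK
input and quantile-crossing constraints across the $\tau$ grid are out
of scope. P-values from different QR inference methods can differ
noticeably at extreme quantiles and small n; scans report which method
produced them.
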