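## Check-loss quantile regression: estimator, inference, goodness of fit.
##
## The fit solves the linear program
##   min tau * 1'u + (1 - tau) * 1'v  s.t.  X b + u - v = y, u, v >= 0
## exactly, returning a vertex solution that interpolates p observations
## (see src/qr_simplex.cpp).

#' The check (pinball) loss
#'
#' rho_tau(e) = tau * e for e >= 0 and -(1 - tau) * e for e < 0. Its
#' minimizer over a constant is the empirical tau-quantile.
#'
#' @param eps numeric residual(s)
#' @param tau quantile in (0, 1)
#' @return non-negative numeric of the same length as \code{eps}
#' @examples
#' checkLoss(2, 0.1)    # 0.2
#' checkLoss(-2, 0.1)   # 1.8
#' @export
checkLoss <- function(eps, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1)
    stop("tau must be a single number in (0, 1)")
  eps * (tau - (eps < 0))
}

#' Fit quantile regression at one quantile
#'
#' @param X n x p design matrix (full column rank, n > p)
#' @param y length-n response
#' @param tau quantile in (0, 1)
#' @return A \linkS4class{QRFit}. The coefficients are a vertex solution
#'   of the check-loss linear program; when the minimizer is an interval
#'   (e.g. the even-n median), the returned vertex is one endpoint.
#' @examples
#' fit <- fitQuantile(cbind(1, c(0, 1, 2, 0, 1)), c(1, 3, 5, 2, 2), 0.5)
#' fit@coef
#' @export
fitQuantile <- function(X, y, tau) {
  X <- as.matrix(X)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1)
    stop("tau must be a single number in (0, 1)")
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (n <= p) stop("need n > p")
  res <- .qr_fit_cpp(X, y, tau)
  if (!identical(res$status, "optimal")) {
    if (identical(res$status, "rank_deficient"))
      stop("design matrix is rank deficient")
    stop("quantile regression solver failed (", res$status,
         ") after ", res$iter, " iterations")
  }
  cf <- as.numeric(res$coef)
  names(cf) <- colnames(X)
  new("QRFit", tau = tau, coef = cf, objective = res$objective,
      residuals = as.numeric(res$residuals), dual = as.numeric(res$dual),
      basis = as.integer(res$basis), iter = as.integer(res$iter))
}

## Hall-Sheather bandwidth for the sparsity difference quotient
.hallSheather <- function(tau, n, alpha = 0.05) {
  z <- qnorm(tau)
  n^(-1/3) * qnorm(1 - alpha / 2)^(2/3) *
    ((1.5 * dnorm(z)^2) / (2 * z^2 + 1))^(1/3)
}

.waldNid <- function(X, y, fit) {
  n <- nrow(X); tau <- fit@tau
  eps <- .Machine$double.eps^(2/3)
  h <- .hallSheather(tau, n)
  tl <- tau - h; tu <- tau + h
  if (tl <= 0 || tu >= 1) {
    warning("Hall-Sheather band tau +/- ", signif(h, 3),
            " leaves (0, 1); clamping")
    tl <- max(tl, eps); tu <- min(tu, 1 - eps)
  }
  bl <- fitQuantile(X, y, tl)@coef
  bu <- fitQuantile(X, y, tu)@coef
  dyhat <- as.numeric(X %*% (bu - bl))
  f <- pmax(0, (tu - tl) / (dyhat - eps))
  f <- pmax(f, 1e-6 * max(f))          # guard exact singularity of X'FX
  H <- crossprod(X * sqrt(f))
  J <- crossprod(X)
  Hi <- solve(H)
  V <- tau * (1 - tau) * Hi %*% J %*% Hi
  se <- sqrt(pmax(diag(V), 0))
  z <- fit@coef / se
  list(estimate = fit@coef, se = setNames(se, names(fit@coef)),
       p_value = setNames(2 * pnorm(-abs(z)), names(fit@coef)))
}

.bootstrapXY <- function(X, y, fit, B, seed) {
  if (B < 200) stop("bootstrap requires B >= 200")
  n <- nrow(X); p <- ncol(X)
  bs <- matrix(NA_real_, B, p)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- .qr_fit_cpp(X[idx, , drop = FALSE], y[idx], fit@tau)
    if (identical(r$status, "optimal")) bs[b, ] <- r$coef
  }
  se <- apply(bs, 2, sd, na.rm = TRUE)
  z <- fit@coef / se
  list(estimate = fit@coef, se = setNames(se, names(fit@coef)),
       p_value = setNames(2 * pnorm(-abs(z)), names(fit@coef)))
}

.rankScore <- function(X, y, fit, columns) {
  tau <- fit@tau
  n <- nrow(X)
  out_se <- out_p <- setNames(rep(NA_real_, ncol(X)), names(fit@coef))
  for (j in columns) {
    X0 <- X[, -j, drop = FALSE]
    f0 <- fitQuantile(X0, y, tau)
    psi <- f0@dual
    xt <- X[, j] - X0 %*% qr.coef(qr(X0), X[, j])
    ssx <- sum(xt^2)
    if (ssx < 1e-10 * (sum(X[, j]^2) + 1)) next   # collinear with null design
    S <- sum(xt * psi)
    V <- tau * (1 - tau) * ssx
    out_se[j] <- sqrt(V) / ssx      # se on the coefficient scale (approx)
    out_p[j] <- 2 * pnorm(-abs(S / sqrt(V)))
  }
  list(estimate = fit@coef, se = out_se, p_value = out_p)
}

#' Inference for quantile-regression coefficients
#'
#' Three methods. \code{"score"} (default) is the regression rank-score
#' test: each tested coefficient is set to zero, the model is refitted,
#' and the score statistic contrasts the dual (rank-score) values of the
#' null fit with the tested column residualized on the null design. It
#' involves no density estimation and keeps its size at small n and
#' extreme tau. \code{"wald_nid"} uses sandwich standard errors with a
#' local sparsity estimate (difference quotient of fitted quantiles at
#' tau +/- the Hall-Sheather bandwidth); it is well calibrated for small
#' designs at central quantiles but becomes anticonservative at extreme
#' quantiles with many covariates. \code{"bootstrap_xy"} resamples (x, y)
#' pairs and uses the normal approximation to the bootstrap distribution.
#'
#' @param X,y the design and response used for \code{fit}
#' @param fit a \linkS4class{QRFit} from \code{\link{fitQuantile}}
#' @param method "score", "wald_nid" or "bootstrap_xy"
#' @param columns which coefficients to test with the score method
#'   (default: all but the first, assumed intercept)
#' @param B bootstrap replicates (>= 200)
#' @param seed RNG seed for the bootstrap (results are reproducible)
#' @return list with elements \code{estimate}, \code{se}, \code{p_value}
#'   (named per coefficient) and \code{method}
#' @export
qrTest <- function(X, y, fit, method = c("score", "wald_nid", "bootstrap_xy"),
                   columns = NULL, B = 1000L, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  stopifnot(is(fit, "QRFit"), nrow(X) == length(y))
  out <- switch(method,
    score = {
      if (is.null(columns)) columns <- setdiff(seq_len(ncol(X)), 1L)
      .rankScore(X, y, fit, columns)
    },
    wald_nid = .waldNid(X, y, fit),
    bootstrap_xy = .bootstrapXY(X, y, fit, B, seed))
  out$method <- method
  out
}

#' Koenker-Machado pseudo-R1 goodness of fit
#'
#' R1(tau) = 1 - V_full / V_null, where V is the minimized check loss of
#' the full model and of the null model (intercept plus any covariates
#' retained under the null). Isolates the contribution of the added
#' predictor(s) at quantile tau.
#'
#' @param objectiveFull,objectiveNull minimized check-loss objectives,
#'   with \code{objectiveNull >= objectiveFull >= 0}
#' @return R1 in [0, 1]
#' @export
pseudoR1 <- function(objectiveFull, objectiveNull) {
  if (objectiveNull <= 0)
    stop("null objective is zero: degenerate (constant) response")
  if (objectiveFull < 0 || objectiveFull > objectiveNull + 1e-12)
    stop("need objectiveNull >= objectiveFull >= 0")
  max(0, min(1, 1 - objectiveFull / objectiveNull))
}
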