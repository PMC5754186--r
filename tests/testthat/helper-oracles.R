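# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: brute-force enumeration for the check-loss
# minimum, a dense matrix evaluation of the restricted log-likelihood,
# and direct normal-equations least squares.

# check-loss objective of a candidate coefficient vector
obj_check <- function(X, y, beta, tau) {
  r <- y - as.numeric(as.matrix(X) %*% beta)
  sum(r * (tau - (r < 0)))
}

# intercept-only: an optimum is attained at one of the data points
brute_qr_intercept <- function(y, tau) {
  min(vapply(y, function(c) sum((y - c) * (tau - ((y - c) < 0))), 0))
}

# general small case: enumerate all vertices (exact fits of p points)
brute_qr_vertex <- function(X, y, tau) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  best <- Inf
  for (idx in utils::combn(n, p, simplify = FALSE)) {
    Xh <- X[idx, , drop = FALSE]
    if (abs(det(Xh)) < 1e-10) next
    beta <- solve(Xh, y[idx])
    best <- min(best, obj_check(X, y, beta, tau))
  }
  best
}

# dense restricted log-likelihood of the plot model at given components.
# df must have factors genotype, environment, block, gxe and response y.
reml_loglik_dense <- function(df, sg, sga, sb, se, includeGxE = TRUE) {
  n <- nrow(df)
  X <- stats::model.matrix(~ environment, df)
  Zg <- stats::model.matrix(~ 0 + genotype, df)
  Zb <- stats::model.matrix(~ 0 + block, df)
  V <- se * diag(n) + sg * tcrossprod(Zg) + sb * tcrossprod(Zb)
  if (includeGxE) {
    Zga <- stats::model.matrix(~ 0 + gxe, df)
    V <- V + sga * tcrossprod(Zga)
  }
  cV <- chol(V)
  logdetV <- 2 * sum(log(diag(cV)))
  Vi_y <- backsolve(cV, forwardsolve(t(cV), df$y))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, Vi_X)
  cX <- chol(XtViX)
  logdetX <- 2 * sum(log(diag(cX)))
  bhat <- solve(XtViX, crossprod(X, Vi_y))
  r <- df$y - X %*% bhat
  Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
  quad <- sum(r * Vi_r)
  p <- ncol(X)
  -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetX + quad)
}

# the model frame the package builds internally, reproduced here so the
# oracle does not depend on unexported helpers
lmm_frame <- function(records, trait) {
  r <- phenoRecords(records)
  r <- r[r$trait == trait, , drop = FALSE]
  data.frame(genotype = factor(r$genotype),
             environment = factor(r$environment),
             block = factor(paste(r$environment, r$block, sep = ":")),
             gxe = factor(paste(r$genotype, r$environment, sep = ":")),
             y = r$value)
}
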