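// Exact check-loss quantile regression by vertex exchange.
//
// The estimator solves min_b sum_i rho_tau(y_i - x_i' b), the linear
// program  min tau*1'u + (1-tau)*1'v  s.t.  Xb + u - v = y, u,v >= 0.
// A vertex of this LP fits p = ncol(X) observations exactly; the solver
// walks between such vertices (simplex steps with the long-step line
// search of Barrodale & Roberts), so the returned solution is an exact
// basic solution, not an interior-point approximation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// one-sided derivative of rho_tau at residual 0 when the residual moves
// at rate -d (i.e. x_i'beta moves at rate +d)
static inline double rho_dir0(double d, double tau) {
  return (d <= 0.0) ? (-tau * d) : ((1.0 - tau) * d);
}

// greedy selection of p linearly independent rows (modified Gram-Schmidt)
static bool initial_basis(const mat& X, uvec& h) {
  const uword n = X.n_rows, p = X.n_cols;
  mat Q(p, p, fill::zeros);
  uword got = 0;
  h.set_size(p);
  for (uword i = 0; i < n && got < p; ++i) {
    vec v = X.row(i).t();
    double nrm0 = norm(v);
    if (nrm0 <= 0) continue;
    for (uword j = 0; j < got; ++j) v -= dot(Q.col(j), v) * Q.col(j);
    double nrm = norm(v);
    if (nrm > 1e-10 * (nrm0 + 1e-300)) {
      Q.col(got) = v / nrm;
      h(got) = i;
      ++got;
    }
  }
  return got == p;
}

// [[Rcpp::export(name = ".qr_fit_cpp")]]
Rcpp::List qr_fit_cpp(const arma::mat& X, const arma::vec& y, double tau,
                      int maxit = 0) {
  const uword n = X.n_rows, p = X.n_cols;
  if (maxit <= 0) maxit = 200 + 50 * (int)n;

  uvec h;
  if (!initial_basis(X, h))
    return Rcpp::List::create(Rcpp::Named("status") = "rank_deficient");

  const double yscale = std::max(1.0, norm(y, "inf"));
  const double rtol   = 1e-9 * yscale;   // residual-is-zero tolerance
  const double dtol   = 1e-9 * std::sqrt((double)n); // optimality slack

  vec beta(p), r(n);
  mat Xh(p, p);
  int iter = 0;
  std::string status = "maxit";

  for (iter = 0; iter < maxit; ++iter) {
    // vertex solve: residuals of basis rows are exactly zero
    for (uword j = 0; j < p; ++j) Xh.row(j) = X.row(h(j));
    bool ok = solve(beta, Xh, y.elem(h), solve_opts::no_approx);
    if (!ok) { status = "singular_basis"; break; }
    r = y - X * beta;
    r.elem(h).zeros();

    // subgradient of the smooth part (rows with nonzero residual, off basis)
    vec c(n, fill::zeros);
    std::vector<uword> zoff;   // off-basis rows with zero residual
    uvec inbasis(n, fill::zeros);
    for (uword j = 0; j < p; ++j) inbasis(h(j)) = 1;
    for (uword i = 0; i < n; ++i) {
      if (inbasis(i)) continue;
      if (r(i) > rtol)       c(i) = -tau;
      else if (r(i) < -rtol) c(i) = 1.0 - tau;
      else { r(i) = 0.0; zoff.push_back(i); }
    }
    vec g = X.t() * c;                 // gradient contribution
    vec phi = solve(Xh.t(), g, solve_opts::no_approx); // phi_k = g' * (Xh^{-1} e_k)

    // directional derivatives for the 2p edge directions at this vertex
    // direction (k, s): delta = s * Xh^{-1} e_k, so x_{h_k}' delta = s
    double bestT = -dtol;
    int bestk = -1, bests = 0;
    mat Dz;                            // x_i' Xh^{-1} for zero-residual rows
    if (!zoff.empty()) {
      mat Xz(zoff.size(), p);
      for (uword t = 0; t < zoff.size(); ++t) Xz.row(t) = X.row(zoff[t]);
      Dz = solve(Xh.t(), Xz.t(), solve_opts::no_approx).t();
    }
    for (uword k = 0; k < p; ++k) {
      for (int s = -1; s <= 1; s += 2) {
        double T = s * phi(k) + (s > 0 ? (1.0 - tau) : tau);
        if (!zoff.empty())
          for (uword t = 0; t < zoff.size(); ++t)
            T += rho_dir0(s * Dz(t, k), tau);
        if (T < bestT) { bestT = T; bestk = (int)k; bests = s; }
      }
    }
    if (bestk < 0) { status = "optimal"; break; }

    // move along delta; d_i = x_i' delta
    vec ek(p, fill::zeros); ek((uword)bestk) = 1.0;
    vec dir = solve(Xh, ek, solve_opts::no_approx) * (double)bests;
    vec d = X * dir;

    // long-step line search over residual zero crossings t_i = r_i / d_i
    std::vector<std::pair<double, uword>> cross;
    cross.reserve(n);
    for (uword i = 0; i < n; ++i) {
      if (inbasis(i)) continue;
      if (std::abs(d(i)) < 1e-12) continue;
      if (r(i) == 0.0) continue;       // accounted for exactly in T
      double ti = r(i) / d(i);
      if (ti > 0) cross.emplace_back(ti, i);
    }
    if (cross.empty()) { status = "degenerate"; break; }
    std::sort(cross.begin(), cross.end());

    double slope = bestT;
    uword enter = cross.back().second;
    for (auto& cr : cross) {
      slope += std::abs(d(cr.second));
      if (slope >= 0) { enter = cr.second; break; }
    }
    h((uword)bestk) = enter;
  }

  if (status == "maxit" || status == "degenerate" || status == "singular_basis")
    return Rcpp::List::create(Rcpp::Named("status") = status,
                              Rcpp::Named("iter") = iter);

  // exact objective at the vertex
  double obj = 0.0;
  for (uword i = 0; i < n; ++i)
    obj += (r(i) >= 0) ? tau * r(i) : -(1.0 - tau) * r(i);

  // dual values psi_i in [tau-1, tau] with X'psi = 0 at the optimum:
  // off-basis rows take tau - I(r<0); basis rows solve the p x p system
  const double rtol2 = 1e-9 * std::max(1.0, norm(y, "inf"));
  vec psi(n);
  uvec inb(n, fill::zeros);
  for (uword j = 0; j < p; ++j) inb(h(j)) = 1;
  for (uword i = 0; i < n; ++i) {
    if (inb(i)) psi(i) = 0.0;
    else if (r(i) > rtol2)  psi(i) = tau;
    else if (r(i) < -rtol2) psi(i) = tau - 1.0;
    else psi(i) = 0.0;                // degenerate off-basis zero residual
  }
  vec rhs = -(X.t() * psi);           // want X_h' psi_h = rhs
  mat Xh2(p, p);
  for (uword j = 0; j < p; ++j) Xh2.row(j) = X.row(h(j));
  vec psih;
  if (solve(psih, Xh2.t(), rhs, solve_opts::no_approx)) {
    for (uword j = 0; j < p; ++j)
      psi(h(j)) = std::min(tau, std::max(tau - 1.0, psih(j)));
  } else {
    for (uword j = 0; j < p; ++j) psi(h(j)) = 0.0;
  }

  return Rcpp::List::create(
      Rcpp::Named("status") = "optimal",
      Rcpp::Named("coef") = beta,
      Rcpp::Named("residuals") = r,
      Rcpp::Named("objective") = obj,
      Rcpp::Named("basis") = h + 1,
      Rcpp::Named("dual") = psi,
      Rcpp::Named("iter") = iter);
}
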