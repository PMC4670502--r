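// Numerical kernels for the CCRS pipeline: the univariate bridge
// minimizer, cyclic coordinate descent in Gram form, and the alternating
// rank-1 constrained matrix decomposition. These sit in C++ because the
// permutation reference distribution re-runs the penalized fit hundreds of
// thousands of times per scan.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Global minimizer of g(gamma) = 0.5*a*(gamma - b)^2 + nu*|gamma|^kappa,
// a > 0, nu >= 0, 0 < kappa < 1. Candidates: gamma = 0 and the local
// minimum of the smooth branch on sign(b)*(0, |b|), located by bisection
// on g' (the smooth branch has at most two stationary points; the larger
// one is the local minimum). Ties between 0 and a nonzero candidate go
// to 0.
// [[Rcpp::export]]
double cpp_uni_bridge(double a, double b, double nu, double kappa) {
  if (nu <= 0.0) return b;
  if (b == 0.0) return 0.0;
  const double w = std::fabs(b);
  const double s = (b > 0.0) ? 1.0 : -1.0;
  // g'(gamma) = a*(gamma - w) + nu*kappa*gamma^(kappa-1) on gamma > 0 is
  // decreasing then increasing, minimized at gstar.
  const double gstar = std::pow(nu * kappa * (1.0 - kappa) / a,
                                1.0 / (2.0 - kappa));
  if (gstar >= w) return 0.0;  // g' > 0 on (0, w): penalty dominates
  const double hstar = a * (gstar - w) + nu * kappa * std::pow(gstar, kappa - 1.0);
  if (hstar >= 0.0) return 0.0;
  double lo = gstar, hi = w;
  for (int it = 0; it < 200 && (hi - lo) > 1e-10; ++it) {
    const double mid = 0.5 * (lo + hi);
    const double h = a * (mid - w) + nu * kappa * std::pow(mid, kappa - 1.0);
    if (h < 0.0) lo = mid; else hi = mid;
  }
  const double g1 = 0.5 * (lo + hi);
  const double f1 = 0.5 * a * (g1 - w) * (g1 - w) + nu * std::pow(g1, kappa);
  const double f0 = 0.5 * a * w * w;
  return (f1 < f0) ? s * g1 : 0.0;
}

static double bridge_objective(const arma::vec& gamma, const arma::mat& G,
                               const arma::vec& Zty, double yty,
                               double nu, double kappa) {
  const double quad = yty - 2.0 * arma::dot(gamma, Zty) +
    arma::dot(gamma, G * gamma);
  double pen = 0.0;
  for (arma::uword j = 0; j < gamma.n_elem; ++j)
    if (gamma[j] != 0.0) pen += std::pow(std::fabs(gamma[j]), kappa);
  return 0.5 * std::max(quad, 0.0) + nu * pen;
}

// One coordinate-descent solve from a given start; works entirely on the
// Gram matrix G = Z'Z, the score vector Zty = Z'y and yty = y'y, so a
// sweep costs O(r^2) independent of n. Returns iterations used (negative
// if not converged) and fills gamma in place.
static int bridge_cd(arma::vec& gamma, const arma::mat& G,
                     const arma::vec& Zty, double nu, double kappa,
                     double tol, int max_iter,
                     std::vector<double>* obj_trace,
                     double yty) {
  const arma::uword r = gamma.n_elem;
  arma::vec s = G * gamma;  // s = G * gamma, kept up to date
  for (int sweep = 1; sweep <= max_iter; ++sweep) {
    double maxdel = 0.0;
    for (arma::uword j = 0; j < r; ++j) {
      const double a = G(j, j);
      if (a <= 1e-12) { // column annihilated by the covariate projection
        if (gamma[j] != 0.0) { s -= G.col(j) * gamma[j]; gamma[j] = 0.0; }
        continue;
      }
      const double bj = (Zty[j] - s[j] + a * gamma[j]) / a;
      const double gnew = cpp_uni_bridge(a, bj, nu, kappa);
      const double del = gnew - gamma[j];
      if (del != 0.0) {
        s += G.col(j) * del;
        gamma[j] = gnew;
        const double ad = std::fabs(del);
        if (ad > maxdel) maxdel = ad;
      }
    }
    if (obj_trace)
      obj_trace->push_back(bridge_objective(gamma, G, Zty, yty, nu, kappa));
    if (maxdel < tol) return sweep;
  }
  return -max_iter;
}

// Bridge regression path over a grid of nu values with two deterministic
// starts per value (gamma = 0 and the least-squares solution); the start
// reaching the lower objective wins. Inputs are the Gram-form summaries of
// the (already covariate-projected) design.
// [[Rcpp::export]]
List cpp_bridge_path(const arma::mat& G, const arma::vec& Zty, double yty,
                     const arma::vec& nu_grid, double kappa,
                     double tol, int max_iter) {
  const arma::uword r = G.n_rows, K = nu_grid.n_elem;
  arma::vec gls;
  bool have_ls = arma::solve(gls, G, Zty,
                             arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
  if (!have_ls) {
    gls = arma::pinv(G) * Zty;
    have_ls = gls.is_finite();
  }
  arma::mat gamma_out(r, K, arma::fill::zeros);
  arma::vec rss(K), obj(K);
  arma::ivec nnz(K), iters(K);
  LogicalVector converged(K);
  for (arma::uword k = 0; k < K; ++k) {
    const double nu = nu_grid[k];
    arma::vec g0(r, arma::fill::zeros);
    int it0 = bridge_cd(g0, G, Zty, nu, kappa, tol, max_iter, nullptr, yty);
    double f0 = bridge_objective(g0, G, Zty, yty, nu, kappa);
    arma::vec gbest = g0;
    double fbest = f0;
    int itbest = it0;
    if (have_ls) {
      arma::vec g1 = gls;
      int it1 = bridge_cd(g1, G, Zty, nu, kappa, tol, max_iter, nullptr, yty);
      const double f1 = bridge_objective(g1, G, Zty, yty, nu, kappa);
      if (f1 < fbest) { gbest = g1; fbest = f1; itbest = it1; }
    }
    gamma_out.col(k) = gbest;
    double quad = yty - 2.0 * arma::dot(gbest, Zty) + arma::dot(gbest, G * gbest);
    rss[k] = std::max(quad, 0.0);
    obj[k] = fbest;
    nnz[k] = arma::accu(gbest != 0.0);
    iters[k] = std::abs(itbest);
    converged[k] = itbest > 0;
  }
  return List::create(_["gamma"] = gamma_out, _["rss"] = rss,
                      _["objective"] = obj, _["nnz"] = nnz,
                      _["iterations"] = iters, _["converged"] = converged);
}

// Single-start coordinate descent that records the objective after every
// sweep; used to verify monotone descent.
// [[Rcpp::export]]
List cpp_bridge_trace(const arma::mat& G, const arma::vec& Zty, double yty,
                      double nu, double kappa, const arma::vec& gamma0,
                      double tol, int max_iter) {
  arma::vec gamma = gamma0;
  std::vector<double> trace;
  int it = bridge_cd(gamma, G, Zty, nu, kappa, tol, max_iter, &trace, yty);
  double quad = yty - 2.0 * arma::dot(gamma, Zty) + arma::dot(gamma, G * gamma);
  return List::create(_["gamma"] = gamma, _["rss"] = std::max(quad, 0.0),
                      _["objective_trace"] = trace,
                      _["converged"] = it > 0);
}

static arma::vec soft_vec(const arma::vec& x, double delta) {
  return arma::sign(x) % arma::max(arma::abs(x) - delta, arma::zeros(x.n_elem));
}

// Rank-1 constrained decomposition: maximize u'Xv subject to ||u||2 = 1,
// ||v||2 <= 1, ||v||1 <= c, by alternating exact updates. The v update
// soft-thresholds X'u with the smallest delta >= 0 (bisection) such that
// the L1 bound holds after L2 normalization.
// [[Rcpp::export]]
List cpp_rank1_pmd(const arma::mat& X, double c, const arma::vec& v0,
                   double tol, int max_iter) {
  arma::vec v = v0 / arma::norm(v0, 2);
  arma::vec u = X * v;
  double un = arma::norm(u, 2);
  if (un <= 0.0) stop("initial v lies in the null space of X");
  u /= un;
  std::vector<double> obj_trace;
  bool converged = false;
  int used = 0;
  for (int it = 1; it <= max_iter; ++it) {
    arma::vec a = X.t() * u;
    double delta = 0.0;
    const double amax = arma::abs(a).max();
    if (amax <= 0.0) stop("degenerate residual in rank-1 update");
    double l2 = arma::norm(a, 2);
    if (arma::norm(a, 1) / l2 > c) {
      double lo = 0.0, hi = amax;
      for (int k = 0; k < 200 && (hi - lo) > 1e-8; ++k) {
        const double mid = 0.5 * (lo + hi);
        arma::vec sv = soft_vec(a, mid);
        const double n2 = arma::norm(sv, 2);
        const double ratio = (n2 > 0.0) ? arma::norm(sv, 1) / n2 : 1.0;
        if (ratio > c) lo = mid; else hi = mid;
      }
      delta = hi;
    }
    arma::vec sv = soft_vec(a, delta);
    double n2 = arma::norm(sv, 2);
    if (n2 <= 0.0) { // all mass thresholded away (tied maxima): one-hot fallback
      sv.zeros();
      sv[arma::abs(a).index_max()] = 1.0;
      n2 = 1.0;
    }
    arma::vec v_new = sv / n2;
    arma::vec Xv = X * v_new;
    const double d = arma::norm(Xv, 2);
    if (d <= 0.0) stop("degenerate v in rank-1 update");
    arma::vec u_new = Xv / d;
    obj_trace.push_back(d);  // = u_new' X v_new
    const double change = std::max(arma::abs(v_new - v).max(),
                                   arma::abs(u_new - u).max());
    v = v_new; u = u_new; used = it;
    if (change < tol) { converged = true; break; }
  }
  const double d = arma::dot(u, X * v);
  return List::create(_["u"] = u, _["v"] = v, _["d"] = d,
                      _["objective_trace"] = obj_trace,
                      _["iterations"] = used, _["converged"] = converged);
}
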