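#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Minimise over x in R^M:  sum_m { 0.5 a_m x_m^2 - b_m x_m } + lam ||x||_2.
// The block is zero iff ||b||_2 <= lam; otherwise x_m = b_m r / (a_m r + lam)
// where r = ||x||_2 solves a scalar fixed-point equation (bisection; the
// residual g(r) = ||b r / (a r + lam)|| - r crosses zero exactly once).
static vec group_prox(const vec& a, const vec& b, double lam) {
  const uword M = a.n_elem;
  vec x(M, fill::zeros);
  double bn = norm(b);
  if (bn <= lam || bn <= 0.0) return x;
  double amin = a.min(), amax = a.max();
  if (amax - amin <= 1e-13 * (1.0 + amin)) {
    // equal curvatures: closed-form shrinkage
    double r = (bn - lam) / amin;
    return b * (r / (amin * r + lam));
  }
  double hi = norm(b / a);  // r <= ||b/a||
  double lo = 0.0;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double s = 0.0;
    for (uword m = 0; m < M; ++m) {
      double t = b[m] * mid / (a[m] * mid + lam);
      s += t * t;
    }
    if (std::sqrt(s) > mid) lo = mid; else hi = mid;
    if (hi - lo <= 1e-15 * (1.0 + hi)) break;
  }
  double r = 0.5 * (lo + hi);
  for (uword m = 0; m < M; ++m) x[m] = b[m] * r / (a[m] * r + lam);
  return x;
}

static double gl_objective(const cube& H, const mat& xi, const vec& wbar,
                           double lam, const mat& B) {
  const uword d = H.n_rows, M = H.n_slices;
  double obj = 0.0;
  for (uword m = 0; m < M; ++m) {
    obj += wbar[m] * (as_scalar(B.col(m).t() * H.slice(m) * B.col(m))
                      - 2.0 * dot(B.col(m), xi.col(m)));
  }
  for (uword j = 1; j < d; ++j) obj += lam * norm(B.row(j).t());
  return obj;
}

// Block coordinate descent for the summary-statistic group lasso:
//   min_B sum_m wbar_m (B_m' H_m B_m - 2 B_m' xi_m) + lam sum_{j>=2} ||B[j,]||_2
// H: d x d x M, xi: d x M, wbar: positive weights (fold-size shares),
// B: d x M warm start.  Row 1 (intercept) is unpenalised.
// [[Rcpp::export]]
Rcpp::List bcd_group_lasso_cpp(const arma::cube& H, const arma::mat& xi,
                               const arma::vec& wbar, double lam,
                               arma::mat B, double tol, int maxit) {
  const uword d = H.n_rows, M = H.n_slices;
  mat G(d, M);  // G.col(m) = H_m B_m, maintained incrementally
  for (uword m = 0; m < M; ++m) G.col(m) = H.slice(m) * B.col(m);
  vec a(M), b(M);
  std::vector<bool> active(d, true);
  bool converged = false;
  int sweeps = 0;
  bool full = true;
  while (sweeps < maxit) {
    ++sweeps;
    double maxdelta = 0.0;
    for (uword j = 0; j < d; ++j) {
      if (!full && !active[j]) continue;
      if (j == 0) {
        for (uword m = 0; m < M; ++m) {
          double hjj = H(0, 0, m);
          if (hjj <= 0.0) continue;
          double newv = (xi(0, m) - (G(0, m) - hjj * B(0, m))) / hjj;
          double delta = newv - B(0, m);
          if (delta != 0.0) {
            G.col(m) += H.slice(m).col(0) * delta;
            B(0, m) = newv;
            maxdelta = std::max(maxdelta, std::fabs(delta));
          }
        }
        continue;
      }
      for (uword m = 0; m < M; ++m) {
        double hjj = H(j, j, m);
        a[m] = 2.0 * wbar[m] * std::max(hjj, 1e-12);
        b[m] = 2.0 * wbar[m] * (xi(j, m) - (G(j, m) - hjj * B(j, m)));
      }
      vec xnew = group_prox(a, b, lam);
      bool nz = false;
      for (uword m = 0; m < M; ++m) {
        double delta = xnew[m] - B(j, m);
        if (delta != 0.0) {
          G.col(m) += H.slice(m).col(j) * delta;
          B(j, m) = xnew[m];
          maxdelta = std::max(maxdelta, std::fabs(delta));
        }
        if (xnew[m] != 0.0) nz = true;
      }
      active[j] = nz;
    }
    if (maxdelta < tol) {
      if (full) { converged = true; break; }
      full = true;           // verify with one full sweep
    } else {
      full = false;          // iterate on the active set
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("B") = B,
    Rcpp::Named("sweeps") = sweeps,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("objective") = gl_objective(H, xi, wbar, lam, B));
}

// Objective evaluation (exported for tests / GIC bookkeeping)
// [[Rcpp::export]]
double group_lasso_objective_cpp(const arma::cube& H, const arma::mat& xi,
                                 const arma::vec& wbar, double lam,
                                 const arma::mat& B) {
  return gl_objective(H, xi, wbar, lam, B);
}
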