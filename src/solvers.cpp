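// Penalized solvers used across the package:
//  - cyclic coordinate descent for the lasso, in Gram ("covariance update")
//    form with warm starts along a lambda path and active-set iteration;
//  - block coordinate descent graphical lasso with an off-diagonal-only
//    penalty, warm-started along a lambda path.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One coordinate-descent sweep over the coordinates in `idx`.
// r holds the gradient-like quantities r_j = b_j - sum_k G(j,k) cur_k,
// maintained incrementally. Returns the largest coefficient change.
static double cd_sweep(const double* G, const arma::uword q,
                       const arma::uvec& idx, double lam,
                       arma::vec& cur, arma::vec& r) {
  double maxdelta = 0.0;
  double* rp = r.memptr();
  for (arma::uword t = 0; t < idx.n_elem; ++t) {
    const arma::uword j = idx(t);
    const double gjj = G[j * q + j];
    if (gjj <= 0.0) continue;
    const double old = cur(j);
    const double z = rp[j] + gjj * old;
    const double nb = soft_threshold(z, lam) / gjj;
    if (nb != old) {
      const double d = nb - old;
      const double* gcol = G + j * q;
      for (arma::uword k = 0; k < q; ++k) rp[k] -= d * gcol[k];
      cur(j) = nb;
      const double ad = std::abs(d);
      if (ad > maxdelta) maxdelta = ad;
    }
  }
  return maxdelta;
}

// Lasso path by cyclic coordinate descent on the Gram system.
// G = X'X/n (q x q), b = X'y/n (q). Objective per lambda:
//   (1/2n)||y - X beta||^2 + lambda ||beta||_1.
// Warm starts along the (descending) grid; within each lambda, full sweeps
// alternate with active-set sweeps until the largest coefficient change in
// a full sweep falls below `tol`. Columns with G(j,j) == 0 (constant
// predictors) keep beta_j = 0.
// [[Rcpp::export]]
arma::mat cd_lasso_path(const arma::mat& G, const arma::vec& b,
                        const arma::vec& lambda,
                        double tol = 1e-7, int maxit = 100000) {
  const arma::uword q = b.n_elem;
  const arma::uword L = lambda.n_elem;
  arma::mat beta(q, L, arma::fill::zeros);
  arma::vec cur(q, arma::fill::zeros);
  arma::vec r = b;
  const double* Gp = G.memptr();
  arma::uvec all = arma::regspace<arma::uvec>(0, q - 1);

  for (arma::uword l = 0; l < L; ++l) {
    const double lam = lambda(l);
    int it = 0;
    for (;;) {
      double md = cd_sweep(Gp, q, all, lam, cur, r);
      ++it;
      if (md < tol || it >= maxit) break;
      // iterate on the current active set until it stabilizes
      arma::uvec act = arma::find(cur != 0.0);
      while (it < maxit) {
        double mda = cd_sweep(Gp, q, act, lam, cur, r);
        ++it;
        if (mda < tol) break;
      }
    }
    beta.col(l) = cur;
  }
  return beta;
}

// One inner lasso for the graphical lasso subproblem on column j:
//   min_beta 1/2 beta' W11 beta - s12' beta + rho ||beta||_1
// where W11 = W[-j, -j] and s12 = S[-j, j], accessed in place through the
// index map `idx` (the p-1 indices != j).
static void glasso_inner(const arma::mat& W, const arma::vec& S_col,
                         const arma::uvec& idx, arma::uword j,
                         double rho, arma::vec& beta,
                         double tol, int maxit) {
  const arma::uword m = idx.n_elem;
  const arma::uword p = W.n_rows;
  const double* Wp = W.memptr();
  for (int it = 0; it < maxit; ++it) {
    double maxdelta = 0.0;
    for (arma::uword t = 0; t < m; ++t) {
      const arma::uword k = idx(t);
      const double wkk = Wp[k * p + k];
      double dot = 0.0;
      const double* wcol = Wp + k * p;  // column k == row k (W symmetric)
      for (arma::uword u = 0; u < m; ++u) dot += wcol[idx(u)] * beta(u);
      const double z = S_col(k) - dot + wkk * beta(t);
      const double nb = soft_threshold(z, rho) / wkk;
      const double d = nb - beta(t);
      if (d != 0.0) {
        beta(t) = nb;
        const double ad = std::abs(d);
        if (ad > maxdelta) maxdelta = ad;
      }
    }
    if (maxdelta < tol) break;
  }
}

// Graphical lasso along a penalty path (descending rho recommended for
// warm starts). The penalty applies to off-diagonal precision entries
// only; the diagonal of the covariance estimate stays at diag(S). Returns
// a cube of precision matrices (p x p x n_rho); off-diagonal entries are
// exactly zero where the inner lasso zeroed them.
// [[Rcpp::export]]
arma::cube glasso_path(const arma::mat& S, const arma::vec& rho,
                       double tol = 1e-5, int maxit = 200,
                       double inner_tol = 1e-7, int inner_maxit = 10000) {
  const arma::uword p = S.n_rows;
  const arma::uword L = rho.n_elem;
  arma::cube Theta(p, p, L, arma::fill::zeros);
  arma::mat W = S;                           // working covariance estimate
  arma::mat B(p - 1, p, arma::fill::zeros);  // per-column inner solutions

  // per-column index maps (indices != j)
  std::vector<arma::uvec> maps(p);
  for (arma::uword j = 0; j < p; ++j) {
    arma::uvec idx(p - 1);
    arma::uword c = 0;
    for (arma::uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
    maps[j] = idx;
  }

  double off_scale = 0.0;
  for (arma::uword j = 1; j < p; ++j)
    for (arma::uword i = 0; i < j; ++i) off_scale += std::abs(S(i, j));
  off_scale = std::max(1e-12, off_scale / (p * (p - 1) / 2.0));

  for (arma::uword l = 0; l < L; ++l) {
    const double r = rho(l);
    for (int sweep = 0; sweep < maxit; ++sweep) {
      double change = 0.0;
      for (arma::uword j = 0; j < p; ++j) {
        const arma::uvec& idx = maps[j];
        arma::vec beta = B.col(j);
        glasso_inner(W, S.col(j), idx, j, r, beta, inner_tol, inner_maxit);
        B.col(j) = beta;
        for (arma::uword t = 0; t < p - 1; ++t) {
          double w12 = 0.0;
          const arma::uword k = idx(t);
          for (arma::uword u = 0; u < p - 1; ++u)
            w12 += W(k, idx(u)) * beta(u);
          // note: uses current W row; matches blockwise Gauss-Seidel
          const double d = std::abs(W(k, j) - w12);
          if (d > change) change = d;
          W(k, j) = w12;
          W(j, k) = w12;
        }
      }
      if (change < tol * off_scale) break;
    }
    // recover the precision matrix from the final (W, B)
    arma::mat Th(p, p, arma::fill::zeros);
    for (arma::uword j = 0; j < p; ++j) {
      const arma::uvec& idx = maps[j];
      const arma::vec beta = B.col(j);
      double dot = 0.0;
      for (arma::uword t = 0; t < p - 1; ++t) dot += W(idx(t), j) * beta(t);
      const double t22 = 1.0 / (W(j, j) - dot);
      Th(j, j) = t22;
      for (arma::uword t = 0; t < p - 1; ++t) {
        if (beta(t) != 0.0) Th(idx(t), j) = -beta(t) * t22;
      }
    }
    // enforce exact symmetry of the support and values
    for (arma::uword j = 1; j < p; ++j) {
      for (arma::uword i = 0; i < j; ++i) {
        if (Th(i, j) == 0.0 || Th(j, i) == 0.0) {
          Th(i, j) = 0.0; Th(j, i) = 0.0;
        } else {
          const double v = 0.5 * (Th(i, j) + Th(j, i));
          Th(i, j) = v; Th(j, i) = v;
        }
      }
    }
    Theta.slice(l) = Th;
  }
  return Theta;
}
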