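#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Minimize 0.5*da*a^2 - ca*a + 0.5*db*b^2 - cb*b + lam*sqrt(a^2+b^2).
// Zero block iff ||(ca,cb)|| <= lam; otherwise a = ca/(da+mu), b = cb/(db+mu)
// with mu = lam/||(a,b)|| found by bisection (g(mu) is monotone increasing).
static inline void solve_block(double ca, double cb, double da, double db,
                               double lam, double &a, double &b) {
  double cn = std::sqrt(ca * ca + cb * cb);
  if (cn <= lam || cn == 0.0) { a = 0.0; b = 0.0; return; }
  if (lam <= 0.0) { a = ca / da; b = cb / db; return; }
  double dmin = std::min(da, db), dmax = std::max(da, db);
  double lo = lam * dmin / (cn - lam);
  double hi = lam * dmax / (cn - lam);
  if (hi - lo < 1e-15 * (1.0 + hi)) {
    double mu = 0.5 * (lo + hi);
    a = ca / (da + mu); b = cb / (db + mu);
    return;
  }
  for (int it = 0; it < 200; ++it) {
    double mu = 0.5 * (lo + hi);
    double ra = mu * ca / (da + mu), rb = mu * cb / (db + mu);
    double g = ra * ra + rb * rb - lam * lam;
    if (g > 0.0) hi = mu; else lo = mu;
    if (hi - lo < 1e-14 * (1.0 + hi)) break;
  }
  double mu = 0.5 * (lo + hi);
  a = ca / (da + mu); b = cb / (db + mu);
}

static double objective(const std::vector<mat> &R, const mat &Om,
                        const std::vector<mat> &Gam,
                        const std::vector<double> &ninv,
                        double lambda1, double lambda2) {
  const int K = (int)R.size();
  const int p = Om.n_rows;
  double obj = 0.0;
  for (int k = 0; k < K; ++k)
    obj += 0.5 * ninv[k] * accu(square(R[k]));
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      obj += lambda1 * std::sqrt(Om(i, j) * Om(i, j) + Om(j, i) * Om(j, i));
      for (int k = 0; k < K; ++k)
        obj += lambda2 * std::sqrt(Gam[k](i, j) * Gam[k](i, j) +
                                   Gam[k](j, i) * Gam[k](j, i));
    }
  return obj;
}

// Block coordinate descent for the joint node-wise regression
//   sum_k 1/(2 n_k) ||X^(k) - X^(k) (Omega + Gamma^(k))||_F^2
//   + lambda1 * sum_{i<j} ||(Omega_ij, Omega_ji)||_2
//   + lambda2 * sum_k sum_{i<j} ||(Gamma^(k)_ij, Gamma^(k)_ji)||_2
// with all diagonals constrained to zero. Sweep order: common blocks in
// (i,j) lexicographic order, then specific blocks per group. Deterministic
// given inputs (zero initialization).
// [[Rcpp::export]]
Rcpp::List jewel_cd(Rcpp::List Xs, double lambda1, double lambda2,
                    double tol, int max_iter, bool trace) {
  const int K = Xs.size();
  std::vector<mat> X(K), R(K), Gam(K);
  std::vector<double> ninv(K);
  int p = -1;
  for (int k = 0; k < K; ++k) {
    X[k] = Rcpp::as<mat>(Xs[k]);
    if (p < 0) p = X[k].n_cols;
    if ((int)X[k].n_cols != p)
      Rcpp::stop("all groups must have the same number of variables");
    R[k] = X[k];                 // residuals at Theta = 0
    Gam[k].zeros(p, p);
    ninv[k] = 1.0 / (double)X[k].n_rows;
  }
  mat Om(p, p, fill::zeros);
  mat D(p, K);                   // D(i,k) = ||x_i^(k)||^2 / n_k
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < p; ++i)
      D(i, k) = ninv[k] * dot(X[k].col(i), X[k].col(i));

  std::vector<double> objs;
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double maxdel = 0.0;
    // common blocks
    for (int i = 0; i < p; ++i) {
      for (int j = i + 1; j < p; ++j) {
        double a_old = Om(i, j), b_old = Om(j, i);
        double ca = 0.0, cb = 0.0, da = 0.0, db = 0.0;
        for (int k = 0; k < K; ++k) {
          ca += ninv[k] * dot(X[k].col(i), R[k].col(j));
          cb += ninv[k] * dot(X[k].col(j), R[k].col(i));
          da += D(i, k);
          db += D(j, k);
        }
        ca += a_old * da;
        cb += b_old * db;
        double a, b;
        solve_block(ca, cb, da, db, lambda1, a, b);
        if (a != a_old || b != b_old) {
          for (int k = 0; k < K; ++k) {
            R[k].col(j) += (a_old - a) * X[k].col(i);
            R[k].col(i) += (b_old - b) * X[k].col(j);
          }
          Om(i, j) = a; Om(j, i) = b;
          maxdel = std::max(maxdel,
                            std::max(std::fabs(a - a_old), std::fabs(b - b_old)));
        }
      }
    }
    // group-specific blocks
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < p; ++i) {
        for (int j = i + 1; j < p; ++j) {
          double a_old = Gam[k](i, j), b_old = Gam[k](j, i);
          double da = D(i, k), db = D(j, k);
          double ca = ninv[k] * dot(X[k].col(i), R[k].col(j)) + a_old * da;
          double cb = ninv[k] * dot(X[k].col(j), R[k].col(i)) + b_old * db;
          double a, b;
          solve_block(ca, cb, da, db, lambda2, a, b);
          if (a != a_old || b != b_old) {
            R[k].col(j) += (a_old - a) * X[k].col(i);
            R[k].col(i) += (b_old - b) * X[k].col(j);
            Gam[k](i, j) = a; Gam[k](j, i) = b;
            maxdel = std::max(maxdel,
                              std::max(std::fabs(a - a_old), std::fabs(b - b_old)));
          }
        }
      }
    }
    if (trace) objs.push_back(objective(R, Om, Gam, ninv, lambda1, lambda2));
    if (maxdel < tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  Rcpp::List gam_out(K), rss_out(K);
  for (int k = 0; k < K; ++k) {
    gam_out[k] = Gam[k];
    // per-column residual sum of squares, used for BIC
    rowvec rss = sum(square(R[k]), 0);
    rss_out[k] = Rcpp::NumericVector(rss.begin(), rss.end());
  }
  return Rcpp::List::create(
      Rcpp::Named("Omega") = Om,
      Rcpp::Named("Gamma") = gam_out,
      Rcpp::Named("rss") = rss_out,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("objective") = Rcpp::NumericVector(objs.begin(), objs.end()));
}
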