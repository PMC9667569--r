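// Hot loops of the alternating least-squares solver for the regularized,
// weighted, optionally shifted factorization. Conventions:
//  - Y is N x T with zeros off the mask; W2 holds squared weights (zero off
//    the mask), so the data term is sum_{n,t} W2(n,t) (Y - M)^2.
//  - shifts z_n translate the basic profiles: M(n, t) = [U V'](n, t - z_n);
//    out-of-range cells either clamp to the profile edge (replicate
//    boundary) or take latent value 0 (zero padding).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Source index for cell t of a row shifted by z. With replicate boundary
// handling out-of-range indices clamp to the profile edge; otherwise -1
// flags a zero-padded cell.
static inline int shift_source(int t, int z, int T, bool replicate) {
  int ts = t - z;
  if (ts >= 0 && ts < T) return ts;
  if (!replicate) return -1;
  return ts < 0 ? 0 : T - 1;
}

// Shift-adjusted latent matrix U V' Z_n per row.
// [[Rcpp::export]]
arma::mat cpp_latent(const arma::mat& U, const arma::mat& V,
                     const arma::ivec& shifts, bool replicate) {
  const uword N = U.n_rows, T = V.n_rows;
  mat P = U * V.t();
  mat L(N, T, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    int z = shifts(n);
    for (uword t = 0; t < T; ++t) {
      int ts = shift_source(t, z, T, replicate);
      if (ts >= 0) L(n, t) = P(n, ts);
    }
  }
  return L;
}

// Row-wise exact ridge solve for the coefficients U at fixed V.
// [[Rcpp::export]]
arma::mat cpp_update_U(const arma::mat& Y, const arma::mat& W2,
                       const arma::mat& V, const arma::ivec& shifts,
                       double beta1, bool replicate) {
  const uword N = Y.n_rows, T = Y.n_cols, r = V.n_cols;
  mat U(N, r, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    int z = shifts(n);
    mat A(r, r, fill::zeros);
    vec b(r, fill::zeros);
    A.diag() += beta1;
    for (uword t = 0; t < T; ++t) {
      double w2 = W2(n, t);
      if (w2 <= 0.0) continue;
      int ts = shift_source(t, z, T, replicate);
      if (ts < 0) continue;  // zero-padded cell: constant w.r.t. U
      vec v = V.row(ts).t();
      A += w2 * (v * v.t());
      b += (w2 * Y(n, t)) * v;
    }
    vec u;
    if (!solve(u, A, b, solve_opts::no_approx))
      Rcpp::stop("singular normal matrix in coefficient update for row %d; "
                 "use a ridge penalty beta1 > 0", n + 1);
    U.row(n) = u.t();
  }
  return U;
}

// Exact solve of the stacked (T*r)-dimensional quadratic subproblem for the
// basic profiles V at fixed U, including weights, shifts, and the penalty
// beta2 ||V||_F^2 + beta3 ||R V||_F^2 (RtR = R'R, T x T).
// [[Rcpp::export]]
arma::mat cpp_update_V(const arma::mat& Y, const arma::mat& W2,
                       const arma::mat& U, const arma::ivec& shifts,
                       double beta2, double beta3, const arma::mat& RtR,
                       bool replicate) {
  const uword N = Y.n_rows, T = Y.n_cols, r = U.n_cols;
  mat G(T * r, T * r, fill::zeros);
  vec b(T * r, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    int z = shifts(n);
    vec u = U.row(n).t();
    mat uu = u * u.t();
    for (uword t = 0; t < T; ++t) {
      double w2 = W2(n, t);
      if (w2 <= 0.0) continue;
      int ts = shift_source(t, z, T, replicate);
      if (ts < 0) continue;
      uword off = static_cast<uword>(ts) * r;
      G.submat(off, off, off + r - 1, off + r - 1) += w2 * uu;
      b.subvec(off, off + r - 1) += (w2 * Y(n, t)) * u;
    }
  }
  for (uword i = 0; i < T; ++i) {
    for (uword j = 0; j < T; ++j) {
      double p = beta3 * RtR(i, j) + (i == j ? beta2 : 0.0);
      if (p != 0.0)
        for (uword k = 0; k < r; ++k) G(i * r + k, j * r + k) += p;
    }
  }
  vec v;
  if (!solve(v, G, b, solve_opts::no_approx))
    Rcpp::stop("singular system in profile update; use beta2 > 0");
  // v is ordered t-major: v[t*r + k] = V(t, k)
  mat Vt(v.memptr(), r, T);
  return Vt.t();
}

// Exhaustive per-row search for the discrepancy-minimizing shift in
// [-max_shift, max_shift]. Candidates are visited in the order
// 0, -1, +1, -2, +2, ... with strict improvement required, which breaks
// ties toward smaller |z| and then toward the negative shift.
// [[Rcpp::export]]
arma::ivec cpp_search_shifts(const arma::mat& Y, const arma::mat& W2,
                             const arma::mat& U, const arma::mat& V,
                             int max_shift, bool replicate) {
  const uword N = Y.n_rows, T = Y.n_cols;
  mat P = U * V.t();
  ivec z(N, fill::zeros);
  std::vector<int> cand;
  cand.push_back(0);
  for (int a = 1; a <= max_shift; ++a) {
    cand.push_back(-a);
    cand.push_back(a);
  }
  for (uword n = 0; n < N; ++n) {
    double best = datum::inf;
    int bestz = 0;
    for (int c : cand) {
      double d = 0.0;
      for (uword t = 0; t < T; ++t) {
        double w2 = W2(n, t);
        if (w2 <= 0.0) continue;
        int ts = shift_source(t, c, T, replicate);
        double m = ts >= 0 ? P(n, ts) : 0.0;
        double res = Y(n, t) - m;
        d += w2 * res * res;
      }
      if (d < best) {
        best = d;
        bestz = c;
      }
    }
    z(n) = bestz;
  }
  return z;
}
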