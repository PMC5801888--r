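// Inner loop of the auxiliary-data grid searches: for one projected dataset
// (fixed clipping bounds), score every candidate budget split under K
// common-random-number noise draws. Scoring = perturb the statistics, PSD-
// repair nxx, solve the fixed-precision conjugate posterior, predict on the
// (projected) auxiliary inputs, Spearman-correlate with the original
// targets. The R reference implementation in R/tuning.R mirrors this
// routine entry for entry; agreement is asserted in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// average ranks (ties share the mean rank), 1-based like R's rank()
static arma::vec avg_rank(const arma::vec& v) {
  const arma::uword n = v.n_elem;
  arma::uvec ord = arma::stable_sort_index(v);
  arma::vec r(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && v(ord(j + 1)) == v(ord(i))) ++j;
    double rr = 0.5 * (double)(i + j) + 1.0;
    for (arma::uword k = i; k <= j; ++k) r(ord(k)) = rr;
    i = j + 1;
  }
  return r;
}

static double pearson(const arma::vec& a, const arma::vec& b) {
  arma::vec ac = a - arma::mean(a);
  arma::vec bc = b - arma::mean(b);
  double da = arma::dot(ac, ac), db = arma::dot(bc, bc);
  if (da <= 0.0 || db <= 0.0) return NA_REAL;
  return arma::dot(ac, bc) / std::sqrt(da * db);
}

// eigenvalue clipping at zero = nearest PSD matrix in Frobenius norm
static arma::mat psd_clip(const arma::mat& M) {
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, M);
  if (eval(0) >= 0.0) return M;
  eval.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  arma::mat R = evec * arma::diagmat(eval) * evec.t();
  return 0.5 * (R + R.t());
}

// scales: S x 2 matrix of (s_xx, s_xy) Laplace scales per split candidate;
// Exx: K x d(d+1)/2 and Exy: K x d unit-Laplace common random numbers.
// Returns S x K Spearman scores (degenerate constant predictions -> -1).
// [[Rcpp::export]]
arma::mat cpp_score_block(const arma::mat& nxx, const arma::vec& nxy,
                          const arma::mat& Xproj, const arma::vec& rank_y,
                          const arma::mat& scales, const arma::mat& Exx,
                          const arma::mat& Exy, double lambda,
                          double lambda0, bool repair) {
  const arma::uword d = nxy.n_elem;
  const arma::uword S = scales.n_rows;
  const arma::uword K = Exx.n_rows;
  const arma::uword nu = d * (d + 1) / 2;
  if (Exx.n_cols != nu || Exy.n_cols != d)
    Rcpp::stop("unit noise dimensions do not match d");
  arma::mat out(S, K);
  arma::mat I = arma::eye(d, d);
  for (arma::uword s = 0; s < S; ++s) {
    const double sxx = scales(s, 0), sxy = scales(s, 1);
    for (arma::uword k = 0; k < K; ++k) {
      // mirror noise on the unique entries (column-major upper triangle)
      arma::mat A = nxx;
      arma::uword u = 0;
      for (arma::uword j = 0; j < d; ++j) {
        for (arma::uword i = 0; i <= j; ++i, ++u) {
          double z = A(i, j) + sxx * Exx(k, u);
          A(i, j) = z;
          A(j, i) = z;
        }
      }
      arma::vec bvec = nxy + sxy * Exy.row(k).t();
      if (repair && sxx != 0.0) A = psd_clip(A);
      arma::mat Lam = lambda0 * I + lambda * A;
      arma::vec mu;
      bool ok = arma::solve(mu, Lam, lambda * bvec,
                            arma::solve_opts::no_approx);
      if (!ok) {  // numerically singular (possible without repair)
        out(s, k) = -1.0;
        continue;
      }
      arma::vec yhat = Xproj * mu;
      arma::vec rh = avg_rank(yhat);
      double sc = pearson(rh, rank_y);
      out(s, k) = std::isnan(sc) ? -1.0 : sc;
    }
  }
  return out;
}
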