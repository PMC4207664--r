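// Permutation engines for the genome-wide variance and covariance scans.
// Genotype codes: 0 = CO homozygote, 1 = MT homozygote, NA_INTEGER = missing.
// Permutations are supplied as 0-based row indices so all randomness stays in
// R's RNG and scans are reproducible from a single seed.

#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PI_HALF = 1.5707963267948966;

// Median via partial sort of a scratch buffer.
static double median_buf(std::vector<double>& buf) {
  const size_t n = buf.size();
  const size_t h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double m = buf[h];
  if (n % 2 == 0) {
    const double lo = *std::max_element(buf.begin(), buf.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// Absolute deviations from the group median; returns the group mean of z and
// writes z into the buffer.
static double zdev_group(std::vector<double>& buf) {
  const double med = median_buf(buf);
  double s = 0.0;
  for (double& v : buf) { v = std::fabs(v - med); s += v; }
  return s / buf.size();
}

// Two-group Brown-Forsythe statistic: one-way Levene F on absolute
// deviations from the group medians. Returns NA when the within-group
// deviations are all zero (undefined statistic). `b0`/`b1` hold the group
// values on entry and are used as scratch space.
static double bf_stat_buf(std::vector<double>& b0, std::vector<double>& b1) {
  const double n0 = b0.size(), n1 = b1.size(), N = n0 + n1;
  const double zb0 = zdev_group(b0), zb1 = zdev_group(b1);
  const double zb = (n0 * zb0 + n1 * zb1) / N;
  const double num = n0 * (zb0 - zb) * (zb0 - zb) + n1 * (zb1 - zb) * (zb1 - zb);
  double den = 0.0;
  for (double v : b0) den += (v - zb0) * (v - zb0);
  for (double v : b1) den += (v - zb1) * (v - zb1);
  if (den <= 0.0) return NA_REAL;
  return (N - 2.0) * num / den;
}

static void class_indices(const IntegerMatrix& geno, int j,
                          arma::uvec& idx0, arma::uvec& idx1) {
  std::vector<arma::uword> i0, i1;
  const int n = geno.nrow();
  for (int i = 0; i < n; ++i) {
    const int g = geno(i, j);
    if (g == NA_INTEGER) continue;
    if (g == 0) i0.push_back(i); else i1.push_back(i);
  }
  idx0 = arma::uvec(i0); idx1 = arma::uvec(i1);
}

// [[Rcpp::export]]
List cpp_scan_bf(const arma::vec& y, const IntegerMatrix& geno,
                 const IntegerMatrix& perms) {
  const int m = geno.ncol(), np = perms.ncol(), n = geno.nrow();
  if ((int)y.n_elem != n) stop("genotype/trait dimension mismatch");

  std::vector<arma::uvec> I0(m), I1(m);
  for (int j = 0; j < m; ++j) class_indices(geno, j, I0[j], I1[j]);

  NumericVector obs(m);
  IntegerVector n0(m), n1(m);
  std::vector<double> b0, b1;
  b0.reserve(n); b1.reserve(n);
  const auto fill_groups = [&](const arma::vec& yy, int j) {
    b0.resize(I0[j].n_elem); b1.resize(I1[j].n_elem);
    for (size_t i = 0; i < b0.size(); ++i) b0[i] = yy[I0[j][i]];
    for (size_t i = 0; i < b1.size(); ++i) b1[i] = yy[I1[j][i]];
  };
  for (int j = 0; j < m; ++j) {
    n0[j] = I0[j].n_elem; n1[j] = I1[j].n_elem;
    if (n0[j] < 2 || n1[j] < 2) { obs[j] = NA_REAL; continue; }
    fill_groups(y, j);
    obs[j] = bf_stat_buf(b0, b1);
  }

  NumericVector perm_max(np, NA_REAL);
  arma::vec yp(n);
  for (int p = 0; p < np; ++p) {
    for (int i = 0; i < n; ++i) yp[i] = y[perms(i, p)];
    double mx = -arma::datum::inf;
    bool any = false;
    for (int j = 0; j < m; ++j) {
      if (n0[j] < 2 || n1[j] < 2) continue;
      fill_groups(yp, j);
      const double s = bf_stat_buf(b0, b1);
      if (!ISNAN(s) && (!any || s > mx)) { mx = s; any = true; }
    }
    if (any) perm_max[p] = mx;
  }

  return List::create(_["statistic"] = obs, _["n_CO"] = n0, _["n_MT"] = n1,
                      _["perm_max"] = perm_max);
}

// Eigenvectors of a symmetric matrix in decreasing eigenvalue order, each
// column signed so its largest-magnitude component is positive.
static arma::mat lead_eigvecs(const arma::mat& G, int k) {
  arma::vec eval; arma::mat evec;
  arma::eig_sym(eval, evec, G);        // ascending
  const int p = G.n_rows;
  arma::mat A(p, k);
  for (int j = 0; j < k; ++j) {
    arma::vec v = evec.col(p - 1 - j);
    v /= std::sqrt(arma::dot(v, v));
    arma::uword imax = arma::abs(v).index_max();
    if (v[imax] < 0) v = -v;
    A.col(j) = v;
  }
  return A;
}

// method codes: 0 = Box's M (trace form), 1 = Gmax angle, 2 = negative
// Krzanowski index (the scan maximizes dissimilarity).
static double cov_stat(const arma::mat& Y0, const arma::mat& Y1,
                       int method, int k) {
  const double V0 = Y0.n_rows - 1.0, V1 = Y1.n_rows - 1.0;
  const arma::mat G0 = arma::cov(Y0), G1 = arma::cov(Y1);
  if (method == 0) {
    const double S0 = arma::trace(G0), S1 = arma::trace(G1);
    if (S0 <= 0.0 || S1 <= 0.0) return NA_REAL;
    const double N = V0 + V1, S = (V0 * S0 + V1 * S1) / N;
    return N * std::log(S) - V0 * std::log(S0) - V1 * std::log(S1);
  }
  if (method == 1) {
    if (arma::norm(G0, "fro") <= 0.0 || arma::norm(G1, "fro") <= 0.0)
      return NA_REAL;
    const arma::mat u = lead_eigvecs(G0, 1), v = lead_eigvecs(G1, 1);
    double c = arma::dot(u.col(0), v.col(0));
    c = std::max(-1.0, std::min(1.0, c));
    double theta = std::acos(c);
    return theta > PI_HALF ? arma::datum::pi - theta : theta;
  }
  // Krzanowski: trace(A^T B B^T A), returned negated.
  const arma::mat A = lead_eigvecs(G0, k), B = lead_eigvecs(G1, k);
  const arma::mat M = A.t() * B;
  return -arma::accu(arma::square(M));
}

// [[Rcpp::export]]
List cpp_scan_cov(const arma::mat& Y, const IntegerMatrix& geno,
                  const int method, const int k, const int min_class,
                  const IntegerMatrix& perms) {
  const int m = geno.ncol(), np = perms.ncol(), n = geno.nrow();
  if ((int)Y.n_rows != n) stop("genotype/trait dimension mismatch");

  std::vector<arma::uvec> I0(m), I1(m);
  for (int j = 0; j < m; ++j) class_indices(geno, j, I0[j], I1[j]);

  NumericVector obs(m);
  IntegerVector n0(m), n1(m);
  for (int j = 0; j < m; ++j) {
    n0[j] = I0[j].n_elem; n1[j] = I1[j].n_elem;
    obs[j] = (n0[j] < min_class || n1[j] < min_class)
                 ? NA_REAL
                 : cov_stat(Y.rows(I0[j]), Y.rows(I1[j]), method, k);
  }

  NumericVector perm_max(np, NA_REAL);
  arma::uvec pidx(n);
  for (int p = 0; p < np; ++p) {
    for (int i = 0; i < n; ++i) pidx[i] = perms(i, p);
    const arma::mat Yp = Y.rows(pidx);
    double mx = -arma::datum::inf;
    bool any = false;
    for (int j = 0; j < m; ++j) {
      if (n0[j] < min_class || n1[j] < min_class) continue;
      const double s = cov_stat(Yp.rows(I0[j]), Yp.rows(I1[j]), method, k);
      if (!ISNAN(s) && (!any || s > mx)) { mx = s; any = true; }
    }
    if (any) perm_max[p] = mx;
  }

  return List::create(_["statistic"] = obs, _["n_CO"] = n0, _["n_MT"] = n1,
                      _["perm_max"] = perm_max);
}
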