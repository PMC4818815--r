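#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// entropy in bits of a count vector
static double h_counts(const std::vector<int> &cnt, int n) {
  double h = 0.0;
  for (size_t i = 0; i < cnt.size(); ++i) {
    if (cnt[i] > 0) {
      double p = (double)cnt[i] / n;
      h -= p * std::log2(p);
    }
  }
  return h;
}

// MI(f_j; class) for every feature and CMI(f_j; class | f_i) for every
// ordered pair, from integer code matrices. codes: n_samples x n_features,
// values in 0..B-1; cls: values in 0..C-1.
// [[Rcpp::export]]
List pairwise_cache_cpp(IntegerMatrix codes, IntegerVector cls) {
  const int n = codes.nrow(), p = codes.ncol();
  int B = 0, C = 0;
  for (int s = 0; s < n; ++s) C = std::max(C, cls[s] + 1);
  for (int j = 0; j < p; ++j)
    for (int s = 0; s < n; ++s) B = std::max(B, codes(s, j) + 1);

  NumericVector mi(p);
  NumericMatrix cmi(p, p);
  std::vector<double> h_f(p), h_fc(p);  // H(f_i), H(f_i, class)
  std::vector<int> c1(B), c2(B * C), c3(B * B), c4(B * C * B);

  std::vector<int> ccls(C, 0);
  for (int s = 0; s < n; ++s) ccls[cls[s]]++;
  const double h_c = h_counts(ccls, n);

  for (int j = 0; j < p; ++j) {
    std::fill(c1.begin(), c1.end(), 0);
    std::fill(c2.begin(), c2.begin() + B * C, 0);
    for (int s = 0; s < n; ++s) {
      c1[codes(s, j)]++;
      c2[codes(s, j) + B * cls[s]]++;
    }
    h_f[j] = h_counts(c1, n);
    std::vector<int> c2v(c2.begin(), c2.begin() + B * C);
    h_fc[j] = h_counts(c2v, n);
    double v = h_f[j] + h_c - h_fc[j];
    mi[j] = v > 0 ? v : 0.0;
  }

  // CMI(f_j; class | f_i) = H(f_j,f_i) + H(class,f_i) - H(f_i) - H(f_j,class,f_i)
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) {
      if (i == j) continue;
      std::fill(c3.begin(), c3.end(), 0);
      std::fill(c4.begin(), c4.end(), 0);
      for (int s = 0; s < n; ++s) {
        int fi = codes(s, i), fj = codes(s, j), cl = cls[s];
        c3[fj + B * fi]++;
        c4[fj + B * cl + B * C * fi]++;
      }
      double h_ji = h_counts(c3, n);
      double h_jci = h_counts(c4, n);
      double v = h_ji + h_fc[i] - h_f[i] - h_jci;
      cmi(i, j) = v > 0 ? v : 0.0;
    }
  }
  return List::create(_["mi"] = mi, _["cmi_given"] = cmi);
}

// Shapley values from the binary coalition payoff: for each feature i,
// count size-k subsets K of the other features with
//   sum_{j in K} d(i,j) >= 0   and   sum_{j in K} psi(i,j) >= k/2,
// then phi_i = count * k! (n-k-1)! / n!.
// [[Rcpp::export]]
NumericVector shapley_phi_cpp(IntegerMatrix psi, NumericMatrix d, int k) {
  const int n = psi.nrow();
  if (k < 1 || k >= n) stop("coalition size must satisfy 1 <= k <= n-1");
  // per-coalition weight k!(n-k-1)!/n! = k! / (n (n-1) ... (n-k)):
  // numerator and denominator stay exact in double for any sane k
  double num = 1.0, den = 1.0;
  for (int t = 2; t <= k; ++t) num *= t;
  for (int t = n - k; t <= n; ++t) den *= t;
  const double w = num / den;

  NumericVector phi(n);
  std::vector<int> others(n - 1), idx(k);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) if (j != i) others[m++] = j;
    // enumerate k-combinations of others
    for (int t = 0; t < k; ++t) idx[t] = t;
    long long count = 0;
    const int nm = n - 1;
    while (true) {
      double ds = 0.0; int ps = 0;
      for (int t = 0; t < k; ++t) {
        int j = others[idx[t]];
        ds += d(i, j);
        ps += psi(i, j);
      }
      if (ds >= 0.0 && 2 * ps >= k) ++count;
      // advance combination
      int t = k - 1;
      while (t >= 0 && idx[t] == nm - k + t) --t;
      if (t < 0) break;
      ++idx[t];
      for (int u = t + 1; u < k; ++u) idx[u] = idx[u - 1] + 1;
    }
    phi[i] = count * w;
  }
  return phi;
}
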