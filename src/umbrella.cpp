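#include <Rcpp.h>
using namespace Rcpp;

// Umbrella rank permutation engine.
//
// For one feature: pairwise comparison matrix C[s][t] = 1 if x_s < x_t,
// 0.5 on ties. Group-aggregated Mann-Whitney counts U[i][j] are contracted
// against per-rotation weight matrices W (k x k x k, column-major) encoding
// the umbrella ordering with each phase group as candidate peak; the
// statistic is the maximum standardized A over rotations. The permutation
// null permutes group labels (perms, 0-based, shared across features).

static double umbrella_stat(const std::vector<double>& C, int n,
                            const int* g, const int* perm, int k,
                            const double* W, const double* E,
                            const double* SD, std::vector<double>& U) {
  std::fill(U.begin(), U.end(), 0.0);
  for (int s = 0; s < n; ++s) {
    int gs = perm ? g[perm[s]] : g[s];
    for (int t = 0; t < n; ++t) {
      int gt = perm ? g[perm[t]] : g[t];
      U[gs + k * gt] += C[s + n * t];
    }
  }
  double best = R_NegInf;
  for (int r = 0; r < k; ++r) {
    double A = 0.0;
    const double* Wr = W + r * k * k;
    for (int q = 0; q < k * k; ++q) A += Wr[q] * U[q];
    double z = (A - E[r]) / SD[r];
    if (z > best) best = z;
  }
  return best;
}

// [[Rcpp::export]]
List umbrella_perm_pvalues(NumericMatrix X, IntegerVector g,
                           IntegerMatrix perms, NumericVector W,
                           NumericVector E, NumericVector SD) {
  const int nf = X.nrow(), n = X.ncol(), k = E.size();
  const int np = perms.nrow();
  std::vector<int> g0(n);
  for (int s = 0; s < n; ++s) g0[s] = g[s];
  // copy permutations row-wise for cache-friendly access
  std::vector<int> P((size_t)np * n);
  for (int b = 0; b < np; ++b)
    for (int s = 0; s < n; ++s) P[(size_t)b * n + s] = perms(b, s);
  NumericVector pval(nf), stat(nf);
  std::vector<double> C((size_t)n * n), U((size_t)k * k);
  for (int f = 0; f < nf; ++f) {
    for (int s = 0; s < n; ++s)
      for (int t = 0; t < n; ++t) {
        double xs = X(f, s), xt = X(f, t);
        C[s + n * t] = xs < xt ? 1.0 : (xs == xt ? 0.5 : 0.0);
      }
    double obs = umbrella_stat(C, n, g0.data(), nullptr, k, W.begin(),
                               E.begin(), SD.begin(), U);
    int ge = 0;
    for (int b = 0; b < np; ++b) {
      double st = umbrella_stat(C, n, g0.data(), P.data() + (size_t)b * n, k,
                                W.begin(), E.begin(), SD.begin(), U);
      if (st >= obs - 1e-9) ++ge;
    }
    pval[f] = (1.0 + ge) / (np + 1.0);
    stat[f] = obs;
  }
  return List::create(_["p"] = pval, _["stat"] = stat);
}

// [[Rcpp::export]]
List umbrella_exact_pvalues(NumericMatrix X, IntegerVector g,
                            IntegerMatrix perms, NumericVector W,
                            NumericVector E, NumericVector SD) {
  // perms here enumerates ALL permutations (including the identity);
  // p = #{stat >= observed} / #perms
  const int nf = X.nrow(), n = X.ncol(), k = E.size();
  const int np = perms.nrow();
  std::vector<int> g0(n);
  for (int s = 0; s < n; ++s) g0[s] = g[s];
  std::vector<int> P((size_t)np * n);
  for (int b = 0; b < np; ++b)
    for (int s = 0; s < n; ++s) P[(size_t)b * n + s] = perms(b, s);
  NumericVector pval(nf), stat(nf);
  std::vector<double> C((size_t)n * n), U((size_t)k * k);
  for (int f = 0; f < nf; ++f) {
    for (int s = 0; s < n; ++s)
      for (int t = 0; t < n; ++t) {
        double xs = X(f, s), xt = X(f, t);
        C[s + n * t] = xs < xt ? 1.0 : (xs == xt ? 0.5 : 0.0);
      }
    double obs = umbrella_stat(C, n, g0.data(), nullptr, k, W.begin(),
                               E.begin(), SD.begin(), U);
    int ge = 0;
    for (int b = 0; b < np; ++b) {
      double st = umbrella_stat(C, n, g0.data(), P.data() + (size_t)b * n, k,
                                W.begin(), E.begin(), SD.begin(), U);
      if (st >= obs - 1e-9) ++ge;
    }
    pval[f] = (double)ge / np;
    stat[f] = obs;
  }
  return List::create(_["p"] = pval, _["stat"] = stat);
}
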