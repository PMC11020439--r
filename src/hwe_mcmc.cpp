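#include <Rcpp.h>
using namespace Rcpp;

// Markov chain over genotype tables with fixed allele counts.
// State: 2n allele-copy slots arranged as n ordered pairs.  A random
// transposition of two slot contents is always accepted; the uniform
// distribution over labelled arrangements induces exactly the conditional
// Hardy-Weinberg distribution P(f) proportional to 2^h / prod(f_ij!).
// The p-value is the chain fraction of tables no more probable than the
// observed one (tie convention: table probability).

static inline int cell(int a, int b, int k) {
  // lower-triangular index (row >= col)
  int r = a > b ? a : b, c = a > b ? b : a;
  return r * k + c;
}

// [[Rcpp::export]]
double hwe_mcmc_cpp(IntegerVector i1, IntegerVector i2, int k,
                    int steps, int dememorization) {
  int n = i1.size();
  std::vector<int> slot(2 * n);
  for (int g = 0; g < n; ++g) { slot[2 * g] = i1[g]; slot[2 * g + 1] = i2[g]; }

  std::vector<double> f(k * k, 0.0);
  for (int g = 0; g < n; ++g) f[cell(slot[2 * g], slot[2 * g + 1], k)] += 1.0;

  // log P up to a constant: h log 2 - sum lgamma(f+1)
  double logp = 0.0;
  for (int r = 0; r < k; ++r)
    for (int c = 0; c <= r; ++c) {
      double v = f[r * k + c];
      logp -= R::lgammafn(v + 1.0);
      if (r != c) logp += v * 0.0; // het bonus added below per genotype
    }
  double h = 0.0;
  for (int g = 0; g < n; ++g) if (slot[2 * g] != slot[2 * g + 1]) h += 1.0;
  logp += h * M_LN2;

  const double logp_obs = logp;
  const double tol = 1e-9 * (1.0 + std::fabs(logp_obs));

  long hits = 0;
  int total = steps + dememorization;
  for (int t = 0; t < total; ++t) {
    int s1 = (int)(unif_rand() * 2 * n);
    int s2 = (int)(unif_rand() * 2 * n);
    if (s1 >= 2 * n) s1 = 2 * n - 1;
    if (s2 >= 2 * n) s2 = 2 * n - 1;
    int p1 = s1 / 2, p2 = s2 / 2;
    if (p1 != p2 && slot[s1] != slot[s2]) {
      int g1o = cell(slot[2 * p1], slot[2 * p1 + 1], k);
      int g2o = cell(slot[2 * p2], slot[2 * p2 + 1], k);
      bool h1o = slot[2 * p1] != slot[2 * p1 + 1];
      bool h2o = slot[2 * p2] != slot[2 * p2 + 1];
      std::swap(slot[s1], slot[s2]);
      int g1n = cell(slot[2 * p1], slot[2 * p1 + 1], k);
      int g2n = cell(slot[2 * p2], slot[2 * p2 + 1], k);
      bool h1n = slot[2 * p1] != slot[2 * p1 + 1];
      bool h2n = slot[2 * p2] != slot[2 * p2 + 1];
      // incremental log-probability update, cell by cell so that pairs
      // sharing a genotype cell are handled correctly
      logp += R::lgammafn(f[g1o] + 1.0); f[g1o] -= 1.0;
      logp -= R::lgammafn(f[g1o] + 1.0);
      logp += R::lgammafn(f[g2o] + 1.0); f[g2o] -= 1.0;
      logp -= R::lgammafn(f[g2o] + 1.0);
      logp += R::lgammafn(f[g1n] + 1.0); f[g1n] += 1.0;
      logp -= R::lgammafn(f[g1n] + 1.0);
      logp += R::lgammafn(f[g2n] + 1.0); f[g2n] += 1.0;
      logp -= R::lgammafn(f[g2n] + 1.0);
      logp += ((int)h1n + (int)h2n - (int)h1o - (int)h2o) * M_LN2;
    }
    if (t >= dememorization && logp <= logp_obs + tol) ++hits;
  }
  return (double)hits / (double)steps;
}
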