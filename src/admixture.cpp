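#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with independent allele frequencies
// (the standard Bayesian clustering model for unlinked co-dominant loci).
// Data: per individual and locus, two allele-copy indices (0-based within
// locus; NA_INTEGER = missing).  One sweep:
//   1. cluster allele frequencies ~ Dirichlet(lambda + assignment counts)
//   2. each allele copy's cluster ~ Categorical(q_i[k] * freq[k][l][a])
//   3. each individual's q_i ~ Dirichlet(alpha + its assignment counts)
// Returns the posterior-mean Q and the mean post-burn-in log-likelihood
// log P(data | Q, freq) (plus first/second-half means for a convergence
// check).

static void rdirichlet_inplace(std::vector<double> &x, const double *shape,
                               int m) {
  double s = 0.0;
  for (int i = 0; i < m; ++i) { x[i] = R::rgamma(shape[i], 1.0); s += x[i]; }
  if (s <= 0.0) {
    for (int i = 0; i < m; ++i) x[i] = 1.0 / m;
  } else {
    for (int i = 0; i < m; ++i) x[i] /= s;
  }
}

// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                         int K, int steps, int burn_in,
                         double alpha, double lambda,
                         bool sample_alpha, double alpha_max) {
  int n = geno.nrow();
  int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("geno must have 2 columns per locus");
  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) off[l + 1] = off[l] + n_alleles[l];
  int A = off[L];

  // state
  std::vector<double> freq((size_t)K * A, 0.0);
  std::vector<double> q((size_t)n * K, 1.0 / K);
  std::vector<int> z((size_t)n * 2 * L, -1);
  std::vector<double> cnt_freq((size_t)K * A, 0.0);
  std::vector<double> cnt_ind(K, 0.0);
  std::vector<double> qsum((size_t)n * K, 0.0);
  std::vector<double> tmpK(K), shape(A > K ? A : K);

  // init: random assignments
  for (size_t c = 0; c < z.size(); ++c) {
    int a = geno[c]; // column-major walk matches below only via index math; init any
    (void)a;
    z[c] = (int)(unif_rand() * K);
    if (z[c] >= K) z[c] = K - 1;
  }

  double ll_sum1 = 0.0, ll_sum2 = 0.0;
  int kept = 0, half = (steps - burn_in) / 2;

  for (int t = 0; t < steps; ++t) {
    // 1. frequency update
    std::fill(cnt_freq.begin(), cnt_freq.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a == NA_INTEGER) continue;
          int k = z[((size_t)i * L + l) * 2 + c];
          cnt_freq[(size_t)k * A + off[l] + a] += 1.0;
        }
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        int m = n_alleles[l];
        for (int a = 0; a < m; ++a)
          shape[a] = lambda + cnt_freq[(size_t)k * A + off[l] + a];
        std::vector<double> row(m);
        rdirichlet_inplace(row, shape.data(), m);
        for (int a = 0; a < m; ++a) freq[(size_t)k * A + off[l] + a] = row[a];
      }

    // 2./3. per individual: copy assignments then q
    for (int i = 0; i < n; ++i) {
      std::fill(cnt_ind.begin(), cnt_ind.end(), 0.0);
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a == NA_INTEGER) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            tmpK[k] = q[(size_t)i * K + k] * freq[(size_t)k * A + off[l] + a];
            s += tmpK[k];
          }
          int knew = K - 1;
          if (s > 0) {
            double u = unif_rand() * s, acc = 0.0;
            for (int k = 0; k < K; ++k) {
              acc += tmpK[k];
              if (u < acc) { knew = k; break; }
            }
          } else {
            knew = (int)(unif_rand() * K);
            if (knew >= K) knew = K - 1;
          }
          z[((size_t)i * L + l) * 2 + c] = knew;
          cnt_ind[knew] += 1.0;
        }
      for (int k = 0; k < K; ++k) shape[k] = alpha + cnt_ind[k];
      std::vector<double> qi(K);
      rdirichlet_inplace(qi, shape.data(), K);
      for (int k = 0; k < K; ++k) q[(size_t)i * K + k] = qi[k];
    }

    // optional Metropolis update of the membership concentration alpha
    // (uniform prior on (0, alpha_max), log-scale random-walk proposal)
    if (sample_alpha && K > 1) {
      double sum_log_q = 0.0;
      for (size_t j = 0; j < q.size(); ++j)
        sum_log_q += std::log(q[j] > 1e-300 ? q[j] : 1e-300);
      double prop = alpha * std::exp(0.3 * norm_rand());
      if (prop > 0 && prop < alpha_max) {
        double lcur = n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                      (alpha - 1.0) * sum_log_q;
        double lnew = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) +
                      (prop - 1.0) * sum_log_q;
        // log-scale proposal: Jacobian ratio prop/alpha
        if (std::log(unif_rand()) < lnew - lcur +
            std::log(prop) - std::log(alpha))
          alpha = prop;
      }
    }

    if (t >= burn_in) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a == NA_INTEGER) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k)
              s += q[(size_t)i * K + k] * freq[(size_t)k * A + off[l] + a];
            ll += std::log(s > 1e-300 ? s : 1e-300);
          }
      if (kept < half) ll_sum1 += ll; else ll_sum2 += ll;
      for (size_t j = 0; j < qsum.size(); ++j) qsum[j] += q[j];
      ++kept;
    }
  }

  NumericMatrix Q(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      Q(i, k) = qsum[(size_t)i * K + k] / kept;
  double alpha_final = alpha;
  double llm1 = half > 0 ? ll_sum1 / half : NA_REAL;
  double llm2 = (kept - half) > 0 ? ll_sum2 / (kept - half) : NA_REAL;
  double llm = (ll_sum1 + ll_sum2) / kept;
  return List::create(_["Q"] = Q, _["loglik"] = llm,
                      _["loglik_half1"] = llm1, _["loglik_half2"] = llm2,
                      _["kept"] = kept, _["alpha"] = alpha_final);
}
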