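#include <Rcpp.h>
using namespace Rcpp;

// Equilibrium-heterozygosity simulators for the heterozygosity-excess
// bottleneck test (Cornuet & Luikart procedure): draw allele configurations
// of n genes at mutation-drift equilibrium, conditioned on the observed
// allele number k, and return the unbiased sample heterozygosity
// (n/(n-1)) (1 - sum (n_i/n)^2) of each accepted replicate.

static double het_from_counts(const std::vector<int> &cnt, int n) {
  double s = 0.0;
  for (size_t i = 0; i < cnt.size(); ++i) {
    double p = (double)cnt[i] / n;
    s += p * p;
  }
  return (double)n / (n - 1.0) * (1.0 - s);
}

// Chinese-restaurant-process draw of an infinite-alleles configuration:
// gene i starts a new allele with probability theta / (theta + i).
static int crp_draw(int n, double theta, std::vector<int> &cnt) {
  cnt.clear();
  for (int i = 0; i < n; ++i) {
    double u = unif_rand() * (theta + i);
    if (u < theta) {
      cnt.push_back(1);
    } else {
      // join an existing allele class proportional to its size
      double target = u - theta;
      double acc = 0.0;
      for (size_t j = 0; j < cnt.size(); ++j) {
        acc += cnt[j];
        if (target < acc) { cnt[j] += 1; break; }
      }
    }
  }
  return (int)cnt.size();
}

// [[Rcpp::export]]
NumericVector heq_iam_cpp(int n_genes, int k_obs, double theta, int n_sim,
                          double max_tries) {
  NumericVector out(n_sim);
  std::vector<int> cnt;
  double tries = 0.0;
  int got = 0;
  while (got < n_sim) {
    if (++tries > max_tries)
      stop("acceptance rate below threshold; review n_genes/k_obs/theta");
    if (crp_draw(n_genes, theta, cnt) == k_obs)
      out[got++] = het_from_counts(cnt, n_genes);
  }
  return out;
}

// Stepwise / two-phase mutation on a Kingman coalescent genealogy.
// p_ss = 1 gives the strict stepwise model; with probability 1 - p_ss a
// mutation moves by a geometric(q) number of repeat units (variance set by
// the caller), sign symmetric.
struct Tree {
  std::vector<int> left, right;    // children (-1 for tips)
  std::vector<double> t;           // node times (tips at 0)
};

static void sim_tree(int n, Tree &tr) {
  int total = 2 * n - 1;
  tr.left.assign(total, -1); tr.right.assign(total, -1);
  tr.t.assign(total, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double time = 0.0;
  int next = n;
  for (int j = n; j >= 2; --j) {
    double rate = j * (j - 1) / 2.0;
    time += exp_rand() / rate;
    int a = (int)(unif_rand() * j); if (a >= j) a = j - 1;
    int b = (int)(unif_rand() * (j - 1)); if (b >= j - 1) b = j - 2;
    if (b >= a) ++b;
    tr.left[next] = active[a]; tr.right[next] = active[b]; tr.t[next] = time;
    // replace a by the new node, remove b
    active[a] = next;
    active[b] = active[j - 1];
    active.pop_back();
    ++next;
  }
}

static int mut_steps(double p_ss, double geom_q) {
  int sz = 1;
  if (p_ss < 1.0 && unif_rand() > p_ss)
    sz = 1 + (int)R::rgeom(geom_q);
  return unif_rand() < 0.5 ? -sz : sz;
}

static int smm_config(int n, double theta, double p_ss, double geom_q,
                      std::vector<int> &sizes) {
  Tree tr;
  sim_tree(n, tr);
  int total = 2 * n - 1;
  std::vector<int> state(total, 0);
  // iterate nodes from root downward (higher index = older)
  for (int v = total - 1; v >= n; --v) {
    int ch[2] = { tr.left[v], tr.right[v] };
    for (int c = 0; c < 2; ++c) {
      int w = ch[c];
      double len = tr.t[v] - tr.t[w];
      int nm = (int)R::rpois(0.5 * theta * len);
      int s = state[v];
      for (int m = 0; m < nm; ++m) s += mut_steps(p_ss, geom_q);
      state[w] = s;
    }
  }
  sizes.assign(state.begin(), state.begin() + n);
  std::vector<int> sorted(sizes);
  std::sort(sorted.begin(), sorted.end());
  int k = 1;
  for (int i = 1; i < n; ++i) if (sorted[i] != sorted[i - 1]) ++k;
  return k;
}

// [[Rcpp::export]]
NumericVector heq_smm_cpp(int n_genes, int k_obs, double theta, int n_sim,
                          double p_ss, double geom_q, double max_tries) {
  NumericVector out(n_sim);
  std::vector<int> sizes;
  double tries = 0.0;
  int got = 0;
  while (got < n_sim) {
    if (++tries > max_tries)
      stop("acceptance rate below threshold; review n_genes/k_obs/theta");
    if (smm_config(n_genes, theta, p_ss, geom_q, sizes) == k_obs) {
      std::map<int, int> tab;
      for (size_t i = 0; i < sizes.size(); ++i) tab[sizes[i]] += 1;
      std::vector<int> cnt;
      for (std::map<int, int>::iterator it = tab.begin(); it != tab.end(); ++it)
        cnt.push_back(it->second);
      out[got++] = het_from_counts(cnt, n_genes);
    }
  }
  return out;
}

// Monte-Carlo expected allele count under the stepwise / two-phase model,
// used by the bisection that matches theta to the observed allele number.
// [[Rcpp::export]]
double expected_k_smm_cpp(int n_genes, double theta, int nrep,
                          double p_ss, double geom_q) {
  std::vector<int> sizes;
  double acc = 0.0;
  for (int r = 0; r < nrep; ++r)
    acc += smm_config(n_genes, theta, p_ss, geom_q, sizes);
  return acc / nrep;
}
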