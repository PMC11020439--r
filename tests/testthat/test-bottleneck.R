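# Exhaustive Ewens-sampling-formula oracle: conditional on the allele count
# the configuration distribution is theta-free, with weight
# n! / (prod_j j^{a_j} a_j!) for a partition with a_j classes of size j.
ewens_mean_he <- function(n, k) {
  parts <- function(n, k, mx) {
    if (k == 1) return(if (n <= mx) list(n) else list())
    out <- list()
    for (first in seq(min(n - k + 1, mx), 1))
      for (rest in parts(n - first, k - 1, first))
        out[[length(out) + 1]] <- c(first, rest)
    out
  }
  ps <- parts(n, k, n)
  w <- he <- numeric(length(ps))
  for (i in seq_along(ps)) {
    aj <- table(ps[[i]])
    w[i] <- exp(lfactorial(n) -
                  sum(as.numeric(aj) * log(as.numeric(names(aj)))) -
                  sum(lfactorial(as.numeric(aj))))
    he[i] <- n / (n - 1) * (1 - sum((ps[[i]] / n)^2))
  }
  sum(w * he) / sum(w)
}

test_that("equilibrium heterozygosity simulator: degenerate allele counts", {
  expect_equal(simulate_heq(10, 1, n_sim = 50), rep(0, 50))
  # every gene its own allele: unbiased He is exactly 1
  expect_equal(simulate_heq(4, 4, n_sim = 50), rep(1, 50))
  expect_error(simulate_heq(4, 5), "k_obs")
})

test_that("IAM equilibrium heterozygosity matches the Ewens oracle", {
  for (cs in list(c(6, 2), c(8, 3))) {
    oracle <- ewens_mean_he(cs[1], cs[2])
    sim <- simulate_heq(cs[1], cs[2], mutation_model("IAM"),
                        n_sim = 5000, seed = 5)
    se <- stats::sd(sim) / sqrt(length(sim))
    expect_lt(abs(mean(sim) - oracle), 4 * se + 0.005)
  }
})

test_that("Heq mean rises with the allele count and SMM exceeds IAM", {
  n <- 40
  means_iam <- vapply(c(3, 6, 10), function(k)
    mean(simulate_heq(n, k, mutation_model("IAM"), 2500, seed = k)), 1)
  expect_true(all(diff(means_iam) > 0))          # monotone in k
  for (k in c(4, 8)) {
    hi <- mean(simulate_heq(n, k, mutation_model("IAM"), 2500, seed = 1))
    ht <- mean(simulate_heq(n, k, mutation_model("TPM"), 2500, seed = 1))
    hs <- mean(simulate_heq(n, k, mutation_model("SMM"), 2500, seed = 1))
    # stepwise mutation maintains fewer, more even alleles: for a fixed
    # allele count its equilibrium heterozygosity is the highest, the
    # two-phase model sits in between
    expect_gt(hs, ht)
    expect_gt(ht, hi)
  }
})

test_that("one-tailed Wilcoxon signed-rank: exact tail and symmetry", {
  # 14 positive values with distinct magnitudes: exact p = 2^-14
  x <- seq(0.1, 1.4, by = 0.1)
  r <- msatpop:::wilcoxon_signed_rank_greater(x)
  expect_equal(r$p, 1 / 2^14)
  expect_equal(r$method, "exact")
  # symmetric +/- pairs: p near one half
  y <- c(seq(0.1, 0.7, 0.1), -seq(0.1, 0.7, 0.1) - 0.001)
  expect_gt(msatpop:::wilcoxon_signed_rank_greater(y)$p, 0.3)
  expect_lt(msatpop:::wilcoxon_signed_rank_greater(y)$p, 0.7)
  # degenerate: everything zero
  expect_equal(msatpop:::wilcoxon_signed_rank_greater(rep(0, 5))$p, 1)
})

test_that("heterozygosity-excess test needs four polymorphic loci", {
  p <- random_hwe_panel(20, 2, 4, seed = 3)
  expect_error(heterozygosity_excess_test(p, model = mutation_model("IAM"),
                                          n_sim = 50),
               "4 polymorphic")
})

test_that("M-ratio follows the ladder-occupancy definition", {
  full <- toy_panel(cbind(c(200L, 204L)), cbind(c(208L, 204L)), motif = 4)
  expect_equal(m_ratio(full, 1)$m, 1.0)                 # k=3, r=2
  gap <- toy_panel(cbind(c(200L, 200L)), cbind(c(208L, 208L)), motif = 4)
  expect_equal(m_ratio(gap, 1)$m, 2 / 3)                # k=2, r=2
  mono <- toy_panel(cbind(c(200L, 200L)), cbind(c(200L, 200L)), motif = 4)
  expect_equal(m_ratio(mono, 1)$m, 1)                   # r=0 convention
  off <- toy_panel(cbind(c(200L, 200L)), cbind(c(206L, 206L)), motif = 4)
  r <- m_ratio(off, 1)
  expect_true(r$off_ladder)
  expect_equal(r$r, 1L)                                 # floor(6/4)
})

test_that("deleting interior alleles lowers M below the full-ladder value 1", {
  set.seed(9)
  for (rep in 1:10) {
    k <- sample(4:9, 1)
    sizes <- 200L + 4L * (seq_len(k) - 1L)
    a <- sample(sizes, 30, replace = TRUE)
    b <- sample(sizes, 30, replace = TRUE)
    p <- toy_panel(cbind(a), cbind(b), motif = 4)
    if (length(unique(c(a, b))) < k) next
    expect_equal(m_ratio(p, 1)$m, 1.0)
    # delete one interior rung: individuals carrying it re-coded to an edge
    interior <- sizes[2]
    a[a == interior] <- sizes[1]; b[b == interior] <- sizes[1]
    p2 <- toy_panel(cbind(a), cbind(b), motif = 4)
    expect_lt(m_ratio(p2, 1)$m, 1.0)
  }
})

test_that("a recent crash lowers the M-ratio against a matched control", {
  drops <- 0; n_pairs <- 10
  for (r in seq_len(n_pairs)) {
    crash <- simulate_wright_fisher(wf_config(
      true_ne = 100, n_loci = 40, n_generations = 300, mutation_rate = 1e-2,
      sample_size = 10, founder_alleles = 10, seed = r,
      size_schedule = data.frame(generation = 295, size = 10)))
    ctrl <- simulate_wright_fisher(wf_config(
      true_ne = 100, n_loci = 40, n_generations = 300, mutation_rate = 1e-2,
      sample_size = 10, founder_alleles = 10, seed = r))
    if (m_ratio_mean(crash, "all", "pooled")$m_mean <
        m_ratio_mean(ctrl, "all", "pooled")$m_mean) drops <- drops + 1
  }
  expect_gte(drops, 9)
})

test_that("crashed populations show heterozygosity excess under the SMM reference", {
  sig_crash <- sig_ctrl <- 0
  for (r in 1:5) {
    crash <- simulate_wright_fisher(wf_config(
      true_ne = 500, n_loci = 15, n_generations = 400, mutation_rate = 5e-3,
      sample_size = 30, founder_alleles = 10, seed = r,
      size_schedule = data.frame(generation = 395, size = 30)))
    ctrl <- simulate_wright_fisher(wf_config(
      true_ne = 500, n_loci = 15, n_generations = 400, mutation_rate = 5e-3,
      sample_size = 30, founder_alleles = 10, seed = r))
    pc <- heterozygosity_excess_test(crash, "all", "pooled",
                                     mutation_model("SMM"), 150, seed = r)$p_value
    p0 <- heterozygosity_excess_test(ctrl, "all", "pooled",
                                     mutation_model("SMM"), 150, seed = r)$p_value
    if (pc < 0.05) sig_crash <- sig_crash + 1
    if (p0 < 0.05) sig_ctrl <- sig_ctrl + 1
  }
  expect_gt(sig_crash, sig_ctrl)
})
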