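# Independent Weir-Cockerham component oracle for one biallelic locus and
# two populations, written from the explicit count formulas.
wc_theta_oracle <- function(x1, x2, y1, y2, allele) {
  stat <- function(a, b) {
    n <- length(a)
    p <- (sum(a == allele) + sum(b == allele)) / (2 * n)
    h <- mean((a == allele) != (b == allele))
    c(n = n, p = p, h = h)
  }
  s1 <- stat(x1, x2); s2 <- stat(y1, y2)
  r <- 2
  ns <- c(s1["n"], s2["n"]); ps <- c(s1["p"], s2["p"]); hs <- c(s1["h"], s2["h"])
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ns * ps) / (r * nbar)
  s2v <- sum(ns * (ps - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ns * hs) / (r * nbar)
  a <- (nbar / nc) * (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v -
                               hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2v -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = unname(a), b = unname(b), c = unname(cc))
}

test_that("Weir-Cockerham theta matches the component oracle on a toy panel", {
  set.seed(4)
  n <- 10
  a1 <- sample(c(100L, 104L), n, TRUE); a2 <- sample(c(100L, 104L), n, TRUE)
  b1 <- sample(c(100L, 104L), n, TRUE, prob = c(.8, .2))
  b2 <- sample(c(100L, 104L), n, TRUE, prob = c(.8, .2))
  p <- toy_panel(cbind(c(a1, b1)), cbind(c(a2, b2)),
                 sections = rep(c("P1", "P2"), each = n))
  # sum the per-allele components (two alleles at a biallelic locus give
  # mirrored components; theta uses their sum)
  o100 <- wc_theta_oracle(a1, a2, b1, b2, 100L)
  o104 <- wc_theta_oracle(a1, a2, b1, b2, 104L)
  tot <- o100 + o104
  theta_oracle <- tot["a"] / sum(tot)
  res <- fst_weir_cockerham(p)
  expect_equal(res$theta, unname(theta_oracle), tolerance = 1e-12)
})

test_that("theta is near zero for identical populations and one when fixed", {
  p <- simulate_panel(sim_config(n_individuals = 400, n_loci = 10,
                                 stock_divergence_fst = 0, fis = 0,
                                 season_mixture = list(rainy = .5, dry = .5),
                                 seed = 41))
  th <- fst_weir_cockerham(p, grouping = "stock")$theta
  expect_lt(abs(th), 0.01)

  fixed <- toy_panel(cbind(c(rep(100L, 8), rep(104L, 8))),
                     cbind(c(rep(100L, 8), rep(104L, 8))),
                     sections = rep(c("A", "B"), each = 8))
  expect_equal(fst_weir_cockerham(fixed)$theta, 1)
})

test_that("standardized F'ST dominates FST and saturates on disjoint panels", {
  fixed <- toy_panel(cbind(c(rep(100L, 8), rep(104L, 8))),
                     cbind(c(rep(100L, 8), rep(104L, 8))),
                     sections = rep(c("A", "B"), each = 8))
  fs <- fst_standardized(fixed, permutations = 0)
  expect_equal(fs$fst_std, 1)
  for (s in 1:10) {
    p <- simulate_panel(sim_config(n_individuals = 60, n_loci = 4,
                                   stock_divergence_fst = 0.05, fis = 0,
                                   season_mixture = list(rainy = .5, dry = .5),
                                   seed = 500 + s))
    fs <- fst_standardized(p, grouping = "stock", permutations = 0)
    expect_gte(fs$fst_std, fs$fst - 1e-12)
  }
})

test_that("Jost's D: trivial poles and the direct-formula oracle", {
  fixed <- toy_panel(cbind(c(rep(100L, 8), rep(104L, 8))),
                     cbind(c(rep(100L, 8), rep(104L, 8))),
                     sections = rep(c("A", "B"), each = 8))
  expect_equal(jost_dest(fixed)$d, 1)

  same <- toy_panel(cbind(rep(c(100L, 104L), 20)),
                    cbind(rep(c(104L, 100L), 20)),
                    sections = rep(c("A", "B"), 20))
  expect_lt(abs(jost_dest(same)$d), 0.03)

  # mirrored biallelic frequencies (0.7, 0.3) vs (0.3, 0.7), n = 50 each:
  # direct evaluation of the sample-size-corrected estimator
  mk <- function(p70) {
    g <- c(rep(100L, round(70)), rep(104L, 30))
    g                             # 100 allele copies at the given frequencies
  }
  cA <- c(rep(100L, 70), rep(104L, 30))
  cB <- c(rep(100L, 30), rep(104L, 70))
  pan <- toy_panel(cbind(c(cA[1:50], cB[1:50])),
                   cbind(c(cA[51:100], cB[51:100])),
                   sections = rep(c("A", "B"), each = 50))
  fA <- table(factor(cA, c(100, 104))) / 100
  fB <- table(factor(cB, c(100, 104))) / 100
  hs <- mean(c(1 - sum(fA^2), 1 - sum(fB^2)))
  ht <- 1 - sum(((fA + fB) / 2)^2)
  ntil <- 50
  hs_p <- 2 * ntil / (2 * ntil - 1) * hs
  ht_p <- ht + hs_p / (2 * ntil * 2)
  d_oracle <- 2 * (ht_p - hs_p) / (1 - hs_p)
  expect_equal(jost_dest(pan)$d, d_oracle, tolerance = 1e-12)
})

test_that("AMOVA: null split, df line, and the moment-equation oracle", {
  # random split of one panmictic sample
  p <- random_hwe_panel(60, 4, 6, seed = 61)
  p$meta$section <- rep(c("A", "B"), 30)
  am <- amova(p, permutations = 99, seed = 1)
  expect_lt(abs(am$phi_st), 0.02)
  expect_gt(am$p_value, 0.05)

  # df printed as (groups - 1, 2N - 1)
  q <- simulate_panel(sim_config(seed = 62))   # 324 fish, 5 sections
  aq <- amova(q, permutations = 0)
  expect_equal(aq$df_among, 4L)
  expect_equal(aq$df_total, 647L)
  expect_gte(aq$phi_st_floored, 0)
  expect_lt(aq$phi_st_floored, 0.02)

  # tiny-instance oracle: 3 individuals, 1 locus, groups {i1,i2} vs {i3};
  # allele-identity distances enumerated by hand
  tp <- toy_panel(cbind(c(100L, 100L, 104L)), cbind(c(100L, 104L, 104L)),
                  sections = c("G1", "G1", "G2"))
  am3 <- amova(tp, permutations = 0)
  copies <- list(g1 = c(100, 100, 100, 104), g2 = c(104, 104))
  allc <- unlist(copies)
  sst <- sum(outer(allc, allc, "!=")) / 2 / length(allc)
  ssw <- sum(vapply(copies, function(x)
    sum(outer(x, x, "!=")) / 2 / length(x), 1))
  ssa <- sst - ssw
  s2w <- ssw / (6 - 2)
  n0 <- (6 - (16 + 4) / 6) / 1
  s2a <- (ssa / 1 - s2w) / n0
  expect_equal(am3$ss_among, ssa, tolerance = 1e-12)
  expect_equal(am3$ss_within, ssw, tolerance = 1e-12)
  expect_equal(am3$sigma2_among, s2a, tolerance = 1e-12)
  expect_equal(am3$sigma2_within, s2w, tolerance = 1e-12)
  expect_equal(am3$phi_st, s2a / (s2a + s2w), tolerance = 1e-12)
})

test_that("AMOVA Phi approximates Weir-Cockerham theta on balanced panels", {
  p <- simulate_panel(sim_config(n_individuals = 300, n_loci = 10,
                                 stock_divergence_fst = 0.05, fis = 0,
                                 season_mixture = list(rainy = .5, dry = .5),
                                 seed = 71))
  phi <- amova(p, grouping = "stock", permutations = 0)$phi_st
  th <- fst_weir_cockerham(p, grouping = "stock")$theta
  expect_lt(abs(phi - th), 0.005)
})

test_that("exact G-test: degenerate equality and the enumeration oracle", {
  # identical allele counts in both populations: every fish heterozygous
  eq <- toy_panel(cbind(rep(100L, 20)), cbind(rep(104L, 20)),
                  sections = rep(c("A", "B"), 10))
  gt <- g_test_differentiation(eq, draws = 199, seed = 1)
  expect_equal(gt$per_locus$g[1], 0)
  expect_equal(gt$per_locus$p[1], 1)

  # 2x2 table 30/10 vs 10/30: complete enumeration over the margin-fixed
  # table space, p = sum of hypergeometric probabilities of tables with
  # G >= G_obs
  cA <- c(rep(100L, 30), rep(104L, 10)); cB <- c(rep(100L, 10), rep(104L, 30))
  pan <- toy_panel(cbind(c(cA[1:20], cB[1:20])),
                   cbind(c(cA[21:40], cB[21:40])),
                   sections = rep(c("A", "B"), each = 20))
  gstat <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    2 * sum(tab[tab > 0] * log(tab[tab > 0] / e[tab > 0]))
  }
  gobs <- gstat(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  p_enum <- 0
  for (x in 0:40) {
    tab <- matrix(c(x, 40 - x, 40 - x, x), 2, byrow = TRUE)
    if (gstat(tab) >= gobs - 1e-9)
      p_enum <- p_enum + stats::dhyper(x, 40, 40, 40)
  }
  gt2 <- g_test_differentiation(pan, draws = 4000, seed = 2)
  expect_lt(abs(gt2$per_locus$p[1] - p_enum), 0.01)
})

test_that("the G-test detects simulated stock divergence", {
  sig <- 0
  for (s in 1:5) {
    p <- simulate_panel(sim_config(n_individuals = 300, n_loci = 14,
                                   stock_divergence_fst = 0.05, fis = 0,
                                   season_mixture = list(rainy = .5, dry = .5),
                                   seed = 600 + s))
    gt <- g_test_differentiation(p, grouping = "stock", draws = 300, seed = s)
    if (gt$global$p_value < 0.001) sig <- sig + 1
  }
  expect_gte(sig, 5)
})

test_that("pairwise matrices are symmetric with zero diagonal", {
  p <- simulate_panel(sim_config(n_individuals = 90, n_loci = 5, seed = 81,
                                 section_sizes = c(A = 30, B = 30, C = 30)))
  pd <- pairwise_differentiation(p, permutations = 0)
  expect_equal(pd$fst_std, t(pd$fst_std))
  expect_equal(pd$dest, t(pd$dest))
  expect_equal(diag(pd$fst_std), c(A = 0, B = 0, C = 0))
  expect_equal(pd$combined[upper.tri(pd$combined)],
               pd$dest[upper.tri(pd$dest)])
})
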