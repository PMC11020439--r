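test_that("K = 1 gives a unit membership column and the pooled likelihood", {
  p <- random_hwe_panel(30, 4, 5, seed = 51)
  run <- admixture_mcmc(p, K = 1, steps = 300, burn_in = 100, seed = 1)
  expect_equal(dim(run$Q), c(30, 1))
  expect_equal(unname(run$Q[, 1]), rep(1, 30))
  # multinomial log-likelihood of the pooled frequencies (the Dirichlet
  # posterior-mean frequencies differ from the MLE only by the prior)
  ll <- 0
  for (j in 1:4) {
    f <- allele_frequencies(p, j)
    copies <- c(p$a1[, j], p$a2[, j])
    ll <- ll + sum(log(f[as.character(copies)]))
  }
  expect_equal(run$loglik, ll, tolerance = abs(0.02 * ll))
})

test_that("the sampler is deterministic given a seed and rows sum to one", {
  p <- simulate_panel(sim_config(n_individuals = 50, n_loci = 5, seed = 52))
  r1 <- admixture_mcmc(p, 2, steps = 400, burn_in = 100, seed = 9)
  r2 <- admixture_mcmc(p, 2, steps = 400, burn_in = 100, seed = 9)
  expect_identical(r1$Q, r2$Q)
  expect_identical(r1$loglik, r2$loglik)
  expect_equal(unname(rowSums(r1$Q)), rep(1, 50), tolerance = 1e-9)
})

test_that("missing cells are tolerated by the sampler", {
  p <- simulate_panel(sim_config(n_individuals = 40, n_loci = 5,
                                 missing_rate = 0.2, seed = 53))
  run <- admixture_mcmc(p, 2, steps = 300, burn_in = 100, seed = 2)
  expect_false(any(is.na(run$Q)))
})

test_that("replicate alignment undoes a column permutation exactly", {
  Q <- matrix(c(.9, .1, .2, .8, .7, .3), 3, 2, byrow = TRUE)
  ens <- structure(list(runs = list(
    list(K = 2, replicate = 1, Q = Q, loglik = -10),
    list(K = 2, replicate = 2, Q = Q[, 2:1], loglik = -10)),
    k_values = 2, replicates = 2), class = "qmatrix_ensemble")
  out <- align_replicates(ens)
  expect_equal(out$runs[[2]]$Q, Q)
  # K = 1 is a no-op
  e1 <- structure(list(runs = list(list(K = 1, replicate = 1,
                                        Q = Q[, 1, drop = FALSE],
                                        loglik = -1))),
                  class = "qmatrix_ensemble")
  expect_equal(align_replicates(e1)$runs[[1]]$Q, Q[, 1, drop = FALSE])
})

test_that("the Evanno statistic is the normalized second difference", {
  # replicate-constant offsets cancel in the second difference, leaving
  # deltaK(2) = 48 and deltaK(3) = 1 with unit standard deviation
  L <- c(`1` = -100, `2` = -50, `3` = -48, `4` = -47)
  runs <- list()
  for (K in 1:4) for (r in 1:3) {
    off <- c(-1, 0, 1)[r]
    runs[[length(runs) + 1]] <- list(K = K, replicate = r,
                                     Q = matrix(1 / K, 4, K),
                                     loglik = L[[as.character(K)]] + off)
  }
  ens <- structure(list(runs = runs, k_values = 1:4, replicates = 3),
                   class = "qmatrix_ensemble")
  pan <- toy_panel(cbind(rep(c(100L, 104L), 2)), cbind(rep(100L, 4)),
                   sections = c("A", "A", "B", "B"))
  sel <- select_k(ens, pan)
  expect_equal(unname(sel$delta_k[["2"]]), 48)
  expect_equal(unname(sel$delta_k[["3"]]), 1)
  expect_true(is.na(sel$delta_k[["1"]]) && is.na(sel$delta_k[["4"]]))
  expect_equal(unname(sel$by_selector[["evanno"]]), 2)
  # invariance to adding a constant to every log-likelihood
  runs2 <- lapply(runs, function(x) { x$loglik <- x$loglik + 1000; x })
  ens2 <- structure(list(runs = runs2, k_values = 1:4, replicates = 3),
                    class = "qmatrix_ensemble")
  expect_equal(select_k(ens2, pan)$delta_k, sel$delta_k)
})

test_that("Puechmaille counts floor at one and ignore cluster labels", {
  # all memberships diffuse: no cluster passes the threshold in any group
  runs <- list(list(K = 3, replicate = 1, Q = matrix(1 / 3, 6, 3),
                    loglik = -5))
  ens <- structure(list(runs = runs, k_values = 3, replicates = 1),
                   class = "qmatrix_ensemble")
  pan <- toy_panel(cbind(rep(c(100L, 104L), 3)), cbind(rep(100L, 6)),
                   sections = rep(c("A", "B"), each = 3))
  sel <- select_k(ens, pan)
  expect_equal(sel$med_mean_k, 1L)
  expect_equal(sel$max_med_k, 1L)

  # relabeling clusters leaves the counts unchanged
  Q <- cbind(c(.9, .9, .9, .1, .1, .1), c(.1, .1, .1, .9, .9, .9))
  mk <- function(Q) structure(list(runs = list(list(K = 2, replicate = 1,
                                                    Q = Q, loglik = -5))),
                              class = "qmatrix_ensemble")
  s1 <- select_k(mk(Q), pan)
  s2 <- select_k(mk(Q[, 2:1]), pan)
  expect_equal(s1$med_mean_k, s2$med_mean_k)
  expect_equal(s1$med_mean_k, 2L)
})

test_that("two simulated stocks are recovered by the sampler", {
  p <- simulate_panel(sim_config(n_individuals = 300, n_loci = 14,
                                 stock_divergence_fst = 0.05, fis = 0,
                                 seed = 11))
  run <- admixture_mcmc(p, 2, steps = 2000, burn_in = 500, seed = 1)
  best <- max.col(run$Q)
  acc <- max(mean((best == 1) == (p$meta$stock == "Stock1")),
             mean((best == 2) == (p$meta$stock == "Stock1")))
  expect_gte(acc, 0.9)
  expect_gte(mean(apply(run$Q, 1, max) >= 0.8), 0.85)
})

test_that("aligned replicates of a clean signal agree individual by individual", {
  p <- simulate_panel(sim_config(n_individuals = 150, n_loci = 14,
                                 stock_divergence_fst = 0.05, fis = 0,
                                 seed = 55))
  ens <- admixture_ensemble(p, k_values = 2, replicates = 4, steps = 1200,
                            burn_in = 400, seed = 3)
  ens <- align_replicates(ens)
  Qs <- simplify2array(lapply(ens$runs, `[[`, "Q"))
  sds <- apply(Qs, c(1, 2), stats::sd)
  expect_lt(mean(sds), 0.05)
})

test_that("DAPC separates stocks and collapses under label permutation", {
  # fully diverged stocks: disjoint allele sets, with within-group
  # variation so the discriminant problem is well posed
  set.seed(44)
  n <- 60
  grp <- rep(c("g1", "g2"), each = n / 2)
  pool1 <- c(100L, 104L, 108L); pool2 <- c(140L, 144L, 148L)
  draw <- function(pool) sample(pool, n / 2, TRUE)
  a1 <- cbind(c(draw(pool1), draw(pool2)), c(draw(pool1), draw(pool2)))
  a2 <- cbind(c(draw(pool1), draw(pool2)), c(draw(pool1), draw(pool2)))
  p <- toy_panel(a1, a2, sections = grp)
  d <- dapc_lite(p, grp, n_pcs = 2)
  expect_equal(d$accuracy, 1.0)

  q <- simulate_panel(sim_config(n_individuals = 300, n_loci = 14,
                                 stock_divergence_fst = 0.05, fis = 0,
                                 seed = 56))
  d2 <- dapc_lite(q, "stock", n_pcs = 30)
  expect_gte(d2$accuracy, 0.8)
  # separated centroids on the first discriminant axis
  expect_gt(abs(diff(d2$centroids[, 1])),
            2 * stats::sd(d2$coords[, 1][d2$groups == levels(d2$groups)[1]]))

  set.seed(6)
  perm <- sample(q$meta$stock)
  d3 <- dapc_lite(q, perm, n_pcs = 30)
  n1 <- sum(perm == "Stock1")
  chance <- max(n1, 300 - n1) / 300
  expect_lt(d3$accuracy, chance + 1.96 * sqrt(0.25 / 300) + 0.03)
  expect_error(dapc_lite(q, "stock", n_pcs = 299), "overfitting")
})

test_that("season composition assigns by threshold with ties admixed", {
  pan <- toy_panel(cbind(rep(100L, 4)), cbind(rep(104L, 4)),
                   sections = rep("A", 4),
                   seasons = c("rainy", "rainy", "dry", "dry"),
                   years = rep(2020L, 4))
  Q <- rbind(c(1, 0), c(1, 0), c(0.5, 0.5), c(0.2, 0.8))
  sc <- season_composition(pan, Q)
  rainy <- sc[sc$season == "rainy", ]
  expect_equal(rainy$pct[rainy$stock == "Stock1"], 100)
  # the tied individual is admixed, so dry has a single assigned fish
  dry <- sc[sc$season == "dry", ]
  expect_equal(sum(dry$n), 1)
  expect_equal(dry$pct[dry$stock == "Stock2"], 100)
  expect_error(season_composition(toy_panel(cbind(100L), cbind(100L)), Q[1, , drop = FALSE]),
               "seasonal")
})
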