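#' Exact test for Hardy-Weinberg proportions
#'
#' Conditional exact test on the genotype count table given the allele
#' counts.  For small problems (<= 3 alleles and <= 30 individuals) the full
#' table space is enumerated; otherwise a Markov chain over tables with fixed
#' allele counts is run (random transpositions of allele copies between
#' genotype slots, which leaves the conditional Hardy-Weinberg distribution
#' invariant).  The p-value is the probability of tables no more probable
#' than the observed one; ties are resolved on the table probability.
#'
#' @inheritParams allele_frequencies
#' @param steps Markov chain length after dememorization
#' @param dememorization burn-in steps
#' @param seed optional integer seed
#' @param force_mcmc skip the enumeration branch (used for validation)
#' @return list (class `msat_test`) with `statistic` (observed table
#'   log-probability), `p_value`, `method` (`"enumeration"` or `"mcmc"`),
#'   `n_steps`
#' @export
hwe_exact <- function(panel, locus, population = NULL, grouping = "section",
                      steps = 100000, dememorization = 10000, seed = NULL,
                      force_mcmc = FALSE) {
  j <- locus_index(panel, locus)
  ii <- pop_rows(panel, population, grouping)
  a1 <- panel$a1[ii, j]; a2 <- panel$a2[ii, j]
  ok <- !is.na(a1)
  hwe_exact_counts(a1[ok], a2[ok], steps = steps,
                   dememorization = dememorization, seed = seed,
                   force_mcmc = force_mcmc)
}

#' @rdname hwe_exact
#' @param a1,a2 integer vectors of the two alleles per genotyped individual
#' @export
hwe_exact_counts <- function(a1, a2, steps = 100000, dememorization = 10000,
                             seed = NULL, force_mcmc = FALSE) {
  n <- length(a1)
  if (n == 0) stop("no genotypes")
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2)
    return(msat_test(statistic = 0, p_value = 1, method = "monomorphic",
                     n_steps = 0L))
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  f <- matrix(0L, k, k)       # lower-triangular genotype counts (row >= col)
  for (g in seq_len(n)) {
    r <- max(i1[g], i2[g]); c <- min(i1[g], i2[g])
    f[r, c] <- f[r, c] + 1L
  }
  if (!force_mcmc && k <= 3 && n <= 30) {
    p <- hwe_enumerate(f)
    return(msat_test(statistic = log_table_prob(f), p_value = p,
                     method = "enumeration", n_steps = 0L))
  }
  if (!is.null(seed)) set.seed(seed)
  p <- hwe_mcmc_cpp(i1 - 1L, i2 - 1L, k, as.integer(steps),
                    as.integer(dememorization))
  msat_test(statistic = log_table_prob(f), p_value = p, method = "mcmc",
            n_steps = as.integer(steps))
}

msat_test <- function(statistic, p_value, method, n_steps,
                      adjusted_significant = NA, ...) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n_steps = n_steps, adjusted_significant = adjusted_significant,
                 ...),
            class = "msat_test")
}

#' @export
print.msat_test <- function(x, ...) {
  cat("test:", x$method, " statistic =", format(x$statistic, digits = 4),
      " p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

# log P(table | allele counts) up to an additive constant:
# h*log(2) - sum(log(f_ij!))
log_table_prob <- function(f) {
  h <- sum(f[lower.tri(f)])
  h * log(2) - sum(lfactorial(f))
}

# Complete enumeration of genotype tables with the observed allele counts
# (k <= 3).  Heterozygote counts determine the diagonal.
hwe_enumerate <- function(f) {
  k <- nrow(f)
  m <- integer(k)                       # allele counts (f is lower-triangular)
  for (i in seq_len(k))
    m[i] <- 2L * f[i, i] + sum(f[i, -i]) + sum(f[-i, i])
  logp_obs <- log_table_prob(f)
  tol <- 1e-9 * (1 + abs(logp_obs))
  num <- 0; den <- 0
  consider <- function(het) {
    # het: vector of heterozygote counts in fixed (r,c) order
    g <- matrix(0L, k, k)
    idx <- 1L
    for (r in seq_len(k)) for (c in seq_len(r - 1)) {
      g[r, c] <- het[idx]; idx <- idx + 1L
    }
    dg <- m - (rowSums(g) + colSums(g))
    if (any(dg < 0) || any(dg %% 2 != 0)) return()
    diag(g) <- dg %/% 2L
    lp <- log_table_prob(g)
    w <- exp(lp - logp_obs)             # relative weight, stable
    den <<- den + w
    if (lp <= logp_obs + tol) num <<- num + w
  }
  hets <- vector("list", k * (k - 1) / 2)
  idx <- 1L
  for (r in seq_len(k)) for (c in seq_len(r - 1)) {
    hets[[idx]] <- 0:min(m[r], m[c]); idx <- idx + 1L
  }
  grid <- do.call(expand.grid, hets)
  for (rr in seq_len(nrow(grid))) consider(as.integer(grid[rr, ]))
  num / den
}

#' Genotypic linkage-disequilibrium test for a locus pair
#'
#' Log-likelihood-ratio G statistic on the two-locus genotype contingency
#' table; the null distribution is obtained by permuting one locus's
#' genotypes among individuals.
#'
#' @inheritParams allele_frequencies
#' @param locus1,locus2 the two loci
#' @param permutations number of permutations
#' @param seed optional integer seed
#' @param min_shared minimum number of individuals genotyped at both loci
#' @return `msat_test` with `statistic` = G, `p_value`
#'   `= (1 + #\{G_perm >= G_obs\}) / (1 + permutations)`
#' @export
genotypic_ld_test <- function(panel, locus1, locus2, population = NULL,
                              grouping = "section", permutations = 1000,
                              seed = NULL, min_shared = 10) {
  j1 <- locus_index(panel, locus1); j2 <- locus_index(panel, locus2)
  ii <- pop_rows(panel, population, grouping)
  g1 <- paste(panel$a1[ii, j1], panel$a2[ii, j1])
  g2 <- paste(panel$a1[ii, j2], panel$a2[ii, j2])
  ok <- !is.na(panel$a1[ii, j1]) & !is.na(panel$a1[ii, j2])
  if (sum(ok) < min_shared)
    return(msat_test(statistic = NA_real_, p_value = NA_real_,
                     method = "insufficient_data", n_steps = 0L))
  f1 <- factor(g1[ok]); f2 <- factor(g2[ok])
  if (nlevels(f1) < 2 || nlevels(f2) < 2)
    return(msat_test(statistic = 0, p_value = 1, method = "permutation",
                     n_steps = as.integer(permutations)))
  if (!is.null(seed)) set.seed(seed)
  g_obs <- g_statistic(table(f1, f2))
  n <- length(f1)
  exceed <- 0L
  for (b in seq_len(permutations))
    if (g_statistic(table(f1, f2[sample.int(n)])) >= g_obs - 1e-12)
      exceed <- exceed + 1L
  msat_test(statistic = g_obs,
            p_value = (1 + exceed) / (1 + permutations),
            method = "permutation", n_steps = as.integer(permutations))
}

g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  keep <- tab > 0
  2 * sum(tab[keep] * log(tab[keep] / e[keep]))
}

#' Sequential Bonferroni (Holm) correction
#'
#' Holm's step-down procedure: order the m p-values ascending, compare the
#' i-th to `alpha / (m - i + 1)`, and stop at the first failure.
#'
#' @param p_values numeric vector of p-values in \[0,1\]
#' @param alpha family-wise error rate
#' @return logical vector of significance flags, in input order
#' @export
sequential_bonferroni <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  ord <- order(p_values)
  sig <- logical(m)
  for (i in seq_len(m)) {
    pv <- p_values[ord[i]]
    if (is.na(pv) || pv > alpha / (m - i + 1)) break
    sig[ord[i]] <- TRUE
  }
  sig
}

#' Fisher's method for combining independent p-values
#'
#' `X^2 = -2 sum(log p)` referred to a chi-square with `2m` degrees of
#' freedom.  Zero p-values are clamped to the smallest positive double and
#' flagged.
#'
#' @param p_values numeric vector of p-values in (0, 1]
#' @return `msat_test` with `statistic` = X^2, `p_value`, `clamped` flag
#' @export
combine_p_fisher <- function(p_values) {
  if (length(p_values) == 0)
    return(msat_test(statistic = NA_real_, p_value = NA_real_,
                     method = "fisher", n_steps = 0L, clamped = FALSE))
  clamped <- any(p_values <= 0)
  p <- pmax(p_values, .Machine$double.xmin)
  x2 <- -2 * sum(log(p))
  msat_test(statistic = x2,
            p_value = stats::pchisq(x2, df = 2 * length(p),
                                    lower.tail = FALSE),
            method = "fisher", n_steps = 0L, clamped = clamped)
}
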