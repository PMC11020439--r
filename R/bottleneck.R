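#' Mutation model specification
#'
#' @param kind `"IAM"`, `"SMM"` or `"TPM"`
#' @param p_single_step probability that a TPM mutation is a single repeat
#'   step (BOTTLENECK-style convention; default 0.7)
#' @param multistep_variance variance of the multi-step jump size in repeat
#'   units (default 30); the jump magnitude is geometric, sign symmetric
#' @return list of class `mutation_model`
#' @export
mutation_model <- function(kind = c("IAM", "SMM", "TPM"),
                           p_single_step = 0.7, multistep_variance = 30) {
  kind <- match.arg(kind)
  if (p_single_step < 0 || p_single_step > 1)
    stop("p_single_step must lie in [0, 1]")
  if (multistep_variance <= 0) stop("multistep_variance must be positive")
  structure(list(kind = kind, p_single_step = p_single_step,
                 multistep_variance = multistep_variance),
            class = "mutation_model")
}

# geometric success probability giving the requested jump-size variance:
# for size ~ Geometric on {1,2,...}, var = (1-q)/q^2
geom_q_for_variance <- function(v) {
  (-1 + sqrt(1 + 4 * v)) / (2 * v)
}

expected_k_iam <- function(n_genes, theta) {
  sum(theta / (theta + 0:(n_genes - 1)))
}

# Match theta to the observed allele count by bisection on the expected
# allele number (closed form under IAM, Monte-Carlo under SMM/TPM).
solve_theta <- function(n_genes, k_obs, model, mc_rep = 300) {
  target <- k_obs
  ek <- function(theta) {
    if (model$kind == "IAM") expected_k_iam(n_genes, theta)
    else expected_k_smm_cpp(n_genes, theta, mc_rep,
                            if (model$kind == "SMM") 1 else model$p_single_step,
                            geom_q_for_variance(model$multistep_variance))
  }
  lo <- 1e-4; hi <- 1e4
  if (ek(hi) < target) return(hi)
  for (it in 1:24) {
    mid <- sqrt(lo * hi)
    if (ek(mid) < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Simulate equilibrium heterozygosity conditional on the allele number
#'
#' Draws allele configurations of `n_genes` genes at mutation-drift
#' equilibrium under the chosen mutation model, keeping only replicates whose
#' realized allele number equals `k_obs` (theta is first matched to `k_obs`
#' by bisection on the expected allele count).  Each accepted replicate
#' yields the unbiased sample heterozygosity; the resulting distribution is
#' the null reference for the heterozygosity-excess bottleneck test.
#'
#' @param n_genes number of gene copies (2 x genotyped individuals)
#' @param k_obs observed allele count (1..n_genes)
#' @param model a [mutation_model()]
#' @param n_sim number of accepted replicates
#' @param seed optional integer seed
#' @param min_acceptance abort if the acceptance rate drops below this
#' @return numeric vector of `n_sim` equilibrium heterozygosities
#' @export
simulate_heq <- function(n_genes, k_obs, model = mutation_model("IAM"),
                         n_sim = 1000, seed = NULL, min_acceptance = 1e-4) {
  if (k_obs < 1 || k_obs > n_genes)
    stop("k_obs must lie in 1..n_genes")
  if (k_obs == 1) return(rep(0, n_sim))
  if (k_obs == n_genes) return(rep(1, n_sim))  # all singletons, unbiased He = 1
  if (!is.null(seed)) set.seed(seed)
  theta <- solve_theta(n_genes, k_obs, model)
  max_tries <- n_sim / min_acceptance
  if (model$kind == "IAM")
    heq_iam_cpp(n_genes, k_obs, theta, n_sim, max_tries)
  else
    heq_smm_cpp(n_genes, k_obs, theta, n_sim,
                if (model$kind == "SMM") 1 else model$p_single_step,
                geom_q_for_variance(model$multistep_variance), max_tries)
}

#' Heterozygosity-excess bottleneck test
#'
#' For each polymorphic locus, the observed unbiased heterozygosity is
#' standardized against the simulated equilibrium distribution for the same
#' sample size and allele number: `DH = (He_obs - mean Heq) / sd Heq`.  A
#' one-tailed Wilcoxon signed-rank test of median DH > 0 (heterozygosity
#' excess, the signature of a recent bottleneck) gives the population
#' p-value; the exact signed-rank null is used up to 25 loci, the normal
#' approximation beyond.
#'
#' @inheritParams allele_frequencies
#' @param model a [mutation_model()]
#' @param n_sim coalescent replicates per locus
#' @param seed optional integer seed
#' @return list (class `bottleneck_report`) with `population`, `model`,
#'   `p_value`, `per_locus` data frame (locus, he_obs, heq_mean, heq_sd, dh),
#'   `n_sim`, `degenerate`
#' @export
heterozygosity_excess_test <- function(panel, population = NULL,
                                       grouping = "section",
                                       model = mutation_model("IAM"),
                                       n_sim = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ii <- pop_rows(panel, population, grouping)
  rows <- list()
  for (j in seq_len(ncol(panel$a1))) {
    a1 <- panel$a1[ii, j]; a2 <- panel$a2[ii, j]
    ok <- !is.na(a1)
    n <- sum(ok)
    if (n < 2) next
    x <- c(a1[ok], a2[ok])
    k <- length(unique(x))
    if (k < 2) next                      # monomorphic loci carry no signal
    p <- as.numeric(table(x)) / (2 * n)
    he <- 2 * n / (2 * n - 1) * (1 - sum(p^2))
    heq <- simulate_heq(2 * n, k, model, n_sim)
    m <- mean(heq); s <- stats::sd(heq)
    rows[[length(rows) + 1L]] <-
      data.frame(locus = panel$loci$name[j], he_obs = he, heq_mean = m,
                 heq_sd = s, dh = if (s > 0) (he - m) / s else 0)
  }
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) < 4)
    stop("heterozygosity-excess test needs >= 4 polymorphic loci")
  res <- wilcoxon_signed_rank_greater(per$dh)
  structure(list(population = if (is.null(population)) "all" else population,
                 model = model$kind, p_value = res$p, method = res$method,
                 per_locus = per, n_sim = n_sim,
                 degenerate = res$degenerate),
            class = "bottleneck_report")
}

# One-tailed (median > 0) Wilcoxon signed-rank p-value; exact null via
# psignrank for <= 25 values without ties, normal approximation otherwise.
wilcoxon_signed_rank_greater <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(list(p = 1, method = "degenerate", degenerate = TRUE))
  r <- rank(abs(x))
  v <- sum(r[x > 0])
  if (n <= 25 && !any(duplicated(abs(x)))) {
    p <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    list(p = p, method = "exact", degenerate = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5) / sqrt(sig2)
    list(p = stats::pnorm(z, lower.tail = FALSE), method = "normal",
         degenerate = FALSE)
  }
}

#' Garza-Williamson M-ratio
#'
#' Modified index `M = k / (r + 1)` where `k` is the allele count and `r` the
#' allele size range in repeat units (`(max - min) / motif_length`, rounded;
#' floor division with a note when the range is off-ladder).  Values below
#' 0.68 conventionally indicate a recent, severe reduction in population
#' size.
#'
#' @inheritParams allele_frequencies
#' @return list with `m`, `k`, `r`, `off_ladder`
#' @export
m_ratio <- function(panel, locus, population = NULL, grouping = "section") {
  j <- locus_index(panel, locus)
  ii <- pop_rows(panel, population, grouping)
  x <- c(panel$a1[ii, j], panel$a2[ii, j])
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no data at locus ", panel$loci$name[j])
  k <- length(unique(x))
  motif <- panel$loci$motif_length[j]
  rng <- max(x) - min(x)
  off <- rng %% motif != 0
  r <- if (off) rng %/% motif else as.integer(round(rng / motif))
  list(m = k / (r + 1), k = k, r = r, off_ladder = off)
}

#' @rdname m_ratio
#' @param threshold critical value flagged in the summary (default 0.68)
#' @return `m_ratio_mean`: list with `m_mean`, `below_threshold`, `per_locus`
#' @export
m_ratio_mean <- function(panel, population = NULL, grouping = "section",
                         threshold = 0.68) {
  per <- vapply(seq_len(ncol(panel$a1)), function(j)
    m_ratio(panel, j, population, grouping)$m, 1)
  list(m_mean = mean(per), below_threshold = mean(per) < threshold,
       per_locus = data.frame(locus = panel$loci$name, m = per))
}

#' Full bottleneck report for one population
#'
#' Runs the heterozygosity-excess test under IAM, SMM and TPM and the mean
#' M-ratio, mirroring the usual per-population bottleneck summary table.
#'
#' @inheritParams heterozygosity_excess_test
#' @param tpm a `"TPM"` [mutation_model()] carrying the two-phase parameters
#' @return list with `population`, `p_iam`, `p_smm`, `p_tpm`, `m_ratio`,
#'   `per_locus` (per-model DH tables), `n_sim`
#' @export
bottleneck_report <- function(panel, population = NULL, grouping = "section",
                              n_sim = 1000, seed = NULL,
                              tpm = mutation_model("TPM")) {
  if (!is.null(seed)) set.seed(seed)
  iam <- heterozygosity_excess_test(panel, population, grouping,
                                    mutation_model("IAM"), n_sim)
  smm <- heterozygosity_excess_test(panel, population, grouping,
                                    mutation_model("SMM"), n_sim)
  tp <- heterozygosity_excess_test(panel, population, grouping, tpm, n_sim)
  mr <- m_ratio_mean(panel, population, grouping)
  list(population = if (is.null(population)) "all" else population,
       p_iam = iam$p_value, p_smm = smm$p_value, p_tpm = tp$p_value,
       m_ratio = mr$m_mean, m_below_068 = mr$below_threshold,
       per_locus = list(IAM = iam$per_locus, SMM = smm$per_locus,
                        TPM = tp$per_locus),
       n_sim = n_sim)
}
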