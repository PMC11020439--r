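#' Admixture-model Bayesian clustering (one run)
#'
#' Gibbs sampler for the admixture model with independent allele-frequency
#' priors: iterates cluster allele-frequency draws (Dirichlet posterior),
#' per-allele-copy cluster assignments, and per-individual membership draws
#' `q_i ~ Dirichlet(alpha + assignment counts)` with fixed `alpha`.  Missing
#' cells simply contribute nothing.  Returns the posterior-mean Q and mean
#' post-burn-in data log-likelihood; a large split-half log-likelihood
#' difference flags (but does not fail) non-convergence.
#'
#' @param panel a [genotype_panel()]
#' @param K number of clusters (>= 1)
#' @param steps total Gibbs sweeps
#' @param burn_in sweeps discarded (must be < steps)
#' @param seed optional integer seed
#' @param alpha initial Dirichlet parameter of the membership prior
#' @param sample_alpha update alpha by Metropolis steps under a uniform
#'   prior on (0, `alpha_max`), as the reference implementation of this
#'   model does (default); `FALSE` keeps alpha fixed
#' @param alpha_max upper bound of the alpha prior
#' @param lambda Dirichlet parameter of the allele-frequency prior
#' @param convergence_threshold flag the run when the absolute difference of
#'   first/second-half mean log-likelihood exceeds this
#' @return list (class `admixture_run`) with `K`, `Q` (individuals x K, rows
#'   sum to 1), `loglik`, `converged`, `steps`, `burn_in`, `seed`, `alpha`
#'   (final value)
#' @export
admixture_mcmc <- function(panel, K, steps = 50000, burn_in = 10000,
                           seed = NULL, alpha = 1.0, sample_alpha = TRUE,
                           alpha_max = 10, lambda = 1.0,
                           convergence_threshold = NULL) {
  if (K < 1) stop("K must be >= 1")
  if (steps <= burn_in) stop("steps must exceed burn_in")
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_panel(panel)
  res <- admixture_gibbs_cpp(enc$geno, enc$n_alleles, as.integer(K),
                             as.integer(steps), as.integer(burn_in),
                             alpha, lambda, sample_alpha, alpha_max)
  Q <- res$Q / rowSums(res$Q)
  rownames(Q) <- panel$meta$id
  if (is.null(convergence_threshold))
    convergence_threshold <- 0.002 * abs(res$loglik) + 1
  converged <- is.na(res$loglik_half1) ||
    abs(res$loglik_half1 - res$loglik_half2) <= convergence_threshold
  structure(list(K = K, Q = Q, loglik = res$loglik, converged = converged,
                 steps = steps, burn_in = burn_in, seed = seed,
                 alpha = res$alpha),
            class = "admixture_run")
}

# allele-index encoding of a panel for the C++ sampler
encode_panel <- function(panel) {
  n <- nrow(panel$a1); L <- ncol(panel$a1)
  geno <- matrix(NA_integer_, n, 2 * L)
  n_alleles <- integer(L)
  for (j in seq_len(L)) {
    reg <- panel$registers[[j]]
    n_alleles[j] <- length(reg)
    geno[, 2 * j - 1] <- match(panel$a1[, j], reg) - 1L
    geno[, 2 * j] <- match(panel$a2[, j], reg) - 1L
  }
  list(geno = geno, n_alleles = n_alleles)
}

#' Run the admixture sampler over a K grid with replicates
#'
#' @inheritParams admixture_mcmc
#' @param k_values integer vector of K values
#' @param replicates runs per K
#' @param seed integer seed; replicate seeds are derived from it
#' @return list of class `qmatrix_ensemble`: `runs` (list of
#'   `admixture_run`), `k_values`, `replicates`
#' @export
admixture_ensemble <- function(panel, k_values = 1:8, replicates = 20,
                               steps = 50000, burn_in = 10000, seed = 1,
                               alpha = 1.0, sample_alpha = TRUE,
                               lambda = 1.0) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             length(k_values) * replicates),
                  nrow = length(k_values))
  runs <- list()
  for (a in seq_along(k_values)) for (r in seq_len(replicates)) {
    run <- admixture_mcmc(panel, k_values[a], steps, burn_in,
                          seed = seeds[a, r], alpha = alpha,
                          sample_alpha = sample_alpha, lambda = lambda)
    run$replicate <- r
    runs[[length(runs) + 1L]] <- run
  }
  structure(list(runs = runs, k_values = k_values, replicates = replicates),
            class = "qmatrix_ensemble")
}

#' Align replicate cluster labels within each K
#'
#' Greedy matching of each replicate's Q columns to the first replicate at
#' the same K, by maximal column correlation (label switching removal).
#'
#' @param ensemble a `qmatrix_ensemble`
#' @return the ensemble with permuted Q columns
#' @export
align_replicates <- function(ensemble) {
  for (K in unique(vapply(ensemble$runs, `[[`, 1, "K"))) {
    idx <- which(vapply(ensemble$runs, `[[`, 1, "K") == K)
    if (length(idx) < 2 || K < 2) next
    ref <- ensemble$runs[[idx[1]]]$Q
    for (w in idx[-1]) {
      Q <- ensemble$runs[[w]]$Q
      perm <- greedy_column_match(ref, Q)
      ensemble$runs[[w]]$Q <- Q[, perm, drop = FALSE]
    }
  }
  ensemble
}

greedy_column_match <- function(ref, Q) {
  K <- ncol(ref)
  if (K == 1) return(1L)
  score <- matrix(-Inf, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    s <- suppressWarnings(stats::cor(ref[, i], Q[, j]))
    score[i, j] <- if (is.na(s)) 0 else s
  }
  perm <- integer(K)
  used <- logical(K)
  for (step in seq_len(K)) {
    best <- which(score == max(score), arr.ind = TRUE)[1, ]
    perm[best[1]] <- best[2]
    score[best[1], ] <- -Inf
    score[, best[2]] <- -Inf
    used[best[2]] <- TRUE
  }
  perm
}

#' Select the number of genetic stocks
#'
#' Computes the Evanno second-order statistic
#' `deltaK(K) = mean_r |L_r(K+1) - 2 L_r(K) + L_r(K-1)| / sd_r L_r(K)`
#' (replicates paired by id; defined for interior K only) and the four
#' Puechmaille-style estimators: per replicate at the largest K, a cluster
#' counts as real when its mean (or median) membership within at least one
#' predefined group exceeds `threshold`; MEDMEANK/MAXMEANK take the
#' median/max over replicates of the mean-based count, MEDMEDK/MAXMEDK of
#' the median-based count (floored at 1).  `chosen_k` is the modal value
#' over the five selectors, smaller K on ties.
#'
#' @param ensemble a `qmatrix_ensemble`
#' @param panel the panel the ensemble was fit to (for the predefined
#'   groups)
#' @param grouping predefined-group variable (default river sections)
#' @param threshold membership threshold
#' @return list of class `k_selection` with `delta_k`, `med_mean_k`,
#'   `max_mean_k`, `med_med_k`, `max_med_k`, `chosen_k`, `by_selector`
#' @export
select_k <- function(ensemble, panel, grouping = "section", threshold = 0.5) {
  ks <- vapply(ensemble$runs, `[[`, 1, "K")
  reps <- vapply(ensemble$runs, function(r)
    as.integer(if (is.null(r$replicate)) 1L else r$replicate), 1L)
  ll <- vapply(ensemble$runs, `[[`, 1, "loglik")
  kv <- sort(unique(ks))
  Lmat <- matrix(NA_real_, length(kv), max(reps),
                 dimnames = list(kv, NULL))
  for (i in seq_along(ks)) Lmat[as.character(ks[i]), reps[i]] <- ll[i]

  delta_k <- rep(NA_real_, length(kv)); names(delta_k) <- kv
  for (a in seq_along(kv)) {
    if (a == 1 || a == length(kv)) next
    if (kv[a + 1] - kv[a] != 1 || kv[a] - kv[a - 1] != 1) next
    sdl <- stats::sd(Lmat[a, ], na.rm = TRUE)
    if (is.na(sdl) || sdl == 0) next   # division guard: deltaK undefined
    second <- abs(Lmat[a + 1, ] - 2 * Lmat[a, ] + Lmat[a - 1, ])
    delta_k[a] <- mean(second, na.rm = TRUE) / sdl
  }
  k_evanno <- if (all(is.na(delta_k))) NA_integer_
              else kv[which.max(delta_k)]

  g <- panel_grouping(panel, grouping)
  groups <- unique(g[!is.na(g)])
  kmax <- max(kv)
  top <- which(ks == kmax)
  mean_counts <- med_counts <- integer(length(top))
  for (w in seq_along(top)) {
    Q <- ensemble$runs[[top[w]]]$Q
    mean_hit <- med_hit <- logical(ncol(Q))
    for (k in seq_len(ncol(Q))) for (gr in groups) {
      qk <- Q[g == gr, k]
      if (mean(qk) > threshold) mean_hit[k] <- TRUE
      if (stats::median(qk) > threshold) med_hit[k] <- TRUE
    }
    mean_counts[w] <- max(sum(mean_hit), 1L)
    med_counts[w] <- max(sum(med_hit), 1L)
  }
  sel <- c(evanno = k_evanno,
           med_mean_k = as.integer(stats::median(mean_counts)),
           max_mean_k = max(mean_counts),
           med_med_k = as.integer(stats::median(med_counts)),
           max_med_k = max(med_counts))
  votes <- table(sel[!is.na(sel)])
  chosen <- as.integer(names(votes)[votes == max(votes)])
  structure(list(delta_k = delta_k, med_mean_k = sel[["med_mean_k"]],
                 max_mean_k = sel[["max_mean_k"]],
                 med_med_k = sel[["med_med_k"]],
                 max_med_k = sel[["max_med_k"]],
                 chosen_k = min(chosen), by_selector = sel,
                 membership_threshold = threshold),
            class = "k_selection")
}

#' Discriminant analysis of principal components (compact form)
#'
#' Genotypes are one-hot allele-count encoded (individuals x alleles,
#' counting 0/1/2 copies; missing cells contribute the population mean after
#' centering), reduced by PCA to `n_pcs` components, then classified by
#' linear discriminant analysis.  `n_pcs = "cv"` picks the number of
#' retained components by grouped cross-validation; assignment accuracy is
#' leave-one-out.
#'
#' @param panel a [genotype_panel()]
#' @param group_labels vector of group labels (length = individuals) or a
#'   grouping name for [panel_grouping()]
#' @param n_pcs number of principal components, or `"cv"`
#' @param cv_folds folds for the `"cv"` choice
#' @param seed optional integer seed (fold assignment)
#' @return list of class `dapc_lite` with `coords` (discriminant
#'   coordinates), `centroids`, `accuracy` (leave-one-out), `n_pcs`,
#'   `assignments`
#' @export
dapc_lite <- function(panel, group_labels = "stock", n_pcs = 20,
                      cv_folds = 5, seed = NULL) {
  g <- factor(panel_grouping(panel, group_labels))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  X <- one_hot_alleles(panel)
  X <- scale(X, center = TRUE, scale = FALSE)
  X[is.na(X)] <- 0                       # missing -> column mean
  pc <- stats::prcomp(X, center = FALSE)
  maxpc <- min(nrow(X) - nlevels(g) - 1, sum(pc$sdev > 1e-8))
  if (identical(n_pcs, "cv")) {
    if (!is.null(seed)) set.seed(seed)
    grid <- unique(pmin(c(5, 10, 20, 40, 80), maxpc))
    fold <- sample(rep_len(seq_len(cv_folds), nrow(X)))
    acc <- vapply(grid, function(np) {
      hits <- 0
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        if (length(unique(g[tr])) < 2) return(0)
        fit <- MASS::lda(pc$x[tr, seq_len(np), drop = FALSE], g[tr])
        pr <- stats::predict(fit, pc$x[!tr, seq_len(np), drop = FALSE])$class
        hits <- hits + sum(pr == g[!tr])
      }
      hits / nrow(X)
    }, 1)
    n_pcs <- grid[which.max(acc)]
  }
  if (n_pcs >= nrow(X) - nlevels(g))
    stop("n_pcs too large: overfitting guard requires n_pcs < N - groups")
  n_pcs <- min(n_pcs, maxpc)
  Z <- pc$x[, seq_len(n_pcs), drop = FALSE]
  fit <- MASS::lda(Z, g)
  loo <- MASS::lda(Z, g, CV = TRUE)
  coords <- Z %*% fit$scaling
  centroids <- apply(coords, 2, function(cl) tapply(cl, g, mean))
  list(coords = coords,
       centroids = matrix(centroids, nrow = nlevels(g),
                          dimnames = list(levels(g), colnames(coords))),
       accuracy = mean(loo$class == g, na.rm = TRUE),
       n_pcs = n_pcs, assignments = loo$class, groups = g)
}

one_hot_alleles <- function(panel) {
  cols <- list()
  for (j in seq_len(ncol(panel$a1))) {
    reg <- panel$registers[[j]]
    m <- matrix(0, nrow(panel$a1), length(reg))
    for (a in seq_along(reg))
      m[, a] <- (panel$a1[, j] == reg[a]) + (panel$a2[, j] == reg[a])
    m[is.na(panel$a1[, j]), ] <- NA
    colnames(m) <- paste0(panel$loci$name[j], ".", reg)
    cols[[j]] <- m
  }
  do.call(cbind, cols)
}

#' Stock composition by season and year
#'
#' Each individual is assigned to its largest-membership cluster when that
#' membership reaches `q_threshold` (ties count as admixed), otherwise
#' labelled `"admixed"`; percentages are tabulated per (season, year) over
#' assigned individuals.
#'
#' @param panel a [genotype_panel()] with season/year metadata
#' @param Q membership matrix (individuals x clusters); column names (or
#'   `Stock1..K`) become the stock labels.  Alternatively `NULL` to use
#'   `panel$meta$stock` directly.
#' @param q_threshold assignment threshold
#' @return data frame (class `season_composition`) with season, year, stock,
#'   n and pct (percentages sum to 100 within season x year)
#' @export
season_composition <- function(panel, Q = NULL, q_threshold = 0.5) {
  if (all(is.na(panel$meta$season)) ||
      all(panel$meta$season == "unknown"))
    stop("panel has no seasonal metadata")
  if (is.null(Q)) {
    lab <- as.character(panel$meta$stock)
    if (all(is.na(lab))) stop("neither Q nor stock labels available")
  } else {
    if (is.null(colnames(Q)))
      colnames(Q) <- paste0("Stock", seq_len(ncol(Q)))
    best <- max.col(Q, ties.method = "first")
    qmax <- Q[cbind(seq_len(nrow(Q)), best)]
    tie <- rowSums(abs(Q - qmax) < 1e-12) > 1
    lab <- ifelse(qmax >= q_threshold & !tie, colnames(Q)[best], "admixed")
  }
  keep <- lab != "admixed" & !is.na(lab)
  df <- data.frame(season = panel$meta$season[keep],
                   year = panel$meta$year[keep], stock = lab[keep])
  agg <- as.data.frame(table(df$season, df$year, df$stock),
                       stringsAsFactors = FALSE)
  names(agg) <- c("season", "year", "stock", "n")
  agg <- agg[order(agg$season, agg$year, agg$stock), ]
  cell <- stats::ave(agg$n, agg$season, agg$year, FUN = sum)
  agg$pct <- ifelse(cell > 0, 100 * agg$n / cell, NA_real_)
  agg <- agg[cell > 0, ]
  class(agg) <- c("season_composition", "data.frame")
  agg
}
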