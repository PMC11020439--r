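#' Weir-Cockerham theta (FST)
#'
#' Variance-component estimator of FST: per allele per locus, components
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals) are computed from sample sizes, allele
#' frequencies and heterozygote frequencies; the multilocus estimate is
#' `theta = sum(a) / sum(a + b + c)`.
#'
#' @inheritParams allele_frequencies
#' @param populations optional subset of population labels (default: all)
#' @return list with `theta`, `components` (per-locus data frame of summed
#'   a, b, c), `populations`
#' @export
fst_weir_cockerham <- function(panel, populations = NULL,
                               grouping = "section") {
  g <- panel_grouping(panel, grouping)
  if (is.null(populations)) populations <- unique(g[!is.na(g)])
  if (length(populations) < 2) stop("need >= 2 populations")
  rows <- lapply(seq_len(ncol(panel$a1)), function(j) {
    comp <- wc_components_locus(panel$a1[, j], panel$a2[, j], g, populations)
    data.frame(locus = panel$loci$name[j], a = comp["a"], b = comp["b"],
               c = comp["c"], row.names = NULL)
  })
  comp <- do.call(rbind, rows)
  tot <- colSums(comp[c("a", "b", "c")], na.rm = TRUE)
  theta <- if (sum(tot) > 0) tot[["a"]] / sum(tot) else NA_real_
  list(theta = theta, components = comp, populations = populations)
}

# Weir & Cockerham variance components for one locus, summed over alleles.
wc_components_locus <- function(a1, a2, g, populations) {
  keep <- list()
  for (p in populations) {
    ii <- which(g == p & !is.na(a1))
    if (length(ii) >= 2) keep[[p]] <- ii
  }
  r <- length(keep)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  ns <- vapply(keep, length, 1L)
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(c(a1[unlist(keep)], a2[unlist(keep)])))
  A <- B <- C <- 0
  for (al in alleles) {
    p_i <- h_i <- numeric(r)
    for (q in seq_len(r)) {
      ii <- keep[[q]]
      x1 <- a1[ii]; x2 <- a2[ii]
      p_i[q] <- (sum(x1 == al) + sum(x2 == al)) / (2 * ns[q])
      h_i[q] <- mean((x1 == al) != (x2 == al))
    }
    pbar <- sum(ns * p_i) / (r * nbar)
    s2 <- sum(ns * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

#' Standardized FST (F'ST)
#'
#' `F'ST = FST / FST_max`, where `FST_max` is obtained by recoding: each
#' population's alleles are relabeled so that no allele is shared between
#' populations while the genotype (homozygote/heterozygote) structure is
#' kept, and theta recomputed.  Significance by permuting individuals among
#' populations.
#'
#' @inheritParams fst_weir_cockerham
#' @param permutations number of label permutations for the p-value (0 to
#'   skip)
#' @param seed optional integer seed
#' @return list with `fst_std`, `fst`, `fst_max`, `p_value`
#' @export
fst_standardized <- function(panel, populations = NULL, grouping = "section",
                             permutations = 999, seed = NULL) {
  g <- panel_grouping(panel, grouping)
  if (is.null(populations)) populations <- unique(g[!is.na(g)])
  obs <- fst_std_once(panel, g, populations)
  p <- NA_real_
  if (permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    inpop <- which(g %in% populations)
    exceed <- 0L
    for (b in seq_len(permutations)) {
      gp <- g
      gp[inpop] <- g[sample(inpop)]
      if (fst_std_once(panel, gp, populations)$fst_std >= obs$fst_std - 1e-12)
        exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + permutations)
  }
  c(obs, list(p_value = p))
}

fst_std_once <- function(panel, g, populations) {
  fst <- fst_wc_labels(panel$a1, panel$a2, g, populations)
  # private-allele recoding: offset each population's allele labels
  off <- stats::setNames(seq_along(populations) * 10000000L, populations)
  a1 <- panel$a1; a2 <- panel$a2
  for (p in populations) {
    ii <- which(g == p)
    a1[ii, ] <- a1[ii, , drop = FALSE] + off[[p]]
    a2[ii, ] <- a2[ii, , drop = FALSE] + off[[p]]
  }
  fst_max <- fst_wc_labels(a1, a2, g, populations)
  list(fst_std = if (isTRUE(fst_max > 0)) fst / fst_max else NA_real_,
       fst = fst, fst_max = fst_max)
}

fst_wc_labels <- function(a1, a2, g, populations) {
  comp <- rowSums(vapply(seq_len(ncol(a1)), function(j)
    wc_components_locus(a1[, j], a2[, j], g, populations), numeric(3)),
    na.rm = TRUE)
  if (sum(comp) > 0) comp[["a"]] / sum(comp) else NA_real_
}

#' Jost's D (allelic differentiation)
#'
#' Per locus, `D = (k/(k-1)) (Ht' - Hs') / (1 - Hs')` with the
#' sample-size-corrected estimators `Hs' = (2n~/(2n~-1)) Hs` and
#' `Ht' = Ht + Hs'/(2 n~ k)`, `n~` the harmonic mean of the population
#' sample sizes.  The multilocus value is the harmonic mean of the positive
#' per-locus values (zero when every locus shows none).
#'
#' @inheritParams fst_weir_cockerham
#' @return list with `d` (multilocus), `per_locus` data frame
#' @export
jost_dest <- function(panel, populations = NULL, grouping = "section") {
  g <- panel_grouping(panel, grouping)
  if (is.null(populations)) populations <- unique(g[!is.na(g)])
  if (length(populations) < 2) stop("need >= 2 populations")
  per <- vapply(seq_len(ncol(panel$a1)), function(j)
    jost_d_locus(panel$a1[, j], panel$a2[, j], g, populations), 1)
  d <- per[!is.na(per)]
  dm <- if (length(d) == 0) NA_real_
        else if (all(d <= 0)) 0
        else { dp <- pmax(d, .Machine$double.eps); 1 / mean(1 / dp) }
  list(d = dm,
       per_locus = data.frame(locus = panel$loci$name, d = per))
}

jost_d_locus <- function(a1, a2, g, populations) {
  freqs <- list(); ns <- c()
  for (p in populations) {
    ii <- which(g == p & !is.na(a1))
    if (length(ii) == 0) next
    x <- c(a1[ii], a2[ii])
    freqs[[p]] <- table(factor(x)) / length(x)
    ns <- c(ns, length(ii))
  }
  k <- length(freqs)
  if (k < 2) return(NA_real_)
  alleles <- sort(unique(unlist(lapply(freqs, names))))
  P <- vapply(freqs, function(f) {
    v <- stats::setNames(rep(0, length(alleles)), alleles)
    v[names(f)] <- as.numeric(f)
    v
  }, numeric(length(alleles)))
  P <- matrix(P, nrow = length(alleles))
  hs <- mean(1 - colSums(P^2))
  pbar <- rowMeans(P)
  ht <- 1 - sum(pbar^2)
  ntil <- length(ns) / sum(1 / ns)
  hs_p <- 2 * ntil / (2 * ntil - 1) * hs
  ht_p <- ht + hs_p / (2 * ntil * k)
  if (hs_p >= 1) return(NA_real_)
  (k / (k - 1)) * (ht_p - hs_p) / (1 - hs_p)
}

#' Pairwise differentiation matrices
#'
#' Computes F'ST (below diagonal) and Jost's D (above diagonal) for every
#' population pair, with optional permutation p-values for F'ST.
#'
#' @inheritParams fst_standardized
#' @return list with `labels`, `fst_std` and `dest` symmetric matrices,
#'   `p_values` (for F'ST), `combined` matrix with D above / F'ST below the
#'   diagonal
#' @export
pairwise_differentiation <- function(panel, populations = NULL,
                                     grouping = "section",
                                     permutations = 0, seed = NULL) {
  g <- panel_grouping(panel, grouping)
  if (is.null(populations)) populations <- sort(unique(g[!is.na(g)]))
  np <- length(populations)
  fmat <- dmat <- pmat <- matrix(0, np, np,
                                 dimnames = list(populations, populations))
  diag(pmat) <- NA_real_
  for (i in seq_len(np)) for (j in seq_len(i - 1)) {
    pp <- populations[c(i, j)]
    fs <- fst_standardized(panel, pp, grouping, permutations, seed)
    dd <- jost_dest(panel, pp, grouping)
    fmat[i, j] <- fmat[j, i] <- fs$fst_std
    dmat[i, j] <- dmat[j, i] <- dd$d
    pmat[i, j] <- pmat[j, i] <- fs$p_value
  }
  comb <- fmat
  comb[upper.tri(comb)] <- dmat[upper.tri(dmat)]
  list(labels = populations, fst_std = fmat, dest = dmat,
       p_values = pmat, combined = comb)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Allele-level AMOVA: each individual contributes two gene copies; sums of
#' squares derive from allele-identity distances, and the among/within
#' variance components come from the standard moment equations per locus and
#' are summed across loci.  `Phi_ST = sigma2_among / sigma2_total`;
#' significance by permuting individuals among groups.  The degrees of
#' freedom are printed as (g - 1, 2N - 1) (among, total).
#'
#' @inheritParams allele_frequencies
#' @param permutations number of permutations for the p-value
#' @param seed optional integer seed
#' @return list (class `amova_table`) with `df_among`, `df_within`,
#'   `df_total`, `ss_among`, `ss_within`, `sigma2_among`, `sigma2_within`,
#'   `phi_st` (as computed), `phi_st_floored`, `p_value`
#' @export
amova <- function(panel, grouping = "section", permutations = 999,
                  seed = NULL) {
  g <- panel_grouping(panel, grouping)
  pops <- unique(g[!is.na(g)])
  if (length(pops) < 2) stop("AMOVA needs >= 2 groups")
  obs <- amova_components(panel$a1, panel$a2, g, pops)
  p <- NA_real_
  if (permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(permutations)) {
      gp <- sample(g)
      if (amova_components(panel$a1, panel$a2, gp, pops)$phi >=
          obs$phi - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + permutations)
  }
  N <- nrow(panel$a1)
  structure(list(df_among = length(pops) - 1L,
                 df_within = 2L * N - length(pops),
                 df_total = 2L * N - 1L,
                 ss_among = obs$ssa, ss_within = obs$ssw,
                 sigma2_among = obs$s2a, sigma2_within = obs$s2w,
                 phi_st = obs$phi, phi_st_floored = max(obs$phi, 0),
                 p_value = p, groups = pops),
            class = "amova_table")
}

#' @export
print.amova_table <- function(x, ...) {
  cat(sprintf("AMOVA: Phi_ST(%d, %d) = %.4g, P = %s\n",
              x$df_among, x$df_total, x$phi_st_floored,
              format(x$p_value, digits = 3)))
  cat(sprintf("  among groups:  SS = %.4g, sigma2 = %.4g\n",
              x$ss_among, x$sigma2_among))
  cat(sprintf("  within groups: SS = %.4g, sigma2 = %.4g\n",
              x$ss_within, x$sigma2_within))
  invisible(x)
}

# Per-locus allele-level sums of squares and moment-equation components,
# summed across loci.  For 0/1 allele-identity distances,
# SS of a set of m copies = (m/2)(1 - sum p_a^2).
amova_components <- function(a1, a2, g, pops) {
  ssa_t <- ssw_t <- s2a_t <- s2w_t <- 0
  for (j in seq_len(ncol(a1))) {
    x1 <- a1[, j]; x2 <- a2[, j]
    ok <- !is.na(x1) & g %in% pops
    if (sum(ok) < 3) next
    x <- c(x1[ok], x2[ok])
    m_tot <- length(x)
    p <- table(x) / m_tot
    sst <- m_tot / 2 * (1 - sum(p^2))
    ssw <- 0; mg <- c()
    for (pp in pops) {
      ii <- which(ok & g == pp)
      if (length(ii) == 0) next
      xg <- c(x1[ii], x2[ii])
      pg <- table(xg) / length(xg)
      ssw <- ssw + length(xg) / 2 * (1 - sum(pg^2))
      mg <- c(mg, length(xg))
    }
    ng <- length(mg)
    if (ng < 2) next
    ssa <- sst - ssw
    dfw <- m_tot - ng; dfa <- ng - 1
    s2w <- ssw / dfw
    n0 <- (m_tot - sum(mg^2) / m_tot) / dfa
    s2a <- (ssa / dfa - s2w) / n0
    ssa_t <- ssa_t + ssa; ssw_t <- ssw_t + ssw
    s2a_t <- s2a_t + s2a; s2w_t <- s2w_t + s2w
  }
  tot <- s2a_t + s2w_t
  list(ssa = ssa_t, ssw = ssw_t, s2a = s2a_t, s2w = s2w_t,
       phi = if (tot > 0) s2a_t / tot else 0)
}

#' Exact G-test of allele-frequency differentiation
#'
#' Per locus, the allele-count contingency table (populations x alleles) is
#' tested with the log-likelihood-ratio G statistic; the null distribution
#' is sampled exactly by randomly reallocating allele copies among
#' populations (which fixes both table margins, i.e. draws i.i.d. tables
#' from the conditional null).  A global test across loci combines the
#' per-locus p-values with Fisher's method.
#'
#' @inheritParams fst_weir_cockerham
#' @param draws Monte-Carlo draws from the conditional null per locus
#' @param seed optional integer seed
#' @return list with `per_locus` data frame (locus, g, p, skipped) and
#'   `global` (`msat_test` from Fisher combination)
#' @export
g_test_differentiation <- function(panel, populations = NULL,
                                   grouping = "section", draws = 2000,
                                   seed = NULL) {
  g <- panel_grouping(panel, grouping)
  if (is.null(populations)) populations <- unique(g[!is.na(g)])
  if (length(populations) < 2) stop("need >= 2 populations")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (j in seq_len(ncol(panel$a1))) {
    ok <- !is.na(panel$a1[, j]) & g %in% populations
    copies <- c(panel$a1[ok, j], panel$a2[ok, j])
    pop <- factor(rep(g[ok], 2), levels = populations)
    al <- factor(copies)
    if (nlevels(al) < 2) {
      rows[[j]] <- data.frame(locus = panel$loci$name[j], g = NA_real_,
                              p = NA_real_, skipped = TRUE)
      next
    }
    gobs <- g_statistic(table(pop, al))
    exceed <- 0L
    n <- length(al)
    for (b in seq_len(draws))
      if (g_statistic(table(pop, al[sample.int(n)])) >= gobs - 1e-12)
        exceed <- exceed + 1L
    rows[[j]] <- data.frame(locus = panel$loci$name[j], g = gobs,
                            p = (1 + exceed) / (1 + draws), skipped = FALSE)
  }
  per <- do.call(rbind, rows)
  global <- combine_p_fisher(per$p[!per$skipped])
  list(per_locus = per, global = global)
}
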