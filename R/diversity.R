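#' Allele frequencies at a locus
#'
#' Frequencies are computed over the `2n` allele copies of the non-missing
#' genotypes (pairwise deletion).
#'
#' @param panel a [genotype_panel()]
#' @param locus locus name or column index
#' @param population optional population label; if given, `grouping` selects
#'   the metadata field it refers to
#' @param grouping see [panel_grouping()]
#' @return named numeric vector of frequencies summing to 1
#' @export
allele_frequencies <- function(panel, locus, population = NULL,
                               grouping = "section") {
  j <- locus_index(panel, locus)
  ii <- pop_rows(panel, population, grouping)
  x <- c(panel$a1[ii, j], panel$a2[ii, j])
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no genotyped individuals at ",
                           panel$loci$name[j],
                           if (!is.null(population)) paste0(" in ", population))
  tab <- table(x)
  stats::setNames(as.numeric(tab) / length(x), names(tab))
}

locus_index <- function(panel, locus) {
  j <- if (is.character(locus)) match(locus, panel$loci$name) else as.integer(locus)
  if (is.na(j) || j < 1 || j > ncol(panel$a1)) stop("unknown locus: ", locus)
  j
}

pop_rows <- function(panel, population, grouping) {
  if (is.null(population)) return(seq_len(nrow(panel$a1)))
  g <- panel_grouping(panel, grouping)
  ii <- which(g == population)
  if (length(ii) == 0) stop("no individuals in population ", population)
  ii
}

# Weir-Cockerham within-population variance components for inbreeding:
# summed over alleles, b = n/(n-1) [ (1 - sum p^2) - (2n-1)/(2n) * ho ],
# c = ho.  fis = b / (b + c); fis = 0 exactly when ho equals the unbiased He.
wc_single_pop_bc <- function(a1, a2) {
  ok <- !is.na(a1)
  n <- sum(ok)
  if (n < 2) return(c(b = NA_real_, c = NA_real_))
  x <- c(a1[ok], a2[ok])
  p <- as.numeric(table(x)) / (2 * n)
  ho <- mean(a1[ok] != a2[ok])
  b <- n / (n - 1) * ((1 - sum(p^2)) - (2 * n - 1) / (2 * n) * ho)
  c(b = b, c = ho)
}

#' Per-locus diversity summary for one population
#'
#' Computes sample size, allele count, observed heterozygosity, Nei's
#' unbiased expected heterozygosity `he = 2n/(2n-1) (1 - sum p_i^2)`,
#' polymorphism information content
#' `pic = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`, the Weir-Cockerham
#' within-population inbreeding coefficient, and the Chakraborty null-allele
#' index.  The Hardy-Weinberg p-value is filled by [hwe_exact()] when
#' `p_hwe = TRUE`.
#'
#' @inheritParams allele_frequencies
#' @param p_hwe logical: also run the exact Hardy-Weinberg test
#' @param unbiased logical: apply the small-sample correction to He
#' @param hwe_args list of arguments passed on to [hwe_exact()]
#' @return one-row data frame (class `locus_diversity`)
#' @export
locus_diversity <- function(panel, locus, population = NULL,
                            grouping = "section", p_hwe = FALSE,
                            unbiased = TRUE, hwe_args = list()) {
  j <- locus_index(panel, locus)
  ii <- pop_rows(panel, population, grouping)
  a1 <- panel$a1[ii, j]; a2 <- panel$a2[ii, j]
  ok <- !is.na(a1)
  n <- sum(ok)
  if (n == 0) stop("no data at locus ", panel$loci$name[j])
  x <- c(a1[ok], a2[ok])
  p <- as.numeric(table(x)) / (2 * n)
  na <- length(p)
  ho <- mean(a1[ok] != a2[ok])
  gene_div <- 1 - sum(p^2)
  he <- if (unbiased && n > 1) 2 * n / (2 * n - 1) * gene_div else gene_div
  pic <- 1 - sum(p^2) -
    (sum(outer(p^2, p^2))[1] - sum(p^4)) # 2*sum_{i<j} p_i^2 p_j^2
  fis <- NA_real_
  monomorphic <- na < 2
  if (!monomorphic && n >= 2) {
    bc <- wc_single_pop_bc(a1, a2)
    denom <- bc["b"] + bc["c"]
    fis <- if (is.finite(denom) && denom > 0) unname(bc["b"] / denom)
           else NA_real_
  }
  ph <- NA_real_
  if (p_hwe && !monomorphic)
    ph <- do.call(hwe_exact, c(list(panel, j, population, grouping = grouping),
                               hwe_args))$p_value
  if (p_hwe && monomorphic) ph <- 1
  nf <- if (he > 0) null_allele_frequency(ho, he)$null_freq else NA_real_
  structure(data.frame(locus = panel$loci$name[j],
                       population = if (is.null(population)) "all" else population,
                       n = n, na = na, ho = ho, he = he, pic = pic,
                       fis = fis, p_hwe = ph, null_freq = nf,
                       monomorphic = monomorphic,
                       stringsAsFactors = FALSE),
            class = c("locus_diversity", "data.frame"))
}

#' Multilocus diversity summary with permutation test for Fis
#'
#' Arithmetic means of Na/Ho/He across loci, plus the multilocus
#' Weir-Cockerham inbreeding coefficient (ratio of variance components summed
#' across loci).  Significance of Fis > 0 is assessed by shuffling allele
#' copies among individuals within the population (which preserves allele
#' frequencies and breaks genotypic association), one-tailed.
#'
#' @inheritParams allele_frequencies
#' @param n_perm number of permutations (>= 1)
#' @param seed optional integer seed
#' @return a list with `per_locus` (data frame), `mean_na`, `mean_ho`,
#'   `mean_he`, `fis`, `p_fis`, `n_perm`
#' @export
multilocus_summary <- function(panel, population = NULL, grouping = "section",
                               n_perm = 10000, seed = NULL) {
  if (ncol(panel$a1) < 2) stop("multilocus summary needs >= 2 loci")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ii <- pop_rows(panel, population, grouping)
  per <- do.call(rbind, lapply(seq_len(ncol(panel$a1)), function(j)
    locus_diversity(panel, j, population, grouping)))
  # observed multilocus fis from summed components
  comps <- lapply(seq_len(ncol(panel$a1)), function(j)
    wc_single_pop_bc(panel$a1[ii, j], panel$a2[ii, j]))
  B <- sum(vapply(comps, `[`, 1, "b"), na.rm = TRUE)
  C <- sum(vapply(comps, `[`, 1, "c"), na.rm = TRUE)
  fis <- if (B + C > 0) B / (B + C) else NA_real_

  # permutation null: reshuffle allele copies within population per locus;
  # frequencies are invariant, only Ho (hence b and c) changes
  copies <- lapply(seq_len(ncol(panel$a1)), function(j) {
    a1 <- panel$a1[ii, j]; a2 <- panel$a2[ii, j]
    ok <- !is.na(a1)
    list(x = c(a1[ok], a2[ok]), n = sum(ok),
         sump2 = sum((as.numeric(table(c(a1[ok], a2[ok]))) /
                        (2 * sum(ok)))^2))
  })
  perm_fis <- vapply(seq_len(n_perm), function(r) {
    Bp <- Cp <- 0
    for (cp in copies) {
      n <- cp$n
      if (n < 2) next
      x <- sample(cp$x)
      ho <- mean(x[seq_len(n)] != x[n + seq_len(n)])
      Bp <- Bp + n / (n - 1) * ((1 - cp$sump2) - (2 * n - 1) / (2 * n) * ho)
      Cp <- Cp + ho
    }
    if (Bp + Cp > 0) Bp / (Bp + Cp) else 0
  }, 1)
  p_fis <- (1 + sum(perm_fis >= fis)) / (1 + n_perm)
  list(per_locus = per,
       mean_na = mean(per$na), mean_ho = mean(per$ho), mean_he = mean(per$he),
       fis = fis, p_fis = p_fis, n_perm = n_perm)
}

#' Chakraborty homozygote-excess null-allele index
#'
#' The index `(he - ho) / (he + ho)`, clipped to \[0, 1\].  Values above
#' `threshold` flag the locus as a null-allele suspect (the conventional
#' screen that removed Cym10/Cym16-like loci from downstream analyses).
#'
#' @param ho observed heterozygosity
#' @param he expected heterozygosity (> 0)
#' @param threshold suspicion threshold on `r`
#' @return list with `null_freq`, `suspect`, `defined`
#' @export
null_allele_frequency <- function(ho, he, threshold = 0.2) {
  if (is.na(he) || he <= 0)
    return(list(null_freq = NA_real_, suspect = NA, defined = FALSE))
  r <- (he - ho) / (he + ho)
  r <- min(max(r, 0), 1)
  list(null_freq = r, suspect = r > threshold, defined = TRUE)
}

#' Per-population diversity table across all loci
#'
#' Convenience wrapper producing one row per (population, locus) plus an
#' `across_loci` row per population, in the layout of a standard
#' microsatellite diversity table.
#'
#' @inheritParams multilocus_summary
#' @param p_hwe logical: include exact Hardy-Weinberg p-values
#' @param hwe_args list of arguments for [hwe_exact()]
#' @return data frame
#' @export
diversity_table <- function(panel, grouping = "section", p_hwe = FALSE,
                            hwe_args = list(), n_perm = 1000, seed = NULL) {
  pops <- unique(panel_grouping(panel, grouping))
  pops <- pops[!is.na(pops)]
  out <- list()
  for (p in pops) {
    per <- do.call(rbind, lapply(seq_len(ncol(panel$a1)), function(j)
      locus_diversity(panel, j, p, grouping, p_hwe = p_hwe,
                      hwe_args = hwe_args)))
    ml <- multilocus_summary(panel, p, grouping, n_perm = n_perm, seed = seed)
    across <- data.frame(locus = "across_loci", population = p,
                         n = round(mean(per$n)), na = ml$mean_na,
                         ho = ml$mean_ho, he = ml$mean_he, pic = NA_real_,
                         fis = ml$fis,
                         p_hwe = if (p_hwe) combine_p_fisher(
                           per$p_hwe[!is.na(per$p_hwe)])$p_value else NA_real_,
                         null_freq = NA_real_, monomorphic = FALSE,
                         stringsAsFactors = FALSE)
    out[[p]] <- rbind(as.data.frame(per), across)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
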