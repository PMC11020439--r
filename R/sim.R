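#' Configuration for the two-stock admixture panel generator
#'
#' Defaults emulate the study design this package validates against: 324
#' fish genotyped at 14 tri/tetranucleotide loci across five river sections,
#' two weakly diverged genetic stocks mixing by season (the rainy-season
#' catch dominated by Stock2, the dry-season catch by Stock1), and mild
#' inbreeding.
#'
#' @param n_individuals sample size
#' @param n_loci number of loci
#' @param alleles_per_locus integer range (min, max) of allele counts drawn
#'   per locus
#' @param motif_length repeat-unit size(s) in bp, recycled over loci
#' @param ancestral_dirichlet_concentration symmetric Dirichlet parameter for
#'   ancestral allele frequencies
#' @param stock_divergence_fst target FST between the two stocks (the
#'   Balding-Nichols beta parameter is chosen so the expected FST equals it)
#' @param fis within-stock inbreeding coefficient
#' @param section_sizes named integer vector of individuals per section
#' @param season_mixture named list: for each season, the probability an
#'   individual belongs to Stock1 (Stock2 gets the complement)
#' @param years integer vector sampled uniformly for the year field
#' @param null_allele_rate per-locus frequency of a hidden null allele
#' @param missing_rate fraction of cells set missing at random
#' @param seed integer seed (required: the generator is deterministic)
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_individuals = 324, n_loci = 14,
                       alleles_per_locus = c(9, 35), motif_length = 4,
                       ancestral_dirichlet_concentration = 0.6,
                       stock_divergence_fst = 0.006, fis = 0.07,
                       section_sizes = NULL,
                       season_mixture = list(rainy = 0.08, dry = 0.65),
                       years = c(2020, 2021),
                       null_allele_rate = 0, missing_rate = 0,
                       seed = 1) {
  if (is.null(section_sizes)) {
    base <- n_individuals %/% 5
    section_sizes <- stats::setNames(rep(base, 5), paste0("S", 4:8))
    section_sizes[5] <- n_individuals - 4 * base
  }
  stopifnot(sum(section_sizes) == n_individuals,
            stock_divergence_fst >= 0, stock_divergence_fst < 1,
            fis >= 0, fis < 1,
            all(unlist(season_mixture) >= 0),
            all(unlist(season_mixture) <= 1),
            null_allele_rate >= 0, null_allele_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (alleles_per_locus[1] < 2)
    stop("alleles_per_locus must allow >= 2 alleles")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a two-stock admixed genotype panel
#'
#' Ancestral allele frequencies are drawn from a symmetric Dirichlet; each
#' stock's frequencies come from a Balding-Nichols distribution
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)` (Dirichlet analogue for multiallelic
#' loci) whose expected FST equals the configured divergence.  Stock
#' membership is drawn per individual from the season mixture; genotypes are
#' drawn with `P(hom_i) = p_i^2 + p_i (1 - p_i) fis` and
#' `P(het_ij) = 2 p_i p_j (1 - fis)`.  Null alleles are a hidden extra
#' allele: a heterozygous carrier looks homozygous for its visible allele
#' and a null homozygote becomes a missing cell.
#'
#' @param config a [sim_config()]
#' @return a [genotype_panel()] whose `meta$stock` carries the true stock
#'   labels, with attribute `truth` (list of stock frequencies and null
#'   allele frequencies)
#' @export
simulate_panel <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_individuals; L <- config$n_loci
  motif <- rep(config$motif_length, length.out = L)
  F <- config$stock_divergence_fst
  amin <- config$alleles_per_locus[1]; amax <- config$alleles_per_locus[2]

  loci <- data.frame(name = sprintf("L%02d", seq_len(L)),
                     motif_length = as.integer(motif))
  freqs <- vector("list", L)
  sizes <- vector("list", L)
  null_freq <- numeric(L)
  for (j in seq_len(L)) {
    k <- sample(amin:amax, 1)
    anc <- as.numeric(stats::rgamma(k, config$ancestral_dirichlet_concentration))
    if (sum(anc) <= 0) anc <- rep(1, k)
    anc <- anc / sum(anc)
    draw_stock <- function() {
      if (F <= 0) return(anc)
      w <- stats::rgamma(k, anc * (1 - F) / F)
      if (sum(w) <= 0) w <- anc
      w / sum(w)
    }
    freqs[[j]] <- list(Stock1 = draw_stock(), Stock2 = draw_stock())
    start <- sample(100:(450 - (k + 5) * motif[j]), 1)
    sizes[[j]] <- start + motif[j] * (seq_len(k) - 1)
    null_freq[j] <- config$null_allele_rate
  }

  section <- rep(names(config$section_sizes), config$section_sizes)
  season <- sample(names(config$season_mixture), n, replace = TRUE)
  year <- sample(config$years, n, replace = TRUE)
  p_stock1 <- unlist(config$season_mixture)[season]
  stock <- ifelse(stats::runif(n) < p_stock1, "Stock1", "Stock2")

  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    k <- length(sizes[[j]])
    pnull <- null_freq[j]
    for (s in c("Stock1", "Stock2")) {
      ii <- which(stock == s)
      if (length(ii) == 0) next
      p <- freqs[[j]][[s]]
      if (pnull > 0) p <- c(p * (1 - pnull), pnull)   # hidden allele k+1
      m <- length(p)
      c1 <- sample.int(m, length(ii), replace = TRUE, prob = p)
      ibd <- stats::runif(length(ii)) < config$fis
      c2 <- ifelse(ibd, c1,
                   sample.int(m, length(ii), replace = TRUE, prob = p))
      if (pnull > 0) {
        both_null <- c1 == m & c2 == m
        c1[c1 == m] <- c2[c1 == m]       # null carrier looks homozygous
        c2[c2 == m] <- c1[c2 == m]
        c1[both_null] <- NA_integer_; c2[both_null] <- NA_integer_
      }
      a1[ii, j] <- sizes[[j]][c1]
      a2[ii, j] <- sizes[[j]][c2]
    }
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n * L) < config$missing_rate, n, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  # a fully missing locus cannot enter a panel register; resample guard
  empty <- colSums(!is.na(a1)) == 0
  if (any(empty)) stop("simulation produced an empty locus; lower missing_rate")
  meta <- data.frame(id = sprintf("ind%03d", seq_len(n)), section = section,
                     season = season, year = year, stock = stock)
  panel <- genotype_panel(a1, a2, loci, meta)
  attr(panel, "truth") <- list(freqs = freqs, sizes = sizes,
                               null_freq = null_freq, config = config)
  panel
}

#' Configuration for the forward Wright-Fisher simulator
#'
#' @param true_ne diploid effective (census = effective) size
#' @param n_loci unlinked loci
#' @param n_generations generations to run
#' @param mutation_rate per-locus per-generation rate
#' @param mutation_model a [mutation_model()] (IAM mutations create a fresh
#'   allele; SMM/TPM step in repeat units)
#' @param sample_size diploid individuals sampled in the last generation
#' @param motif_length repeat-unit size in bp
#' @param size_schedule optional data frame (generation, size) of population
#'   size changes, e.g. a crash shortly before sampling
#' @param founder_alleles number of equally frequent founder alleles
#' @param seed integer seed
#' @return list of class `wf_config`
#' @export
wf_config <- function(true_ne = 100, n_loci = 20, n_generations = 200,
                      mutation_rate = 1e-3, mutation_model = NULL,
                      sample_size = 50, motif_length = 4,
                      size_schedule = NULL, founder_alleles = 10, seed = 1) {
  if (is.null(mutation_model)) mutation_model <- msatpop::mutation_model("SMM")
  stopifnot(true_ne >= 2, mutation_rate >= 0, mutation_rate <= 1,
            sample_size <= true_ne || !is.null(size_schedule))
  structure(as.list(environment()), class = "wf_config")
}

#' Forward Wright-Fisher simulation of unlinked microsatellite loci
#'
#' Diploid random-mating population of constant (or scheduled) size; each
#' offspring draws two parents, one allele per locus per parent.  Mutations
#' occur per allele copy per generation; the final-generation sample is
#' returned as a [genotype_panel()] (allele sizes = 200 + motif x repeat
#' score).
#'
#' @param config a [wf_config()]
#' @return a [genotype_panel()] of `sample_size` individuals
#' @export
simulate_wright_fisher <- function(config = wf_config()) {
  set.seed(config$seed)
  N <- config$true_ne; L <- config$n_loci
  mu <- config$mutation_rate
  model <- config$mutation_model
  # allele state = repeat score (integer); IAM uses an ever-growing counter
  founders <- seq_len(config$founder_alleles)   # contiguous repeat ladder
  pop <- array(sample(founders, N * L * 2, replace = TRUE), dim = c(N, L, 2))
  iam_counter <- max(founders)
  geomq <- geom_q_for_variance(model$multistep_variance)
  sched <- config$size_schedule
  for (gen in seq_len(config$n_generations)) {
    if (!is.null(sched)) {
      hit <- which(sched$generation == gen)
      if (length(hit)) N <- sched$size[hit[1]]
    }
    Nprev <- dim(pop)[1]
    mothers <- sample.int(Nprev, N, replace = TRUE)
    fathers <- sample.int(Nprev, N, replace = TRUE)
    newpop <- array(0L, dim = c(N, L, 2))
    pick1 <- matrix(sample(1:2, N * L, replace = TRUE), N, L)
    pick2 <- matrix(sample(1:2, N * L, replace = TRUE), N, L)
    for (l in seq_len(L)) {
      newpop[, l, 1] <- pop[cbind(mothers, l, pick1[, l])]
      newpop[, l, 2] <- pop[cbind(fathers, l, pick2[, l])]
    }
    if (mu > 0) {
      nm <- stats::rbinom(1, N * L * 2, mu)
      if (nm > 0) {
        idx <- sample.int(N * L * 2, nm)
        if (model$kind == "IAM") {
          newpop[idx] <- iam_counter + seq_len(nm)
          iam_counter <- iam_counter + nm
        } else {
          step <- rep(1L, nm)
          if (model$kind == "TPM") {
            multi <- stats::runif(nm) > model$p_single_step
            step[multi] <- 1L + stats::rgeom(sum(multi), geomq)
          }
          sgn <- sample(c(-1L, 1L), nm, replace = TRUE)
          newpop[idx] <- newpop[idx] + sgn * step
        }
      }
    }
    pop <- newpop
  }
  if (config$sample_size > dim(pop)[1])
    stop("sample_size exceeds the final population size")
  take <- sample.int(dim(pop)[1], config$sample_size)
  base <- 200L - min(min(pop), 0L) * config$motif_length
  a1 <- base + pop[take, , 1, drop = FALSE][, , 1] * config$motif_length
  a2 <- base + pop[take, , 2, drop = FALSE][, , 1] * config$motif_length
  genotype_panel(a1, a2,
                 data.frame(name = sprintf("wf%02d", seq_len(L)),
                            motif_length = config$motif_length),
                 data.frame(id = sprintf("ind%03d", seq_len(config$sample_size)),
                            section = "wf", season = "unknown",
                            year = NA_integer_))
}
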