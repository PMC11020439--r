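#' Run the full population-genetics analysis
#'
#' Executes, in the order diversity -> Hardy-Weinberg -> bottleneck and Ne
#' -> structure -> differentiation, every module of the package on a panel,
#' writing the familiar table shapes (per-population diversity, bottleneck
#' summary, Ne projections, pairwise differentiation) as CSV files plus a
#' machine-readable JSON-like results list.  Module failures are recorded in
#' `errors` and dependent steps skipped, never silently dropped.
#'
#' @param panel a [genotype_panel()], or a path readable by [read_panel()]
#' @param out_dir output directory (created if absent); `NULL` skips file
#'   output
#' @param grouping primary grouping (default `"section"`)
#' @param seed global seed; every stochastic stage derives its own seed from
#'   it and records it in the results
#' @param format panel file format when `panel` is a path
#' @param hwe_steps,bottleneck_sims,ne_maf,amova_perms,g_draws,
#'   structure_k,structure_reps,structure_steps,structure_burnin
#'   module knobs (defaults are desk-scale)
#' @param horizons projection horizons in generations
#' @return list of class `msatpop_results` with one element per stage plus
#'   `seeds` and `errors`
#' @export
run_full_analysis <- function(panel, out_dir = NULL, grouping = "section",
                              seed = 1, format = "tabular",
                              hwe_steps = 20000, bottleneck_sims = 500,
                              ne_maf = 0.02, amova_perms = 199,
                              g_draws = 500, structure_k = 1:4,
                              structure_reps = 3, structure_steps = 2000,
                              structure_burnin = 500,
                              horizons = c(10, 50, 100)) {
  if (is.character(panel)) {
    if (!file.exists(panel)) stop("input file not found: ", panel)
    panel <- read_panel(panel, format)
  }
  set.seed(seed)
  seeds <- as.list(sample.int(2^30, 8))
  names(seeds) <- c("hwe", "fis", "bottleneck", "ne", "amova", "gtest",
                    "structure", "misc")
  res <- list(seed = seed, seeds = seeds, errors = list())
  pops <- unique(panel_grouping(panel, grouping))
  step <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      res$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    res[[name]] <<- v
    v
  }

  step("diversity", diversity_table(panel, grouping, p_hwe = TRUE,
                                    hwe_args = list(steps = hwe_steps,
                                                    dememorization = hwe_steps %/% 10),
                                    n_perm = 1000, seed = seeds$fis))

  step("bottleneck", {
    set.seed(seeds$bottleneck)
    lapply(stats::setNames(pops, pops), function(p)
      bottleneck_report(panel, p, grouping, n_sim = bottleneck_sims))
  })

  ne <- step("ne", {
    lapply(stats::setNames(pops, pops), function(p)
      tryCatch(estimate_ne_ld(panel, p, grouping, maf_cutoff = ne_maf),
               error = function(e) NULL))
  })
  if (!is.null(ne))
    step("projection", {
      out <- list()
      for (p in names(ne)) {
        if (is.null(ne[[p]])) next
        used <- tryCatch(select_ne_for_projection(ne[[p]]),
                         error = function(e) NULL)
        if (is.null(used)) next
        pr <- project_heterozygosity(used, horizons)
        out[[p]] <- list(ne_used = used, projection = pr,
                         threat = classify_threat(pr))
      }
      out
    })

  ens <- step("structure", {
    e <- admixture_ensemble(panel, structure_k, structure_reps,
                            structure_steps, structure_burnin,
                            seed = seeds$structure)
    align_replicates(e)
  })
  if (!is.null(ens)) {
    ksel <- step("k_selection", select_k(ens, panel, grouping))
    if (!is.null(ksel))
      step("season_composition", {
        # the Evanno selector is the headline K for the seasonal summary
        k_use <- if (!is.na(ksel$by_selector[["evanno"]]))
          ksel$by_selector[["evanno"]] else ksel$chosen_k
        ks <- vapply(ens$runs, `[[`, 1, "K")
        pick <- which(ks == k_use)[1]
        if (k_use >= 2 && !is.na(pick))
          season_composition(panel, ens$runs[[pick]]$Q)
        else NULL
      })
  }

  step("differentiation", {
    pd <- pairwise_differentiation(panel, grouping = grouping,
                                   permutations = 0)
    set.seed(seeds$amova)
    am <- amova(panel, grouping, permutations = amova_perms)
    gt <- g_test_differentiation(panel, grouping = grouping,
                                 draws = g_draws, seed = seeds$gtest)
    list(pairwise = pd, amova = am, g_test = gt)
  })

  class(res) <- "msatpop_results"
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
  if (!is.null(res$diversity)) wcsv(res$diversity, "diversity.csv")
  if (!is.null(res$bottleneck)) {
    bt <- do.call(rbind, lapply(res$bottleneck, function(b)
      data.frame(population = b$population, p_iam = b$p_iam,
                 p_smm = b$p_smm, p_tpm = b$p_tpm, m_ratio = b$m_ratio)))
    wcsv(bt, "bottleneck.csv")
  }
  if (!is.null(res$projection)) {
    pr <- do.call(rbind, lapply(names(res$projection), function(p) {
      x <- res$projection[[p]]
      data.frame(population = p, ne_used = x$ne_used,
                 t = x$projection$horizons,
                 ht_reduction = x$projection$ht_reduction_abs,
                 ht_reduction_pct = x$projection$ht_reduction_pct,
                 threat = x$threat)
    }))
    wcsv(pr, "ne_projection.csv")
  }
  if (!is.null(res$differentiation)) {
    utils::write.csv(res$differentiation$pairwise$combined,
                     file.path(out_dir, "pairwise_differentiation.csv"))
  }
  if (!is.null(res$season_composition))
    wcsv(as.data.frame(res$season_composition), "season_composition.csv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    slim <- res
    slim$structure <- NULL               # Q matrices go to their own files
    jsonlite::write_json(slim, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
  }
  invisible(out_dir)
}
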