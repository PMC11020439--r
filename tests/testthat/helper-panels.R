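# Small panels built in code for the unit tests.

toy_panel <- function(a1, a2, sections = NULL, motif = 4L,
                      seasons = NULL, years = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  n <- nrow(a1); L <- ncol(a1)
  genotype_panel(a1, a2,
                 data.frame(name = paste0("loc", seq_len(L)),
                            motif_length = rep(motif, length.out = L)),
                 data.frame(id = sprintf("i%02d", seq_len(n)),
                            section = sections %||% rep("A", n),
                            season = seasons %||% rep("unknown", n),
                            year = years %||% rep(NA_integer_, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random Hardy-Weinberg panel: one population, independent loci
random_hwe_panel <- function(n = 40, L = 4, k = 5, seed = 1) {
  set.seed(seed)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    p <- as.numeric(stats::rgamma(k, 1)); p <- p / sum(p)
    sizes <- 100L + 4L * seq_len(k)
    a1[, j] <- sizes[sample.int(k, n, TRUE, p)]
    a2[, j] <- sizes[sample.int(k, n, TRUE, p)]
  }
  toy_panel(a1, a2)
}
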