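#' Construct a genotype panel
#'
#' A `genotype_panel` holds co-dominant diploid microsatellite calls for a set
#' of individuals at a set of loci, plus per-individual metadata.  Alleles are
#' stored as integer fragment sizes in base pairs; each call is an unordered
#' pair of sizes, canonicalized smaller-first, or missing (both `NA`).
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele sizes in bp.
#'   Column names are locus names.  A cell is missing iff both entries are
#'   `NA`; half-calls are rejected.
#' @param loci data frame with columns `name` and `motif_length` (bp per
#'   repeat unit, >= 1).  `motif_length` is the divisor used by the
#'   Garza-Williamson M-ratio.
#' @param meta data frame with columns `id` (unique), `section`, `season`
#'   (`"rainy"`, `"dry"` or `"unknown"`), `year`, and optionally `stock`.
#' @return an object of class `genotype_panel` with elements `a1`, `a2`
#'   (canonicalized), `loci`, `meta`, and `registers` (per-locus sorted
#'   vector of observed allele sizes).
#' @export
genotype_panel <- function(a1, a2, loci, meta) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("a1 and a2 must have identical dimensions")
  if (nrow(loci) != ncol(a1))
    stop("loci table has ", nrow(loci), " rows but call matrices have ",
         ncol(a1), " columns")
  if (nrow(meta) != nrow(a1))
    stop("meta has ", nrow(meta), " rows but call matrices have ",
         nrow(a1), " rows")
  loci <- as.data.frame(loci)
  if (!all(c("name", "motif_length") %in% names(loci)))
    stop("loci must have columns 'name' and 'motif_length'")
  if (any(loci$motif_length < 1)) stop("motif_length must be >= 1")
  if (anyDuplicated(loci$name)) stop("duplicate locus names")
  meta <- as.data.frame(meta)
  if (!"id" %in% names(meta)) stop("meta must have an 'id' column")
  if (anyDuplicated(meta$id)) stop("individual ids must be unique")
  for (col in c("section", "season", "year"))
    if (!col %in% names(meta)) meta[[col]] <- rep("unknown", nrow(meta))
  if (!"stock" %in% names(meta)) meta$stock <- rep(NA_character_, nrow(meta))
  colnames(a1) <- colnames(a2) <- loci$name

  # half-calls are invalid: missing is all-or-nothing per cell
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-called genotypes at ", sum(half), " cell(s); a cell must be ",
         "fully called or fully missing")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele sizes must be positive integers")

  # canonical order: smaller allele first
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  registers <- lapply(seq_len(ncol(a1)), function(j)
    sort(unique(c(a1[, j], a2[, j])[!is.na(c(a1[, j], a2[, j]))])))
  names(registers) <- loci$name
  structure(list(a1 = a1, a2 = a2, loci = loci, meta = meta,
                 registers = registers),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$a1), "individuals x", ncol(x$a1), "loci\n")
  na <- vapply(x$registers, length, 1L)
  cat("  alleles/locus:", min(na), "-", max(na),
      "| missing calls:", sum(is.na(x$a1)), "\n")
  cat("  sections:", paste(sort(unique(x$meta$section)), collapse = " "), "\n")
  invisible(x)
}

#' Number of individuals / loci in a panel
#' @param panel a `genotype_panel`
#' @return integer count
#' @export
n_individuals <- function(panel) nrow(panel$a1)

#' @rdname n_individuals
#' @export
n_loci <- function(panel) ncol(panel$a1)

#' Resolve a population grouping to a factor over individuals
#'
#' @param panel a `genotype_panel`
#' @param grouping `"section"`, `"stock"`, `"season"`, `"season_year"`, or
#'   `"pooled"` (everyone in one population); alternatively a vector of labels
#'   of length `n_individuals(panel)`.
#' @return character vector of population labels
#' @export
panel_grouping <- function(panel, grouping = "section") {
  if (length(grouping) == nrow(panel$meta)) return(as.character(grouping))
  switch(as.character(grouping),
    section = as.character(panel$meta$section),
    stock = as.character(panel$meta$stock),
    season = as.character(panel$meta$season),
    season_year = paste(panel$meta$season, panel$meta$year, sep = "_"),
    pooled = rep("all", nrow(panel$meta)),
    stop("unknown grouping: ", grouping))
}

#' Subset a panel by individuals and/or loci
#'
#' @param panel a `genotype_panel`
#' @param individuals logical/integer index or character ids
#' @param loci logical/integer index or character locus names
#' @return a `genotype_panel`; allele registers are rebuilt from the subset
#' @export
subset_panel <- function(panel, individuals = NULL, loci = NULL) {
  ii <- seq_len(nrow(panel$a1)); jj <- seq_len(ncol(panel$a1))
  if (!is.null(individuals)) {
    ii <- if (is.character(individuals)) match(individuals, panel$meta$id)
          else ii[individuals]
    if (anyNA(ii)) stop("unknown individual id(s)")
  }
  if (!is.null(loci)) {
    jj <- if (is.character(loci)) match(loci, panel$loci$name) else jj[loci]
    if (anyNA(jj)) stop("unknown locus name(s)")
  }
  if (length(jj) == 0) stop("cannot drop all loci")
  if (length(ii) == 0) stop("cannot drop all individuals")
  genotype_panel(panel$a1[ii, jj, drop = FALSE],
                 panel$a2[ii, jj, drop = FALSE],
                 panel$loci[jj, , drop = FALSE],
                 panel$meta[ii, , drop = FALSE])
}

#' Filter a panel: drop loci, screen rare alleles for Ne, drop sparse individuals
#'
#' Rare alleles below `min_maf` are *not* deleted: they are recorded in the
#' panel's `ne_excluded` attribute and skipped only by the
#' linkage-disequilibrium Ne estimator (diversity statistics keep all data).
#' Loci listed in `drop_loci` are removed everywhere (the conventional
#' treatment of loci carrying null alleles).
#'
#' @param panel a `genotype_panel`
#' @param min_maf minimum allele frequency in \[0,1\] for the Ne-eligible set
#' @param drop_loci character vector of locus names to remove
#' @param drop_missing_above drop individuals whose fraction of missing loci
#'   exceeds this threshold (default 1 = keep all)
#' @return a filtered `genotype_panel`
#' @export
filter_panel <- function(panel, min_maf = 0, drop_loci = NULL,
                         drop_missing_above = 1) {
  if (min_maf < 0 || min_maf > 1 || drop_missing_above < 0 ||
      drop_missing_above > 1)
    stop("thresholds must lie in [0, 1]")
  keep <- !(panel$loci$name %in% drop_loci)
  if (!any(keep)) stop("filter would drop all loci")
  out <- panel
  if (!all(keep)) out <- subset_panel(out, loci = which(keep))
  miss <- rowMeans(is.na(out$a1))
  if (any(miss > drop_missing_above)) {
    if (all(miss > drop_missing_above)) stop("filter would drop all individuals")
    out <- subset_panel(out, individuals = miss <= drop_missing_above)
  }
  excl <- lapply(out$loci$name, function(lc) {
    p <- allele_frequencies(out, lc)
    as.integer(names(p)[p < min_maf])
  })
  names(excl) <- out$loci$name
  out$ne_excluded <- excl
  out
}
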