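#' Read a genotype panel from a text file
#'
#' Three dialects are supported:
#' \describe{
#'   \item{tabular}{comma- or tab-delimited, header
#'     `id,section,season,year[,stock],<locus>_1,<locus>_2,...`; empty or
#'     `NA` fields are missing.  An optional leading comment line
#'     `# motif_length: <locus>=<bp> ...` records repeat-unit sizes; without
#'     it, motif lengths are inferred per locus as the greatest common divisor
#'     of allele-size differences.}
#'   \item{genepop}{GenePop 4.x: title line, one locus name per line, `Pop`
#'     separators, `id ,` followed by 6-digit diploid codes, `000000` (or an
#'     allele code of 0) meaning missing.  If a sidecar file
#'     `<path>.alleles` written by [write_panel()] is present, codes are
#'     translated back to true fragment sizes; otherwise codes are taken as
#'     sizes.  The GenePop population becomes the `section` field.}
#'   \item{structure}{whitespace-delimited, header of locus names, then one
#'     or two rows per individual (`rows_per_ind`); first two columns are id
#'     and population label, `-9` is missing.}
#' }
#'
#' @param path file to read
#' @param format `"tabular"`, `"genepop"` or `"structure"`
#' @param motif_lengths optional named vector of repeat-unit sizes in bp,
#'   overriding anything inferred from the file
#' @param rows_per_ind for STRUCTURE files, 1 or 2 rows per individual
#' @return a [genotype_panel()]
#' @export
read_panel <- function(path, format = c("tabular", "genepop", "structure"),
                       motif_lengths = NULL, rows_per_ind = 2) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  panel <- switch(format,
    tabular = read_panel_tabular(path),
    genepop = read_panel_genepop(path),
    structure = read_panel_structure(path, rows_per_ind))
  if (!is.null(motif_lengths)) {
    hit <- match(panel$loci$name, names(motif_lengths))
    panel$loci$motif_length <- ifelse(is.na(hit), panel$loci$motif_length,
                                      as.integer(motif_lengths[hit]))
  }
  panel
}

# Motif length fallback: gcd of allele-size differences on the register
# (microsatellite ladders are arithmetic in the repeat unit).
infer_motif <- function(register) {
  if (length(register) < 2) return(4L)
  d <- diff(sort(register))
  g <- d[1]
  for (x in d[-1]) g <- gcd2(g, x)
  as.integer(max(g, 1L))
}
gcd2 <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }

parse_call_cols <- function(header) {
  gc <- grep("_[12]$", header)
  if (length(gc) == 0 || length(gc) %% 2 != 0)
    stop("malformed header: expected paired <locus>_1/<locus>_2 columns")
  loci <- unique(sub("_[12]$", "", header[gc]))
  for (lc in loci)
    if (!all(paste0(lc, c("_1", "_2")) %in% header))
      stop("locus ", lc, " lacks one of its two allele columns")
  list(loci = loci, cols = gc)
}

read_panel_tabular <- function(path) {
  lines <- readLines(path, warn = FALSE)
  motif <- NULL
  while (length(lines) && grepl("^#", lines[1])) {
    if (grepl("^#\\s*motif_length:", lines[1])) {
      spec <- sub("^#\\s*motif_length:\\s*", "", lines[1])
      kv <- strsplit(strsplit(spec, "[,;]?\\s+")[[1]], "=")
      motif <- stats::setNames(as.integer(vapply(kv, `[`, "", 2)),
                               vapply(kv, `[`, "", 1))
    }
    lines <- lines[-1]
  }
  if (length(lines) < 2) stop("tabular file has no data rows")
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), check.names = FALSE)
  pc <- parse_call_cols(names(df))
  a1 <- as.matrix(df[paste0(pc$loci, "_1")])
  a2 <- as.matrix(df[paste0(pc$loci, "_2")])
  meta <- df[setdiff(names(df), names(df)[pc$cols])]
  if (!"id" %in% names(meta)) stop("tabular file lacks an 'id' column")
  ml <- vapply(seq_along(pc$loci), function(j) {
    lc <- pc$loci[j]
    if (!is.null(motif) && lc %in% names(motif)) motif[[lc]]
    else infer_motif(unique(c(a1[, j], a2[, j])))
  }, 1L)
  genotype_panel(a1, a2,
                 data.frame(name = pc$loci, motif_length = ml), meta)
}

read_panel_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("GenePop file too short")
  body <- lines[-1]                       # drop title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("GenePop file has no 'Pop' line")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); pops <- character(); rows <- list()
  pop_no <- 0L
  for (k in seq(pop_idx[1], length(body))) {
    ln <- body[k]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_no <- pop_no + 1L
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop("GenePop parse error at line ", k + 1, ": missing ',' separator")
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("GenePop parse error at line ", k + 1, ": expected ",
           length(loci), " genotypes, got ", length(codes))
    g <- t(vapply(codes, function(cd) {
      if (!grepl("^[0-9]{4}$|^[0-9]{6}$", cd))
        stop("GenePop parse error at line ", k + 1, ": bad code '", cd, "'")
      w <- nchar(cd) / 2
      c(as.integer(substr(cd, 1, w)), as.integer(substr(cd, w + 1, 2 * w)))
    }, integer(2)))
    g[g == 0] <- NA_integer_               # allele code 0 = missing
    g[is.na(g[, 1]) | is.na(g[, 2]), ] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, paste0("pop", pop_no))
    rows[[length(rows) + 1L]] <- g
  }
  a1 <- do.call(rbind, lapply(rows, function(g) g[, 1]))
  a2 <- do.call(rbind, lapply(rows, function(g) g[, 2]))
  ml <- rep(4L, length(loci))
  sidecar <- paste0(path, ".alleles")
  if (file.exists(sidecar)) {
    map <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
    for (j in seq_along(loci)) {
      mj <- map[map$locus == loci[j], ]
      if (nrow(mj)) {
        tr <- stats::setNames(mj$size, mj$code)
        a1[, j] <- as.integer(tr[as.character(a1[, j])])
        a2[, j] <- as.integer(tr[as.character(a2[, j])])
        ml[j] <- mj$motif_length[1]
      }
    }
  } else {
    for (j in seq_along(loci))
      ml[j] <- infer_motif(unique(c(a1[, j], a2[, j])))
  }
  genotype_panel(a1, a2, data.frame(name = loci, motif_length = ml),
                 data.frame(id = ids, section = pops,
                            season = "unknown", year = NA_integer_))
}

read_panel_structure <- function(path, rows_per_ind = 2) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  dat <- lines[-1]
  if (length(dat) %% rows_per_ind != 0)
    stop("STRUCTURE file: ", length(dat), " data rows not divisible by ",
         rows_per_ind)
  fields <- lapply(dat, function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  nf <- lengths(fields)
  if (length(unique(nf)) != 1)
    stop("STRUCTURE parse error: ragged rows (line ",
         which(nf != nf[1])[1] + 1, ")")
  per_row <- if (rows_per_ind == 2) 1L else 2L  # allele columns per locus
  if (nf[1] != 2 + per_row * length(loci))
    stop("STRUCTURE parse error: expected ", 2 + per_row * length(loci),
         " fields per row, found ", nf[1])
  n <- length(dat) / rows_per_ind
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  ids <- pops <- character(n)
  for (i in seq_len(n)) {
    if (rows_per_ind == 2) {
      r1 <- fields[[2 * i - 1]]; r2 <- fields[[2 * i]]
      if (r1[1] != r2[1])
        stop("STRUCTURE parse error: row pair for individual ", i,
             " has mismatched ids")
      ids[i] <- r1[1]; pops[i] <- r1[2]
      a1[i, ] <- as.integer(r1[-(1:2)]); a2[i, ] <- as.integer(r2[-(1:2)])
    } else {
      r <- fields[[i]]
      ids[i] <- r[1]; pops[i] <- r[2]
      v <- as.integer(r[-(1:2)])
      a1[i, ] <- v[seq(1, length(v), 2)]; a2[i, ] <- v[seq(2, length(v), 2)]
    }
  }
  a1[a1 == -9] <- NA_integer_; a2[a2 == -9] <- NA_integer_
  bad <- xor(is.na(a1), is.na(a2))
  a1[bad] <- NA_integer_; a2[bad] <- NA_integer_
  ml <- vapply(seq_along(loci), function(j)
    infer_motif(unique(c(a1[, j], a2[, j]))), 1L)
  genotype_panel(a1, a2, data.frame(name = loci, motif_length = ml),
                 data.frame(id = ids, section = pops,
                            season = "unknown", year = NA_integer_))
}

#' Write a genotype panel to a text file
#'
#' GenePop export rank-encodes each allele as a 3-digit code within its locus
#' register and writes a sidecar `<path>.alleles` CSV (locus, code, size,
#' motif_length) so true fragment sizes survive a round trip; STRUCTURE
#' export writes integer sizes with `-9` for missing.
#'
#' @param panel a [genotype_panel()]
#' @param path output file
#' @param format `"tabular"`, `"genepop"` or `"structure"`
#' @param rows_per_ind for STRUCTURE, 1 or 2 rows per individual
#' @param grouping population grouping used for GenePop `Pop` blocks and the
#'   STRUCTURE population column (see [panel_grouping()])
#' @return `path`, invisibly
#' @export
write_panel <- function(panel, path,
                        format = c("tabular", "genepop", "structure"),
                        rows_per_ind = 2, grouping = "section") {
  format <- match.arg(format)
  if (nrow(panel$a1) == 0 || ncol(panel$a1) == 0)
    stop("refusing to write an empty panel")
  switch(format,
    tabular = write_panel_tabular(panel, path),
    genepop = write_panel_genepop(panel, path, grouping),
    structure = write_panel_structure(panel, path, rows_per_ind, grouping))
  invisible(path)
}

write_panel_tabular <- function(panel, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# motif_length: ",
                    paste0(panel$loci$name, "=", panel$loci$motif_length,
                           collapse = " ")), con)
  df <- panel$meta
  for (j in seq_len(ncol(panel$a1))) {
    df[[paste0(panel$loci$name[j], "_1")]] <- panel$a1[, j]
    df[[paste0(panel$loci$name[j], "_2")]] <- panel$a2[, j]
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
}

write_panel_genepop <- function(panel, path, grouping = "section") {
  if (any(vapply(panel$registers, length, 1L) > 999))
    stop("GenePop export supports at most 999 alleles per locus")
  con <- file(path, "w"); on.exit(close(con))
  writeLines("msatpop GenePop export", con)
  writeLines(panel$loci$name, con)
  pops <- panel_grouping(panel, grouping)
  code <- function(j, a) {
    ifelse(is.na(a), "000",
           formatC(match(a, panel$registers[[j]]), width = 3, flag = "0"))
  }
  for (p in unique(pops)) {
    writeLines("Pop", con)
    for (i in which(pops == p)) {
      codes <- vapply(seq_len(ncol(panel$a1)), function(j)
        paste0(code(j, panel$a1[i, j]), code(j, panel$a2[i, j])), "")
      writeLines(paste0(panel$meta$id[i], " , ", paste(codes, collapse = " ")),
                 con)
    }
  }
  map <- do.call(rbind, lapply(seq_len(ncol(panel$a1)), function(j)
    data.frame(locus = panel$loci$name[j],
               code = seq_along(panel$registers[[j]]),
               size = panel$registers[[j]],
               motif_length = panel$loci$motif_length[j])))
  utils::write.csv(map, paste0(path, ".alleles"), row.names = FALSE)
}

write_panel_structure <- function(panel, path, rows_per_ind = 2,
                                  grouping = "section") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(panel$loci$name, collapse = " "), con)
  pops <- panel_grouping(panel, grouping)
  popcode <- as.integer(factor(pops))
  enc <- function(a) ifelse(is.na(a), -9L, a)
  for (i in seq_len(nrow(panel$a1))) {
    if (rows_per_ind == 2) {
      writeLines(paste(c(panel$meta$id[i], popcode[i], enc(panel$a1[i, ])),
                       collapse = " "), con)
      writeLines(paste(c(panel$meta$id[i], popcode[i], enc(panel$a2[i, ])),
                       collapse = " "), con)
    } else {
      inter <- as.vector(rbind(enc(panel$a1[i, ]), enc(panel$a2[i, ])))
      writeLines(paste(c(panel$meta$id[i], popcode[i], inter),
                       collapse = " "), con)
    }
  }
}
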