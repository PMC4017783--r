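# Plain-text readers and writers.
#
# Genotype TSV: header "id" plus one column per locus; one row per
# individual; each cell "t:c" with t the total copy number and c the allele-1
# count (e.g. "2:1", "3:2", "0:0").
#
# Haplotype TSV (truth or phased output): columns id, chrom, then per-locus
# chromosome symbols from {-,0,1,00,01,11}; two rows per individual.
# Phased files start with "#"-prefixed metadata lines (mode, K, seed, block).
#
# Frequency TSV: columns haplotype (per-locus symbols joined by ","),
# frequency.

# haplotype state key (digit string) <-> display symbol string
key_to_symbols <- function(key, mode = "noninternal") {
  codes <- as.integer(strsplit(key, "", fixed = TRUE)[[1L]])
  paste(state_symbols(mode)[codes], collapse = ",")
}

symbols_to_key <- function(sym, mode = "noninternal") {
  parts <- strsplit(sym, ",", fixed = TRUE)[[1L]]
  paste(match(parts, state_symbols(mode)), collapse = "")
}

#' Write / read a genotype TSV
#'
#' @param geno a `cnv_geno`.
#' @param path file path.
#' @return `read_genotypes` returns a `cnv_geno`.
#' @export
write_genotypes <- function(geno, path) {
  L <- n_loci(geno)
  cells <- matrix(paste(geno$cn, geno$ones, sep = ":"), nrow = nrow(geno$cn))
  df <- data.frame(id = geno$ids, cells, stringsAsFactors = FALSE)
  names(df) <- c("id", sprintf("L%04d", seq_len(L)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  parts <- regmatches(cells, regexec("^([0-9]+):([0-9]+)$", cells))
  bad <- which(lengths(parts) != 3L, arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(cells))
    stop(sprintf("malformed genotype cell '%s' at row %d, column %s",
                 cells[bad[1L]], rc[1L], colnames(cells)[rc[2L]]))
  }
  cn <- matrix(as.integer(vapply(parts, `[`, character(1), 2L)),
               nrow = nrow(cells))
  ones <- matrix(as.integer(vapply(parts, `[`, character(1), 3L)),
                 nrow = nrow(cells))
  ok <- !is.na(cn) & !is.na(ones) & cn >= 0L & cn <= 4L & ones >= 0L & ones <= cn
  if (!all(ok)) {
    rc <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype cell '%s' at row %d, column %s",
                 cells[rc[1L], rc[2L]], rc[1L], colnames(cells)[rc[2L]]))
  }
  new_genotypes(cn, ones, ids)
}

#' Write / read haplotype assignments as TSV
#'
#' Two rows per individual, per-locus chromosome symbols; `meta` entries are
#' written as leading `# key=value` lines.
#'
#' @param assignments list of 2-row state-code matrices.
#' @param ids individual labels.
#' @param path file path.
#' @param meta optional named list recorded as comment header.
#' @return `read_haplotypes` returns `list(assignments =, ids =, meta =)`.
#' @export
write_haplotypes <- function(assignments, ids, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
  L <- ncol(assignments[[1L]])
  writeLines(paste(c("id", "chrom", sprintf("L%04d", seq_len(L))),
                   collapse = "\t"), con)
  for (t in seq_along(assignments)) {
    mat <- format_states(assignments[[t]])
    for (r in seq_len(nrow(mat)))
      writeLines(paste(c(ids[t], r, mat[r, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1L, eq - 1L)]] <- substring(kv, eq + 1L)
  }
  df <- utils::read.table(text = lines[!hdr], sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  ids <- unique(df$id)
  assignments <- lapply(ids, function(id) {
    rows <- df[df$id == id, -(1:2), drop = FALSE]
    mat <- t(apply(as.matrix(rows), 1L, parse_states))
    dimnames(mat) <- NULL
    attr(mat, "mode") <- "noninternal"
    mat
  })
  list(assignments = assignments, ids = ids, meta = meta)
}

#' Write / read a haplotype frequency TSV
#'
#' @param f named frequency vector (haplotype state keys).
#' @param path file path.
#' @param mode phasing mode for symbol rendering.
#' @return `read_frequencies` returns a named numeric vector keyed like `f`.
#' @export
write_frequencies <- function(f, path, mode = "noninternal") {
  df <- data.frame(
    haplotype = vapply(names(f), key_to_symbols, character(1), mode = mode),
    frequency = as.numeric(f), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequencies
#' @export
read_frequencies <- function(path, mode = "noninternal") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  f <- df$frequency
  names(f) <- vapply(df$haplotype, symbols_to_key, character(1), mode = mode)
  f
}

#' Write / read duplicated-region truth records
#'
#' Columns: ind, chrom, start, end (0-based half-open), copy1, copy2
#' (allele strings over 0/1).
#'
#' @param records list of internal truth records (see [sample_individuals()]).
#' @param path file path.
#' @export
write_internal_truth <- function(records, path) {
  df <- data.frame(
    ind = vapply(records, `[[`, integer(1), "ind"),
    chrom = vapply(records, `[[`, integer(1), "chrom"),
    start = vapply(records, function(r) as.integer(r$start), integer(1)),
    end = vapply(records, function(r) as.integer(r$end), integer(1)),
    copy1 = vapply(records, function(r)
      paste(r$copies[1L, ], collapse = ""), character(1)),
    copy2 = vapply(records, function(r)
      paste(r$copies[2L, ], collapse = ""), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_internal_truth
#' @export
read_internal_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "integer", "integer",
                                         "integer", "character", "character"))
  lapply(seq_len(nrow(df)), function(i) {
    c1 <- as.integer(strsplit(df$copy1[i], "")[[1L]])
    c2 <- as.integer(strsplit(df$copy2[i], "")[[1L]])
    list(ind = df$ind[i], chrom = df$chrom[i], start = df$start[i],
         end = df$end[i], copies = rbind(c1, c2, deparse.level = 0))
  })
}
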