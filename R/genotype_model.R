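# Data model for joint CNV/SNP genotypes and chromosome-level haplotypes.
#
# Two phasing modes share one machinery:
#  * non-internal: each of the two chromosomes of a diploid individual carries,
#    at every locus, one of the site states "-" (deleted), "0", "1" (single
#    copy), "00", "01", "11" (duplicated).  Per-chromosome copy number is
#    therefore 0, 1 or 2 and the observed total copy number ranges 0..4.
#  * internal: within a region of fixed total ploidy p (1..4) the individual
#    is treated as a p-ploid organism whose haplotype copies carry "-","0","1".
#
# States are stored as small integer codes; symbols are for display/IO only.

.NONINT_SYMBOLS <- c("-", "0", "1", "00", "01", "11")
.NONINT_COPIES  <- c(0L, 1L, 1L, 2L, 2L, 2L)
.NONINT_ONES    <- c(0L, 0L, 1L, 0L, 1L, 2L)

.INT_SYMBOLS <- c("-", "0", "1")
.INT_COPIES  <- c(0L, 1L, 1L)
.INT_ONES    <- c(0L, 0L, 1L)

state_symbols <- function(mode) {
  if (mode == "noninternal") .NONINT_SYMBOLS else .INT_SYMBOLS
}
state_copies <- function(mode) {
  if (mode == "noninternal") .NONINT_COPIES else .INT_COPIES
}
state_ones <- function(mode) {
  if (mode == "noninternal") .NONINT_ONES else .INT_ONES
}

.check_mode <- function(mode) {
  match.arg(mode, c("noninternal", "internal"))
}

#' Construct a CNV/SNP genotype set
#'
#' A genotype set holds, for `T` individuals at `L` diallelic loci, the
#' observed integer total copy number (0--4) and the count of allele 1 at
#' each locus.  Per-chromosome copy number is restricted to 0, 1 or 2 (a
#' single deletion or a single amplification per chromosome), so the total
#' never exceeds 4.
#'
#' @param cn integer matrix `T x L` of total copy numbers in `0:4`.
#' @param ones integer matrix `T x L` of allele-1 counts, `0 <= ones <= cn`.
#' @param ids optional character vector of individual labels.
#' @return An object of class `cnv_geno` with elements `cn`, `ones`, `ids`.
#' @export
new_genotypes <- function(cn, ones, ids = NULL) {
  cn <- as.matrix(cn); ones <- as.matrix(ones)
  storage.mode(cn) <- "integer"; storage.mode(ones) <- "integer"
  if (!all(dim(cn) == dim(ones)))
    stop("cn and ones must have identical dimensions")
  bad <- which(is.na(cn) | is.na(ones) | cn < 0L | cn > 4L |
                 ones < 0L | ones > cn, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "invalid genotype at individual %d, locus %d: total_cn=%s allele1=%s",
      bad[1L, 1L], bad[1L, 2L],
      cn[bad[1L, , drop = FALSE]], ones[bad[1L, , drop = FALSE]]))
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(cn)))
  if (length(ids) != nrow(cn)) stop("ids length must equal individual count")
  structure(list(cn = cn, ones = ones, ids = as.character(ids)),
            class = "cnv_geno")
}

#' @export
print.cnv_geno <- function(x, ...) {
  cat(sprintf("CNV/SNP genotype set: %d individuals x %d loci\n",
              nrow(x$cn), ncol(x$cn)))
  cat(sprintf("total CN range: %d..%d; CNV loci (cn != 2): %d\n",
              min(x$cn), max(x$cn), sum(colSums(x$cn != 2L) > 0L)))
  invisible(x)
}

n_individuals <- function(g) nrow(g$cn)
n_loci <- function(g) ncol(g$cn)

#' Subset a genotype set
#'
#' @param x a `cnv_geno` object.
#' @param i individual indices.
#' @param j locus indices (1-based columns).
#' @param ... unused.
#' @export
`[.cnv_geno` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$cn))
  if (missing(j)) j <- seq_len(ncol(x$cn))
  new_genotypes(x$cn[i, j, drop = FALSE], x$ones[i, j, drop = FALSE],
                x$ids[i])
}

#' Enumerate site states compatible with one observation
#'
#' Lists every unordered combination of per-chromosome site states whose
#' summed copy numbers equal `total_cn` and summed allele-1 copies equal
#' `allele1`.  In non-internal mode combinations are pairs over
#' `{-,0,1,00,01,11}`; in internal mode the per-locus allele multiset of the
#' `p = total_cn` copies over `{0,1}` is fully determined by the counts, so a
#' single multiset is returned.
#'
#' @param total_cn integer total copy number in `0:4`.
#' @param allele1 integer allele-1 count, `0 <= allele1 <= total_cn`.
#' @param mode `"noninternal"` or `"internal"`.
#' @param diploid_at_cn2 when `TRUE` (default) a total copy number of 2 is
#'   taken as two single-copy chromosomes, excluding the masked
#'   deletion-plus-duplication states such as `(-,01)`.
#' @param codes return integer state codes instead of symbols.
#' @return A list of unordered state tuples (character vectors of symbols, or
#'   integer code vectors when `codes = TRUE`), deterministically ordered.
#' @export
enumerate_site_states <- function(total_cn, allele1, mode = "noninternal",
                                  diploid_at_cn2 = TRUE, codes = FALSE) {
  mode <- .check_mode(mode)
  if (length(total_cn) != 1L || length(allele1) != 1L ||
      is.na(total_cn) || is.na(allele1) ||
      total_cn < 0L || total_cn > 4L || allele1 < 0L || allele1 > total_cn)
    stop(sprintf("invalid site observation: total_cn=%s allele1=%s",
                 total_cn, allele1))
  out <- if (mode == "noninternal") {
    cp <- .NONINT_COPIES; on <- .NONINT_ONES
    res <- list()
    for (a in 1:6) for (b in a:6) {
      if (cp[a] + cp[b] == total_cn && on[a] + on[b] == allele1) {
        if (diploid_at_cn2 && total_cn == 2L && (a == 1L || b == 1L)) next
        res[[length(res) + 1L]] <- c(a, b)
      }
    }
    res
  } else {
    # copies are forced: `allele1` copies of "1", the rest "0"
    if (total_cn == 0L) list(1L) else
      list(sort(c(rep(2L, total_cn - allele1), rep(3L, allele1))))
  }
  if (codes) out else lapply(out, function(v) state_symbols(mode)[v])
}

.hap_key <- function(states) paste(states, collapse = "")

.assignment_key <- function(mat) {
  paste(apply(mat, 1L, paste, collapse = ""), collapse = "|")
}

.canonical_assignment <- function(mat) {
  keys <- apply(mat, 1L, paste, collapse = "")
  mat[order(keys), , drop = FALSE]
}

#' Enumerate haplotype assignments compatible with a genotype
#'
#' Produces the complete duplicate-free list of unordered haplotype
#' assignments consistent with every site of one individual's genotype over a
#' short block of loci.  In non-internal mode an assignment is an unordered
#' pair of chromosome-level haplotypes; in internal mode it is an unordered
#' multiset of `p` haplotype copies, where `p` is the (constant) total copy
#' number across the block.
#'
#' @param cn integer vector of total copy numbers over the block.
#' @param ones integer vector of allele-1 counts over the block.
#' @param mode `"noninternal"` or `"internal"`.
#' @param diploid_at_cn2 see [enumerate_site_states()].
#' @param max_block combinatorial guard on the block length (default 5).
#' @return A list of integer matrices (one haplotype per row, state codes),
#'   rows canonically sorted within each assignment and assignments sorted
#'   lexicographically; each carries the mode as an attribute.
#' @export
enumerate_assignments <- function(cn, ones, mode = "noninternal",
                                  diploid_at_cn2 = TRUE, max_block = 5L) {
  mode <- .check_mode(mode)
  L <- length(cn)
  if (length(ones) != L) stop("cn and ones must have equal length")
  if (L > max_block)
    stop(sprintf("block of %d loci exceeds the maximum of %d; use partition-ligation",
                 L, max_block))
  if (L == 0L) stop("empty block")
  if (mode == "noninternal") {
    opts <- vector("list", L)
    for (i in seq_len(L)) {
      pairs <- enumerate_site_states(cn[i], ones[i], mode,
                                     diploid_at_cn2, codes = TRUE)
      if (length(pairs) == 0L)
        stop(sprintf("no site state compatible with locus %d (%d:%d)",
                     i, cn[i], ones[i]))
      o <- list()
      for (pr in pairs) {
        o[[length(o) + 1L]] <- pr
        if (pr[1L] != pr[2L]) o[[length(o) + 1L]] <- pr[2:1]
      }
      opts[[i]] <- o
    }
    combos <- .cartesian_index(lengths(opts))
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- list(); keys <- character(0)
    for (r in seq_len(nrow(combos))) {
      h1 <- integer(L); h2 <- integer(L)
      for (i in seq_len(L)) {
        pr <- opts[[i]][[combos[r, i]]]
        h1[i] <- pr[1L]; h2[i] <- pr[2L]
      }
      mat <- .canonical_assignment(rbind(h1, h2))
      key <- .assignment_key(mat)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        dimnames(mat) <- NULL
        attr(mat, "mode") <- mode
        out[[length(out) + 1L]] <- mat
        keys <- c(keys, key)
      }
    }
  } else {
    p <- unique(cn)
    if (length(p) != 1L)
      stop("internal mode requires a constant total copy number across the block; split at CN breakpoints or use non-internal mode")
    if (p == 0L) stop("internal phasing of a fully deleted region is empty")
    opts <- vector("list", L)
    for (i in seq_len(L)) {
      k <- ones[i]
      if (k > p) stop(sprintf("allele1 count %d exceeds ploidy %d at locus %d",
                              k, p, i))
      sets <- if (k == 0L) list(integer(0)) else
        lapply(seq_len(ncol(utils::combn(p, k))),
               function(j) utils::combn(p, k)[, j])
      opts[[i]] <- sets
    }
    combos <- .cartesian_index(lengths(opts))
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- list(); keys <- character(0)
    for (r in seq_len(nrow(combos))) {
      mat <- matrix(2L, nrow = p, ncol = L)  # code 2 = "0"
      for (i in seq_len(L)) {
        carriers <- opts[[i]][[combos[r, i]]]
        if (length(carriers)) mat[carriers, i] <- 3L  # code 3 = "1"
      }
      mat <- .canonical_assignment(mat)
      key <- .assignment_key(mat)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        dimnames(mat) <- NULL
        attr(mat, "mode") <- mode
        out[[length(out) + 1L]] <- mat
        keys <- c(keys, key)
      }
    }
  }
  out[order(keys)]
}

# all index combinations over option counts, one row per combination
.cartesian_index <- function(ns) {
  stopifnot(all(ns >= 1L))
  n <- prod(ns)
  m <- matrix(1L, nrow = n, ncol = length(ns))
  rep_each <- 1L
  for (i in seq_along(ns)) {
    m[, i] <- rep(rep(seq_len(ns[i]), each = rep_each), length.out = n)
    rep_each <- rep_each * ns[i]
  }
  m
}

#' Check that an assignment is consistent with a genotype
#'
#' @param assignment integer state-code matrix, one haplotype per row.
#' @param cn,ones the genotype over the same loci.
#' @param mode phasing mode of the assignment.
#' @return `TRUE` iff at every locus the summed per-chromosome copy numbers
#'   equal `cn` and the summed allele-1 copies equal `ones`.
#' @export
is_consistent <- function(assignment, cn, ones, mode = "noninternal") {
  mode <- .check_mode(mode)
  if (ncol(assignment) != length(cn))
    stop(sprintf("assignment covers %d loci but genotype has %d",
                 ncol(assignment), length(cn)))
  cp <- state_copies(mode); on <- state_ones(mode)
  all(colSums(matrix(cp[assignment], nrow = nrow(assignment))) == cn) &&
    all(colSums(matrix(on[assignment], nrow = nrow(assignment))) == ones)
}

#' Build the haplotype universe of a block
#'
#' The universe Z is the deduplicated, first-seen-ordered union of all
#' haplotypes occurring in any individual's compatible assignment list.
#'
#' @param assignment_lists list (one element per individual) of assignment
#'   lists as returned by [enumerate_assignments()].
#' @return An object of class `hap_universe`: `haps` (list of state-code
#'   vectors), `keys`, `index` (environment mapping key to position), `mode`.
#' @export
build_universe <- function(assignment_lists) {
  modes <- unique(unlist(lapply(assignment_lists, function(al)
    vapply(al, function(a) attr(a, "mode"), character(1)))))
  if (length(modes) > 1L) stop("assignments mix phasing modes")
  index <- new.env(hash = TRUE, parent = emptyenv())
  haps <- list(); keys <- character(0)
  for (al in assignment_lists) for (a in al) {
    for (r in seq_len(nrow(a))) {
      key <- paste(a[r, ], collapse = "")
      if (is.null(index[[key]])) {
        haps[[length(haps) + 1L]] <- a[r, ]
        keys <- c(keys, key)
        index[[key]] <- length(haps)
      }
    }
  }
  structure(list(haps = haps, keys = keys, index = index,
                 mode = if (length(modes)) modes else "noninternal"),
            class = "hap_universe")
}

#' @export
print.hap_universe <- function(x, ...) {
  cat(sprintf("haplotype universe: M = %d (%s mode)\n",
              length(x$haps), x$mode))
  invisible(x)
}

universe_size <- function(u) length(u$haps)

universe_lookup <- function(u, hap) {
  idx <- u$index[[paste(hap, collapse = "")]]
  if (is.null(idx)) stop("haplotype missing from universe; build it first")
  idx
}

#' Per-locus ploidy profile and fixed region ploidy
#'
#' @param cn integer vector of total copy numbers for one individual.
#' @return `ploidy_profile` returns `cn` unchanged (the per-locus total
#'   ploidy); `region_ploidy` returns the common total copy number over the
#'   0-based half-open interval `[start, end)` or `NA_integer_` when it
#'   varies.
#' @export
ploidy_profile <- function(cn) as.integer(cn)

#' @rdname ploidy_profile
#' @param start,end 0-based half-open locus interval.
#' @export
region_ploidy <- function(cn, start = 0L, end = length(cn)) {
  if (start < 0L || end > length(cn) || start >= end)
    stop("invalid region [", start, ", ", end, ")")
  v <- unique(cn[(start + 1L):end])
  if (length(v) == 1L) as.integer(v) else NA_integer_
}

#' Render a haplotype or assignment as display symbols
#'
#' @param x integer state-code vector or matrix.
#' @param mode phasing mode.
#' @return character vector/matrix of symbols from the mode's alphabet.
#' @export
format_states <- function(x, mode = "noninternal") {
  mode <- .check_mode(mode)
  sym <- state_symbols(mode)
  if (is.matrix(x)) matrix(sym[x], nrow = nrow(x)) else sym[x]
}

# parse display symbols back to codes
parse_states <- function(sym, mode = "noninternal") {
  mode <- .check_mode(mode)
  codes <- match(sym, state_symbols(mode))
  if (anyNA(codes))
    stop("unknown state symbol: ", sym[which(is.na(codes))[1L]])
  as.integer(codes)
}
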