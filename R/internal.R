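# Internal phasing: resolving the two haplotype copies inside duplicated
# chromosome regions.
#
# Non-internal phasing fixes, per chromosome and locus, the unordered allele
# content ("00", "01", "11") of a duplication.  What remains is to string the
# two copies together along the region: a two-haplotype phasing problem over
# the internally heterozygous ("01") positions, identical in structure to
# diploid SNP phasing.  Duplicated runs are therefore extracted per
# chromosome, grouped by their locus interval across individuals (so the
# population information is shared), and each group is phased with the same
# sampler; copy-number breakpoints are never crossed.

# maximal runs of duplicated states (per-chromosome CN 2) in one chromosome
# row; returns 0-based half-open intervals
.duplicated_runs <- function(states) {
  dup <- .NONINT_COPIES[states] == 2L
  r <- rle(dup)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Phase the copies within duplicated regions
#'
#' Extracts every maximal duplicated run from the chromosomes of a
#' non-internal phasing (or of the truth), groups runs covering the same
#' locus interval across individuals, and phases each group as a diploid
#' SNP problem over the duplication's two copies.
#'
#' @param phasing a `cnv_phasing`, `cnv_truth`, or bare list of 2-row
#'   non-internal assignment matrices.
#' @param K,epsilon,block_size,max_candidates sampler settings, as in
#'   [hierarchical_phase()].
#' @return List of records, each with `ind`, `chrom`, `start`, `end`
#'   (0-based half-open) and `copies`, a `2 x len` 0/1 allele matrix.
#' @export
phase_internal <- function(phasing, K = 50L, epsilon = 1, block_size = 5L,
                           max_candidates = 256L) {
  assign_list <- .as_assignment_list(phasing)
  segs <- list()
  for (t in seq_along(assign_list)) {
    mat <- assign_list[[t]]
    for (r in 1:2) {
      runs <- .duplicated_runs(mat[r, ])
      for (q in seq_len(nrow(runs))) {
        s <- runs[q, 1L]; e <- runs[q, 2L]
        segs[[length(segs) + 1L]] <-
          list(ind = t, chrom = r, start = s, end = e,
               ones = .NONINT_ONES[mat[r, (s + 1L):e]])
      }
    }
  }
  if (length(segs) == 0L) return(list())
  keys <- vapply(segs, function(s) paste(s$start, s$end, sep = ":"),
                 character(1))
  out <- list()
  for (key in unique(keys)) {
    grp <- segs[keys == key]
    len <- grp[[1L]]$end - grp[[1L]]$start
    cn <- matrix(2L, nrow = length(grp), ncol = len)
    ones <- do.call(rbind, lapply(grp, `[[`, "ones"))
    g <- new_genotypes(cn, ones)
    ph <- hierarchical_phase(g, mode = "noninternal", K = K,
                             epsilon = epsilon, block_size = block_size,
                             max_candidates = max_candidates)
    for (i in seq_along(grp)) {
      copies <- matrix(.NONINT_ONES[ph$assignments[[i]]], nrow = 2L)
      out[[length(out) + 1L]] <-
        list(ind = grp[[i]]$ind, chrom = grp[[i]]$chrom,
             start = grp[[i]]$start, end = grp[[i]]$end, copies = copies)
    }
  }
  out
}

#' Switch error rate of internal phasing
#'
#' Matches predicted duplicated-region records to truth records by individual
#' and locus interval (requiring identical per-locus copy multisets, i.e.
#' agreement on the unordered content) and scores, within each matched
#' region, the minimal orientation switches over internally heterozygous
#' positions, exactly as SNP-only switch error.
#'
#' @param truth list of truth records (e.g. `cnv_truth$internal`).
#' @param predicted list of predicted records from [phase_internal()].
#' @return list with `rate`, `switches`, `opportunities`, `matched`,
#'   `unmatched` (truth regions without a content-matched prediction).
#' @export
internal_switch_error <- function(truth, predicted) {
  pkey <- vapply(predicted, function(p)
    paste(p$ind, p$start, p$end, sep = ":"), character(1))
  used <- logical(length(predicted))
  switches <- 0L; opportunities <- 0L; matched <- 0L; unmatched <- 0L
  for (tr in truth) {
    key <- paste(tr$ind, tr$start, tr$end, sep = ":")
    hit <- 0L
    for (i in which(pkey == key & !used)) {
      pc <- predicted[[i]]$copies
      same <- all(pmin(pc[1L, ], pc[2L, ]) == pmin(tr$copies[1L, ], tr$copies[2L, ])) &&
        all(pmax(pc[1L, ], pc[2L, ]) == pmax(tr$copies[1L, ], tr$copies[2L, ]))
      if (same) { hit <- i; break }
    }
    if (hit == 0L) { unmatched <- unmatched + 1L; next }
    used[hit] <- TRUE
    matched <- matched + 1L
    pc <- predicted[[hit]]$copies
    het <- which(tr$copies[1L, ] != tr$copies[2L, ])
    if (length(het) < 2L) next
    m <- pc[1L, het] == tr$copies[1L, het]
    switches <- switches + sum(m[-1L] != m[-length(m)])
    opportunities <- opportunities + length(het) - 1L
  }
  list(rate = if (opportunities > 0L) switches / opportunities else NA_real_,
       switches = switches, opportunities = opportunities,
       matched = matched, unmatched = unmatched)
}
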