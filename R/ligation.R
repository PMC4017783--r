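# CNV-aware partition-ligation.
#
# Marker sets longer than the block limit are split into blocks of at most 5
# consecutive loci, each block is phased independently, and neighboring
# blocks are merged.  A merged candidate pairs one chromosome of the left
# solution with one chromosome of the right solution; only pairings with the
# minimal number of per-chromosome copy-number changes across the junction
# are kept (both pairings when they tie, e.g. when the boundary CNs within a
# block are equal).  Each candidate carries a ligation weight, the product of
# the two source solution weights, and the sampler is rerun over individuals
# with candidate weights offset by the log ligation weight.

#' Partition loci into blocks
#'
#' Tiles `[0, L)` with `floor(L / block_size)` full blocks plus a remainder
#' block when `L` is not a multiple of `block_size`.
#'
#' @param L locus count.
#' @param block_size maximum block length (default 5).
#' @return Integer matrix with columns `start`, `end` (0-based half-open).
#' @export
partition_loci <- function(L, block_size = 5L) {
  L <- as.integer(L); block_size <- as.integer(block_size)
  if (L < 1L) stop("L must be >= 1")
  starts <- seq(0L, L - 1L, by = block_size)
  cbind(start = starts, end = pmin(starts + block_size, L))
}

#' Copy-number changes across a block junction
#'
#' Counts the chromosomes whose per-chromosome copy number at the last locus
#' of the left block differs from that at the first locus of the right block,
#' under a given pairing of left to right chromosomes.
#'
#' @param left,right diploid (non-internal) assignment matrices.
#' @param crossed pair left row 1 with right row 2 (and 2 with 1) instead of
#'   the straight pairing.
#' @return Integer in `0:2`.
#' @export
junction_cn_changes <- function(left, right, crossed = FALSE) {
  if (!identical(attr(left, "mode") %||% "noninternal", "noninternal") ||
      !identical(attr(right, "mode") %||% "noninternal", "noninternal"))
    stop("ligation operates on non-internal (diploid) assignments")
  if (nrow(left) != 2L || nrow(right) != 2L)
    stop("ligation operates on diploid assignments")
  cp <- .NONINT_COPIES
  lc <- cp[left[, ncol(left)]]
  rc <- cp[right[, 1L]]
  if (crossed) rc <- rc[2:1]
  sum(lc != rc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# merge two diploid assignment matrices under a pairing, canonicalized
.merge_pairing <- function(left, right, crossed) {
  r <- if (crossed) right[2:1, , drop = FALSE] else right
  mat <- .canonical_assignment(cbind(left, r))
  attr(mat, "mode") <- "noninternal"
  mat
}

#' Ligate two adjacent block solutions
#'
#' For every individual and every pair of one left and one right assignment,
#' merged candidates are generated for the pairings achieving the minimal
#' number of junction copy-number changes (both pairings when tied).  The
#' sampler is then rerun over individuals with these candidates, their
#' initial weights offset by the log ligation weight (the sum of the two
#' source solutions' log weights).
#'
#' @param left,right `block_solution` objects over adjacent intervals with
#'   the same individuals.
#' @param K particle budget for the rerun (defaults to the left solution's).
#' @param epsilon Dirichlet prior pseudocount for the rerun.
#' @param max_candidates per-individual cap on merged candidates, keeping the
#'   top by ligation weight (default 256).
#' @param order processing order for the rerun.
#' @return A `block_solution` over the concatenated interval.
#' @export
ligate <- function(left, right, K = left$K, epsilon = left$epsilon,
                   max_candidates = 256L, order = NULL) {
  if (left$block[2L] != right$block[1L])
    stop(sprintf("blocks [%d,%d) and [%d,%d) are not adjacent",
                 left$block[1L], left$block[2L],
                 right$block[1L], right$block[2L]))
  if (!identical(left$ids, right$ids))
    stop("block solutions cover different individuals")
  if (left$mode != "noninternal" || right$mode != "noninternal")
    stop("ligation operates on non-internal solutions")
  Tn <- length(left$per_indiv)
  capped <- FALSE
  merged <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    ls <- left$per_indiv[[t]]; rs <- right$per_indiv[[t]]
    acc <- new.env(hash = TRUE, parent = emptyenv())
    keys <- character(0)
    for (i in seq_along(ls$mats)) for (j in seq_along(rs$mats)) {
      base <- log(ls$weight[i]) + log(rs$weight[j])
      ch0 <- junction_cn_changes(ls$mats[[i]], rs$mats[[j]], crossed = FALSE)
      ch1 <- junction_cn_changes(ls$mats[[i]], rs$mats[[j]], crossed = TRUE)
      use <- if (ch0 < ch1) FALSE else if (ch1 < ch0) TRUE else c(FALSE, TRUE)
      for (cr in use) {
        mat <- .merge_pairing(ls$mats[[i]], rs$mats[[j]], cr)
        key <- .assignment_key(mat)
        cur <- acc[[key]]
        if (is.null(cur)) {
          acc[[key]] <- list(mat = mat, lw = base)
          keys <- c(keys, key)
        } else {
          cur$lw <- logsumexp(c(cur$lw, base))
          acc[[key]] <- cur
        }
      }
    }
    lw <- vapply(keys, function(k) acc[[k]]$lw, numeric(1))
    o <- order(-lw, keys)
    if (length(o) > max_candidates) {
      o <- o[seq_len(max_candidates)]
      capped <- TRUE
    }
    merged[[t]] <- list(
      mats = lapply(keys[o], function(k) acc[[k]]$mat),
      offset = lw[o] - logsumexp(lw[o]))
  }
  if (capped)
    message(sprintf("ligation [%d,%d)+[%d,%d): candidate lists capped at %d",
                    left$block[1L], left$block[2L], right$block[1L],
                    right$block[2L], max_candidates))
  universe <- build_universe(lapply(merged, `[[`, "mats"))
  cands <- lapply(merged, function(m)
    build_candidates(m$mats, universe, offset = m$offset))
  if (is.null(order)) order <- seq_len(Tn)
  system <- run_tds(cands, universe_size(universe), K, epsilon, order)
  structure(list(block = c(left$block[1L], right$block[2L]),
                 mode = "noninternal", universe = universe, cands = cands,
                 per_indiv = aggregate_solutions(system, cands),
                 system = system, ids = left$ids, K = as.integer(K),
                 epsilon = epsilon),
            class = "block_solution")
}

#' Phase a full marker set by partition-ligation
#'
#' Partitions the loci into blocks of at most `block_size`, phases each block
#' with [phase_block()], ligates neighboring blocks (progressively
#' left-to-right by default, or pairwise in log-depth rounds), and returns
#' the hard phasing (arg-max aggregated weight per individual, ties to the
#' lexicographically smallest assignment) together with the estimated
#' haplotype frequencies over the final universe.
#'
#' @inheritParams phase_block
#' @param block_size maximum block length (default 5).
#' @param max_candidates per-individual merged-candidate cap at ligation.
#' @param ligation_order `"progressive"` (default) or `"pairwise"`.
#' @param shuffle_seed optional integer; when given, individuals are
#'   processed in a seeded random order instead of input order.
#' @return An object of class `cnv_phasing`: `assignments` (one canonical
#'   2-row state matrix per individual), `frequencies` (named over haplotype
#'   keys), and the final `block_solution` in `$solution`.
#' @export
hierarchical_phase <- function(geno, mode = "noninternal", K = 50L,
                               epsilon = 1, block_size = 5L,
                               diploid_at_cn2 = TRUE, max_candidates = 256L,
                               ligation_order = c("progressive", "pairwise"),
                               shuffle_seed = NULL) {
  mode <- .check_mode(mode)
  ligation_order <- match.arg(ligation_order)
  L <- n_loci(geno); Tn <- n_individuals(geno)
  order <- seq_len(Tn)
  if (!is.null(shuffle_seed)) {
    order <- withr_seed_sample(Tn, shuffle_seed)
  }
  if (mode == "internal" && L > block_size)
    stop("internal mode is phased per fixed-ploidy region (<= block_size loci); see phase_internal()")
  blocks <- partition_loci(L, block_size)
  sols <- lapply(seq_len(nrow(blocks)), function(b) {
    cols <- (blocks[b, 1L] + 1L):blocks[b, 2L]
    phase_block(geno[, cols], mode = mode, K = K, epsilon = epsilon,
                diploid_at_cn2 = diploid_at_cn2, max_block = block_size,
                order = order, block = blocks[b, ])
  })
  final <- if (length(sols) == 1L) {
    sols[[1L]]
  } else if (ligation_order == "progressive") {
    Reduce(function(a, b) ligate(a, b, K = K, epsilon = epsilon,
                                 max_candidates = max_candidates,
                                 order = order),
           sols)
  } else {
    while (length(sols) > 1L) {
      nxt <- list()
      i <- 1L
      while (i <= length(sols)) {
        if (i + 1L <= length(sols)) {
          nxt[[length(nxt) + 1L]] <-
            ligate(sols[[i]], sols[[i + 1L]], K = K, epsilon = epsilon,
                   max_candidates = max_candidates, order = order)
        } else nxt[[length(nxt) + 1L]] <- sols[[i]]
        i <- i + 2L
      }
      sols <- nxt
    }
    sols[[1L]]
  }
  assignments <- lapply(final$per_indiv, function(s) s$mats[[1L]])
  for (t in seq_len(Tn)) {
    if (!is_consistent(assignments[[t]], geno$cn[t, ], geno$ones[t, ], mode))
      stop("internal error: final assignment inconsistent for individual ", t)
  }
  structure(list(assignments = assignments,
                 frequencies = estimate_frequencies(final),
                 solution = final, mode = mode, K = as.integer(K),
                 epsilon = epsilon, block_size = as.integer(block_size),
                 ids = geno$ids, order = order),
            class = "cnv_phasing")
}

# seeded permutation that does not disturb the caller's RNG state
withr_seed_sample <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n)
}

#' @export
print.cnv_phasing <- function(x, ...) {
  cat(sprintf("phasing of %d individuals (%s mode, K = %d, block = %d)\n",
              length(x$assignments), x$mode, x$K, x$block_size))
  cat(sprintf("final universe: %d haplotypes\n",
              length(x$frequencies)))
  invisible(x)
}
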