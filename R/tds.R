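# Tree-based deterministic sequential Monte Carlo sampler.
#
# K solution streams ("particles") are maintained.  Each particle carries the
# assignment history of all processed individuals, the Dirichlet sufficient
# statistics rho implied by that history, and a raw log weight.  Processing
# individual t expands every particle with every assignment compatible with
# c_t, weighting children by the Dirichlet-multinomial predictive
# B(rho + r)/B(rho) (times the multiset-ordering multiplicity, so that the
# posterior is a proper distribution over unordered assignments), and then
# deterministically retains the K highest-weight children.  No resampling
# noise: ties break by (parent index, candidate enumeration index).

# Pack an assignment list into the flat arrays used by the expansion loop.
build_candidates <- function(assignments, universe, offset = NULL) {
  n <- length(assignments)
  if (n == 0L) stop("empty candidate list: genotype inconsistent upstream")
  keys <- character(n); log_mult <- numeric(n)
  idx_flat <- integer(0); cnt_flat <- integer(0); grp <- integer(0)
  p <- nrow(assignments[[1L]])
  for (i in seq_len(n)) {
    a <- assignments[[i]]
    keys[i] <- .assignment_key(a)
    ids <- vapply(seq_len(nrow(a)),
                  function(r) universe_lookup(universe, a[r, ]), integer(1))
    tab <- table(ids)
    idx <- as.integer(names(tab)); cnt <- as.integer(tab)
    idx_flat <- c(idx_flat, idx)
    cnt_flat <- c(cnt_flat, cnt)
    grp <- c(grp, rep.int(i, length(idx)))
    log_mult[i] <- log_orderings(cnt)
  }
  if (is.null(offset)) offset <- numeric(n)
  list(keys = keys, mats = assignments, idx_flat = idx_flat,
       cnt_flat = cnt_flat, grp = grp, p = p, log_mult = log_mult,
       offset = offset, n = n)
}

new_particle_system <- function(M, K, epsilon) {
  list(rho = matrix(dm_prior(M, epsilon), nrow = M, ncol = 1L),
       logw = 0, hist = matrix(integer(0), nrow = 0L, ncol = 1L),
       K = as.integer(K), epsilon = epsilon, M = as.integer(M))
}

#' Expand a particle system with one individual's candidates
#'
#' Every current particle is paired with every compatible assignment of the
#' next individual; each child's log weight is the parent weight plus the
#' Dirichlet-multinomial log predictive of the candidate's count vector under
#' the parent's sufficient statistics (plus the candidate's ordering
#' multiplicity and any externally supplied offset, e.g. a ligation weight).
#'
#' @param system a particle system as used by [phase_block()].
#' @param cand a packed candidate set from `build_candidates`.
#' @return list with the child log-weight matrix and parent/candidate ids.
#' @keywords internal
tds_expand <- function(system, cand) {
  k <- ncol(system$rho)
  lw <- matrix(0, nrow = k, ncol = cand$n)
  for (j in seq_len(k)) {
    rho <- system$rho[, j]
    S <- sum(rho)
    contrib <- lgamma(rho[cand$idx_flat] + cand$cnt_flat) -
      lgamma(rho[cand$idx_flat])
    num <- rowsum(contrib, cand$grp)[, 1L]
    lw[j, ] <- system$logw[j] + num -
      (lgamma(S + cand$p) - lgamma(S)) + cand$log_mult + cand$offset
  }
  list(logw = as.vector(t(lw)),
       parent = rep(seq_len(k), each = cand$n),
       cand_id = rep.int(seq_len(cand$n), k))
}

#' Deterministic top-K selection
#'
#' Retains the K highest-log-weight children (all, if fewer), breaking ties
#' by parent index then candidate enumeration index, and rebuilds the
#' particle state (sufficient statistics, histories).
#'
#' @keywords internal
tds_select <- function(system, children, cand) {
  K <- system$K
  ord <- order(-children$logw, children$parent, children$cand_id)
  keep <- ord[seq_len(min(K, length(ord)))]
  parents <- children$parent[keep]
  cids <- children$cand_id[keep]
  M <- system$M
  rho_new <- system$rho[, parents, drop = FALSE]
  for (s in seq_along(keep)) {
    sel <- cand$grp == cids[s]
    idx <- cand$idx_flat[sel]
    rho_new[idx, s] <- rho_new[idx, s] + cand$cnt_flat[sel]
  }
  hist_new <- rbind(system$hist[, parents, drop = FALSE],
                    matrix(cids, nrow = 1L))
  system$rho <- rho_new
  system$logw <- children$logw[keep]
  system$hist <- hist_new
  system
}

run_tds <- function(cands, M, K = 50L, epsilon = 1,
                    order = seq_along(cands)) {
  system <- new_particle_system(M, K, epsilon)
  for (t in order) {
    children <- tds_expand(system, cands[[t]])
    system <- tds_select(system, children, cands[[t]])
  }
  # hist rows are in processing order; remap to original individual order
  remap <- match(seq_along(cands), order)
  system$hist <- system$hist[remap, , drop = FALSE]
  system$order <- order
  system
}

#' Aggregate a particle system into per-individual solutions
#'
#' Normalizes particle weights and, for each individual, sums them over the
#' distinct assignments occurring across particles.
#'
#' @param system a processed particle system.
#' @param cands the per-individual packed candidate sets.
#' @return list, one element per individual, each with `keys`, `weight`
#'   (normalized, summing to 1), and `mats` (the assignment matrices).
#' @keywords internal
aggregate_solutions <- function(system, cands) {
  w <- exp(system$logw - logsumexp(system$logw))
  lapply(seq_len(nrow(system$hist)), function(t) {
    cid <- system$hist[t, ]
    ws <- tapply(w, cid, sum)
    ids <- as.integer(names(ws))
    o <- order(-ws, ids)
    list(keys = cands[[t]]$keys[ids[o]],
         weight = as.numeric(ws[o]),
         mats = cands[[t]]$mats[ids[o]])
  })
}

#' Phase one block of loci with the deterministic SMC sampler
#'
#' Enumerates the compatible assignments of every individual over the block,
#' builds the haplotype universe, and runs the expand/select recursion over
#' individuals, returning the aggregated per-individual solution weights.
#'
#' @param geno a `cnv_geno` genotype set restricted to the block.
#' @param mode `"noninternal"` (diploid chromosome-level states) or
#'   `"internal"` (fixed-ploidy copies; requires constant total CN).
#' @param K particle budget (default 50).
#' @param epsilon Dirichlet prior pseudocount (default 1).
#' @param diploid_at_cn2 see [enumerate_site_states()].
#' @param max_block combinatorial guard on block length (default 5).
#' @param order processing order of individuals (default input order).
#' @param block 0-based half-open locus interval the genotypes represent,
#'   recorded in the result (default `c(0, L)`).
#' @return An object of class `block_solution`: per-individual weighted
#'   assignment lists, the haplotype universe, and the final particle system.
#' @export
phase_block <- function(geno, mode = "noninternal", K = 50L, epsilon = 1,
                        diploid_at_cn2 = TRUE, max_block = 5L,
                        order = NULL, block = NULL) {
  mode <- .check_mode(mode)
  Tn <- n_individuals(geno); L <- n_loci(geno)
  if (is.null(block)) block <- c(0L, L)
  if (is.null(order)) order <- seq_len(Tn)
  assignment_lists <- lapply(seq_len(Tn), function(t)
    enumerate_assignments(geno$cn[t, ], geno$ones[t, ], mode,
                          diploid_at_cn2, max_block))
  universe <- build_universe(assignment_lists)
  cands <- lapply(assignment_lists, build_candidates, universe = universe)
  system <- run_tds(cands, universe_size(universe), K, epsilon, order)
  structure(list(block = as.integer(block), mode = mode,
                 universe = universe, cands = cands,
                 per_indiv = aggregate_solutions(system, cands),
                 system = system, ids = geno$ids, K = as.integer(K),
                 epsilon = epsilon),
            class = "block_solution")
}

#' @export
print.block_solution <- function(x, ...) {
  cat(sprintf("block solution [%d, %d), %s mode: %d individuals, M = %d, K = %d\n",
              x$block[1L], x$block[2L], x$mode, length(x$per_indiv),
              universe_size(x$universe), x$K))
  invisible(x)
}

#' Estimate population haplotype frequencies from a phased solution
#'
#' Takes the highest-weight particle's Dirichlet sufficient statistics and
#' normalizes them into frequencies, by default after subtracting the prior
#' pseudocounts so that the estimate is the empirical haplotype frequency of
#' the best solution stream.
#'
#' @param solution a `block_solution` (or the result of
#'   [hierarchical_phase()], whose final solution is used).
#' @param subtract_prior subtract the prior pseudocount before normalizing
#'   (default `TRUE`).
#' @param average average the per-particle estimates, weighted by normalized
#'   particle weight, instead of using only the top particle.
#' @return Named numeric vector over the universe's haplotype keys, summing
#'   to 1.
#' @export
estimate_frequencies <- function(solution, subtract_prior = TRUE,
                                 average = FALSE) {
  if (inherits(solution, "cnv_phasing")) solution <- solution$solution
  system <- solution$system
  freq_of <- function(rho) {
    v <- if (subtract_prior) pmax(rho - solution$epsilon, 0) else rho
    if (sum(v) == 0) v <- rho
    v / sum(v)
  }
  if (average) {
    w <- exp(system$logw - logsumexp(system$logw))
    fm <- vapply(seq_len(ncol(system$rho)),
                 function(j) freq_of(system$rho[, j]),
                 numeric(nrow(system$rho)))
    f <- as.numeric(matrix(fm, nrow = nrow(system$rho)) %*% w)
  } else {
    top <- order(-system$logw)[1L]
    f <- freq_of(system$rho[, top])
  }
  names(f) <- solution$universe$keys
  f
}
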