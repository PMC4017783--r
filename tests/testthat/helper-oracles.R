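# Independent oracles used to freeze expected values: brute-force
# enumeration over the full state space and exhaustive posterior enumeration
# via the closed-form Dirichlet-multinomial marginal.  These deliberately do
# not share code with the package internals they check.

NONINT_CP <- c(0L, 1L, 1L, 2L, 2L, 2L)
NONINT_ON <- c(0L, 0L, 1L, 0L, 1L, 2L)

# all unordered site-state pairs by filtering the full 6x6 space
brute_site_states <- function(total_cn, allele1, diploid_at_cn2 = TRUE) {
  out <- list()
  for (a in 1:6) for (b in 1:6) {
    if (a > b) next
    if (NONINT_CP[a] + NONINT_CP[b] != total_cn) next
    if (NONINT_ON[a] + NONINT_ON[b] != allele1) next
    if (diploid_at_cn2 && total_cn == 2L && (a == 1L || b == 1L)) next
    out[[length(out) + 1L]] <- c(a, b)
  }
  out
}

# all unordered diploid assignments by filtering ALL ordered pairs of ALL
# possible state strings (6^L x 6^L); feasible for L <= 3
brute_assignments_nonint <- function(cn, ones, diploid_at_cn2 = TRUE) {
  L <- length(cn)
  haps <- as.matrix(expand.grid(rep(list(1:6), L)))
  keep <- list()
  seen <- character(0)
  for (i in seq_len(nrow(haps))) for (j in seq_len(nrow(haps))) {
    h1 <- haps[i, ]; h2 <- haps[j, ]
    if (any(NONINT_CP[h1] + NONINT_CP[h2] != cn)) next
    if (any(NONINT_ON[h1] + NONINT_ON[h2] != ones)) next
    if (diploid_at_cn2 &&
        any(cn == 2L & (h1 == 1L | h2 == 1L))) next
    mat <- rbind(h1, h2)
    k <- apply(mat, 1L, paste, collapse = "")
    mat <- mat[order(k), , drop = FALSE]
    key <- paste(apply(mat, 1L, paste, collapse = ""), collapse = "|")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      dimnames(mat) <- NULL
      keep[[length(keep) + 1L]] <- mat
    }
  }
  keep[order(seen)]
}

# all unordered internal assignments: every ordered p-tuple of binary
# haplotypes, filtered by per-locus allele-1 sums, deduplicated as multisets
brute_assignments_int <- function(cn, ones) {
  p <- unique(cn)
  stopifnot(length(p) == 1L, p >= 1L)
  L <- length(cn)
  haps <- as.matrix(expand.grid(rep(list(2:3), L)))  # codes 2="0", 3="1"
  nh <- nrow(haps)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(nh)), p)))
  keep <- list(); seen <- character(0)
  for (r in seq_len(nrow(tuples))) {
    mat <- haps[tuples[r, ], , drop = FALSE]
    if (any(colSums(mat == 3L) != ones)) next
    k <- apply(mat, 1L, paste, collapse = "")
    mat <- mat[order(k), , drop = FALSE]
    key <- paste(apply(mat, 1L, paste, collapse = ""), collapse = "|")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      dimnames(mat) <- NULL
      keep[[length(keep) + 1L]] <- mat
    }
  }
  keep[order(seen)]
}

# random valid genotype vectors (every (cn, ones) with 0<=ones<=cn<=4 admits
# at least one state pair)
random_genotype <- function(L) {
  cn <- sample(0:4, L, replace = TRUE)
  ones <- vapply(cn, function(c) if (c == 0L) 0L else sample(0:c, 1L),
                 integer(1))
  list(cn = as.integer(cn), ones = as.integer(ones))
}

# exhaustive posterior over joint assignment histories for a tiny dataset.
# log p(H) = sum_t log(#orderings of h_t) + log B(eps + n) - log B(eps)
# with n the total haplotype counts of the history (telescoped B ratios).
exact_posterior <- function(geno, epsilon = 1, diploid_at_cn2 = TRUE) {
  Tn <- nrow(geno$cn)
  alists <- lapply(seq_len(Tn), function(t)
    smcphase::enumerate_assignments(geno$cn[t, ], geno$ones[t, ],
                                    diploid_at_cn2 = diploid_at_cn2))
  universe <- smcphase::build_universe(alists)
  M <- length(universe$haps)
  rlists <- lapply(alists, function(al)
    lapply(al, smcphase::dm_count_vector, universe = universe))
  combos <- as.matrix(expand.grid(lapply(rlists, seq_along)))
  logp <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    n <- rep(0L, M); lmult <- 0
    for (t in seq_len(Tn)) {
      r <- rlists[[t]][[combos[i, t]]]
      n <- n + r
      nz <- r[r > 0]
      lmult <- lmult + lgamma(sum(nz) + 1) - sum(lgamma(nz + 1))
    }
    logp[i] <- lmult + sum(lgamma(epsilon + n) - lgamma(epsilon)) -
      (lgamma(M * epsilon + sum(n)) - lgamma(M * epsilon))
  }
  w <- exp(logp - max(logp)); w <- w / sum(w)
  marginals <- lapply(seq_len(Tn), function(t) {
    m <- tapply(w, combos[, t], sum)
    v <- numeric(length(rlists[[t]])); v[as.integer(names(m))] <- m
    v
  })
  # frequency estimate of the top history: empirical counts of its
  # assignments over the universe
  top <- which.max(logp)
  n <- rep(0L, M)
  for (t in seq_len(Tn)) n <- n + rlists[[t]][[combos[top, t]]]
  list(marginals = marginals, alists = alists, universe = universe,
       top_freq = n / sum(n), histories = nrow(combos))
}

# sample from Dirichlet(rho) via normalized gammas
rdirichlet <- function(n, rho) {
  x <- matrix(stats::rgamma(n * length(rho), shape = rho), ncol = length(rho),
              byrow = TRUE)
  x / rowSums(x)
}

# build a cnv_geno from plain matrices without exporting internals
make_geno <- function(cn, ones) smcphase::new_genotypes(cn, ones)

# assignment matrix from symbol rows, e.g. sym_mat(c("0","01"), c("1","00"))
sym_mat <- function(...) {
  rows <- list(...)
  mat <- do.call(rbind, lapply(rows, function(r)
    match(r, c("-", "0", "1", "00", "01", "11"))))
  dimnames(mat) <- NULL
  storage.mode(mat) <- "integer"
  attr(mat, "mode") <- "noninternal"
  mat
}
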