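# Dirichlet prior / posterior over population haplotype frequencies and the
# Dirichlet-multinomial posterior predictive used to weight particles.
#
# With theta ~ Dirichlet(rho) and an assignment contributing counts r over
# the universe, the marginal probability of the (ordered) draw sequence is
# B(rho + r) / B(rho), where B(a) = prod(Gamma(a_i)) / Gamma(sum(a_i)).
# Everything is carried in natural-log space via lgamma: the B ratios
# underflow after a few tens of individuals otherwise.

#' Initialize Dirichlet sufficient statistics
#'
#' @param M universe size (number of candidate haplotypes).
#' @param epsilon positive prior pseudocount placed on every haplotype
#'   (default 1, the uniform Dirichlet).
#' @return Numeric vector of length `M`, all entries `epsilon`.
#' @export
dm_prior <- function(M, epsilon = 1) {
  if (M < 1L) stop("empty universe: M must be >= 1")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  rep(as.numeric(epsilon), M)
}

#' Haplotype count vector of an assignment
#'
#' @param assignment state-code matrix, one haplotype per row.
#' @param universe a `hap_universe` containing every row of `assignment`.
#' @return Integer vector `r` of length `M` with `r[m]` the number of copies
#'   of universe haplotype `m` in the assignment; `sum(r) == nrow(assignment)`.
#' @export
dm_count_vector <- function(assignment, universe) {
  r <- integer(universe_size(universe))
  for (i in seq_len(nrow(assignment))) {
    m <- universe_lookup(universe, assignment[i, ])
    r[m] <- r[m] + 1L
  }
  r
}

#' Conjugate posterior update
#'
#' @param rho sufficient statistics (positive numeric vector).
#' @param r count vector of the newly accepted assignment.
#' @return `rho + r` (inputs are not modified).
#' @export
dm_update <- function(rho, r) {
  if (length(rho) != length(r))
    stop(sprintf("length mismatch: rho has %d entries, r has %d",
                 length(rho), length(r)))
  rho + r
}

#' Log Dirichlet-multinomial predictive weight
#'
#' Natural log of `B(rho + r) / B(rho)`: the marginal probability, under
#' `theta ~ Dirichlet(rho)`, of drawing one fixed ordered haplotype sequence
#' with counts `r`.
#'
#' @inheritParams dm_update
#' @return A finite scalar,
#'   `sum(lgamma(rho + r) - lgamma(rho)) - (lgamma(sum(rho) + sum(r)) - lgamma(sum(rho)))`.
#' @export
dm_log_predictive <- function(rho, r) {
  if (length(rho) != length(r))
    stop(sprintf("length mismatch: rho has %d entries, r has %d",
                 length(rho), length(r)))
  nz <- which(r != 0)
  sum(lgamma(rho[nz] + r[nz]) - lgamma(rho[nz])) -
    (lgamma(sum(rho) + sum(r)) - lgamma(sum(rho)))
}

#' Posterior mean haplotype frequencies
#'
#' @param rho sufficient statistics.
#' @return `rho / sum(rho)`; entries sum to 1.
#' @export
dm_posterior_mean <- function(rho) rho / sum(rho)

# log of the number of distinct orderings of the haplotype multiset with
# count vector r: log( (sum r)! / prod(r_m!) ).  An unordered assignment's
# predictive probability is the ordered-draw B ratio times this multiplicity.
log_orderings <- function(r) {
  nz <- r[r > 0]
  lgamma(sum(nz) + 1) - sum(lgamma(nz + 1))
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
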