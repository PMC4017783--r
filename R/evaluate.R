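# Phasing accuracy measures: ambiguity-restricted switch error rate, its
# stratification by copy number, internal (within-duplication) switch error,
# and chi-squared / l1 distances between estimated and gold-standard
# haplotype frequencies.

#' Loci with ambiguous phasing in one genotype
#'
#' A marker is ambiguous when at least two alternative orientation
#' assignments exist: either several compatible unordered state pairs (all
#' total-CN-3 genotypes, for example), or a single pair with two distinct
#' symbols (a heterozygous SNP).
#'
#' @param cn,ones one individual's genotype vectors.
#' @param mode phasing mode.
#' @param diploid_at_cn2 see [enumerate_site_states()].
#' @return Ordered integer vector of ambiguous locus indices (1-based).
#' @export
ambiguous_sites <- function(cn, ones, mode = "noninternal",
                            diploid_at_cn2 = TRUE) {
  which(vapply(seq_along(cn), function(i) {
    st <- enumerate_site_states(cn[i], ones[i], mode, diploid_at_cn2,
                                codes = TRUE)
    length(st) >= 2L || (length(st) == 1L && mode == "noninternal" &&
                           st[[1L]][1L] != st[[1L]][2L])
  }, logical(1)))
}

.as_assignment_list <- function(x) {
  if (inherits(x, "cnv_phasing")) x$assignments
  else if (inherits(x, "cnv_truth")) x$assignments
  else x
}

# per-site CN class for the by-CN stratification: 2 when any chromosome
# carries a duplication at the site (per-chromosome CN 2), else 1
.site_cn_class <- function(truth_pair) {
  if (any(.NONINT_COPIES[truth_pair] == 2L)) 2L else 1L
}

#' Switch error rate of a non-internal phasing
#'
#' For each individual, the scan runs over its ambiguous markers in order and
#' counts the minimal number of haplotype-orientation switches needed to turn
#' the predicted phasing into the truth; the rate is total switches over
#' total opportunities (ambiguous markers minus one per individual, over
#' individuals with at least two scorable markers).  Markers where the
#' predicted unordered state pair differs from the truth's (a genotype-level
#' rather than orientation error, possible only at masked-CN states) or where
#' the truth pair is symmetric carry no orientation information and are
#' dropped from the scan; their count is reported.  Each consecutive pair of
#' scored markers also feeds the by-CN 2x2 table, classed 1 or 2 by whether a
#' duplicated chromosome is involved at the site.
#'
#' @param truth a `cnv_truth` (or list of true 2-row assignment matrices).
#' @param predicted a `cnv_phasing` (or list of predicted matrices).
#' @param genotypes the genotype set; defaults to `truth$genotypes`.
#' @param diploid_at_cn2 ambiguity convention, see [enumerate_site_states()].
#' @return An object of class `switch_report`: `switches`, `opportunities`,
#'   `rate`, `by_cn` (2x2 `switches`, `opportunities`, `rate`), `dropped`,
#'   `n_scored`.
#' @export
switch_error_rate <- function(truth, predicted, genotypes = NULL,
                              diploid_at_cn2 = TRUE) {
  t_assign <- .as_assignment_list(truth)
  p_assign <- .as_assignment_list(predicted)
  if (is.null(genotypes)) {
    if (!inherits(truth, "cnv_truth"))
      stop("supply genotypes when truth is a bare assignment list")
    genotypes <- truth$genotypes
  }
  if (length(t_assign) != length(p_assign))
    stop("truth and prediction cover different numbers of individuals")
  cell_sw <- matrix(0L, 2L, 2L, dimnames = list(c("1", "2"), c("1", "2")))
  cell_op <- cell_sw
  switches <- 0L; opportunities <- 0L; dropped <- 0L; n_scored <- 0L
  for (t in seq_along(t_assign)) {
    cn <- genotypes$cn[t, ]; ones <- genotypes$ones[t, ]
    tr <- t_assign[[t]]; pr <- p_assign[[t]]
    if (ncol(pr) != length(cn))
      stop(sprintf("individual %d: prediction covers %d loci, expected %d",
                   t, ncol(pr), length(cn)))
    if (!is_consistent(pr, cn, ones)) {
      cp <- colSums(matrix(.NONINT_COPIES[pr], nrow = 2L))
      on <- colSums(matrix(.NONINT_ONES[pr], nrow = 2L))
      bad <- which(cp != cn | on != ones)[1L]
      stop(sprintf("prediction inconsistent with genotype: individual %d, locus %d",
                   t, bad))
    }
    amb <- ambiguous_sites(cn, ones, "noninternal", diploid_at_cn2)
    usable <- integer(0)
    for (j in amb) {
      if (tr[1L, j] != tr[2L, j] &&
          identical(sort(tr[, j]), sort(pr[, j]))) {
        usable <- c(usable, j)
      } else dropped <- dropped + 1L
    }
    if (length(usable) < 2L) next
    n_scored <- n_scored + 1L
    m <- pr[1L, usable] == tr[1L, usable]
    cls <- vapply(usable, function(j) .site_cn_class(tr[, j]), integer(1))
    for (k in 2:length(usable)) {
      sw <- m[k] != m[k - 1L]
      cell_op[cls[k - 1L], cls[k]] <- cell_op[cls[k - 1L], cls[k]] + 1L
      opportunities <- opportunities + 1L
      if (sw) {
        cell_sw[cls[k - 1L], cls[k]] <- cell_sw[cls[k - 1L], cls[k]] + 1L
        switches <- switches + 1L
      }
    }
  }
  rate <- if (opportunities > 0L) switches / opportunities else NA_real_
  by_rate <- cell_sw / cell_op
  structure(list(switches = switches, opportunities = opportunities,
                 rate = rate,
                 by_cn = list(switches = cell_sw, opportunities = cell_op,
                              rate = by_rate),
                 dropped = dropped, n_scored = n_scored),
            class = "switch_report")
}

#' @export
print.switch_report <- function(x, ...) {
  cat(sprintf("switch error rate: %.4f (%d / %d, %d individuals scored, %d markers dropped)\n",
              x$rate, x$switches, x$opportunities, x$n_scored, x$dropped))
  cat("by CN class (from x to):\n")
  print(round(x$by_cn$rate, 4))
  invisible(x)
}

#' Switch error stratified by copy number
#'
#' Convenience wrapper returning only the 2x2 by-CN component of
#' [switch_error_rate()].
#'
#' @inheritParams switch_error_rate
#' @return list with 2x2 `switches`, `opportunities` and `rate` matrices.
#' @export
switch_error_by_cn <- function(truth, predicted, genotypes = NULL,
                               diploid_at_cn2 = TRUE) {
  switch_error_rate(truth, predicted, genotypes, diploid_at_cn2)$by_cn
}

#' Chi-squared distance between estimated and gold frequencies
#'
#' `sum over gold haplotypes i of (f_i - g_i)^2 / g_i`, where predicted
#' frequencies are looked up by haplotype identity and count as 0 when the
#' haplotype was not predicted.  Predicted mass on haplotypes outside the
#' gold set does not enter the sum; it is attached as attribute
#' `"stray_mass"` for diagnostics.
#'
#' @param f named predicted frequency vector (haplotype state keys).
#' @param g named gold-standard frequency vector; all entries must be > 0.
#' @return Non-negative scalar.
#' @export
chi2_distance <- function(f, g) {
  .check_freq_pair(f, g)
  fi <- f[names(g)]
  fi[is.na(fi)] <- 0
  out <- sum((fi - g)^2 / g)
  attr(out, "stray_mass") <- sum(f[!(names(f) %in% names(g))])
  out
}

#' l1 distance between estimated and gold frequencies
#'
#' `sum over gold haplotypes of |f_i - g_i|`, in `[0, 2]`; lookup conventions
#' as in [chi2_distance()].
#'
#' @inheritParams chi2_distance
#' @return Scalar in `[0, 2]`.
#' @export
l1_distance <- function(f, g) {
  .check_freq_pair(f, g)
  fi <- f[names(g)]
  fi[is.na(fi)] <- 0
  out <- sum(abs(fi - g))
  attr(out, "stray_mass") <- sum(f[!(names(f) %in% names(g))])
  out
}

.check_freq_pair <- function(f, g) {
  if (length(g) == 0L) stop("empty gold-standard frequency set")
  if (is.null(names(g)) || is.null(names(f)))
    stop("frequency vectors must be named by haplotype keys")
  if (any(g <= 0)) stop("gold-standard frequencies must be positive")
  invisible(TRUE)
}
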