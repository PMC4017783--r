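# Synthetic CNV/SNP dataset generator with known truth.
#
# The construction emulates how CNV-bearing evaluation panels are built from
# a phased SNP reference: an LD-bearing diploid SNP panel is generated by a
# mosaic copying model over a small founder pool (stand-in for a HapMap-style
# phased panel of 88 unrelated individuals), loci with minor allele frequency
# below 5% are removed, the distinct haplotypes and their empirical
# frequencies form the population pool, and CNV segments are then inserted
# into haplotypes chosen with probability proportional to their frequency:
# scanning left to right, each position starts a CNV region with probability
# 0.1, region length is uniform on 3..8 SNPs, and scanning resumes after the
# region end.  A region becomes a deletion or a duplication; duplication
# content is tandem (each allele a -> aa) or resampled (second copy drawn
# from the panel's allele frequencies, which creates internally heterozygous
# duplications).  Individuals are formed by drawing two pool haplotypes
# independently (random mating).

#' Simulation configuration
#'
#' @param L number of loci in the emitted dataset (default 30).
#' @param T number of individuals drawn from the pool (default 88).
#' @param panel_T number of diploid individuals in the reference panel from
#'   which the haplotype pool is extracted (default 88, i.e. 2 * 88
#'   haplotypes).  The panel defines the population and its gold-standard
#'   frequencies independently of `T`.
#' @param maf_min minimum minor allele frequency retained (default 0.05;
#'   loci at exactly the boundary are kept).
#' @param cnv_start_prob per-position probability that a CNV region starts
#'   (default 0.1).
#' @param cnv_len_min,cnv_len_max CNV length bounds in SNPs (default 3 and 8).
#' @param dup_fraction probability that an inserted CNV is a duplication
#'   rather than a deletion (default 0.5).
#' @param dup_content `"tandem"` (duplicate the resident allele) or
#'   `"resampled"` (second copy drawn per locus from panel allele
#'   frequencies).
#' @param modify_fraction fraction of pool haplotypes receiving CNV
#'   insertions (default 0.3).
#' @param n_founders founder pool size of the mosaic copying model.
#' @param switch_rate per-locus probability of switching founder template.
#' @param raw_width width of the raw panel before MAF filtering (default
#'   `max(ceiling(1.5 * L), L + 10)`).
#' @param seed integer seed; all randomness in [simulate_dataset()] flows
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(L = 30L, T = 88L, panel_T = 88L, maf_min = 0.05,
                       cnv_start_prob = 0.1, cnv_len_min = 3L,
                       cnv_len_max = 8L, dup_fraction = 0.5,
                       dup_content = c("tandem", "resampled"),
                       modify_fraction = 0.3, n_founders = 8L,
                       switch_rate = 0.03, raw_width = NULL,
                       seed = 1L) {
  dup_content <- match.arg(dup_content)
  if (L < 1L || T < 1L || panel_T < 1L) stop("L, T and panel_T must be >= 1")
  if (cnv_start_prob < 0 || cnv_start_prob >= 1)
    stop("cnv_start_prob must be in [0, 1)")
  if (cnv_len_min > cnv_len_max || cnv_len_min < 1L)
    stop("invalid CNV length range")
  if (dup_fraction < 0 || dup_fraction > 1)
    stop("dup_fraction must be in [0, 1]")
  if (modify_fraction < 0 || modify_fraction > 1)
    stop("modify_fraction must be in [0, 1]")
  if (n_founders < 2L) stop("founder pool must have at least 2 haplotypes")
  if (is.null(raw_width)) raw_width <- max(ceiling(1.5 * L), L + 10L)
  structure(list(L = as.integer(L), T = as.integer(T),
                 panel_T = as.integer(panel_T), maf_min = maf_min,
                 cnv_start_prob = cnv_start_prob,
                 cnv_len_min = as.integer(cnv_len_min),
                 cnv_len_max = as.integer(cnv_len_max),
                 dup_fraction = dup_fraction, dup_content = dup_content,
                 modify_fraction = modify_fraction,
                 n_founders = as.integer(n_founders),
                 switch_rate = switch_rate,
                 raw_width = as.integer(raw_width),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a phased diploid SNP panel with LD
#'
#' Mosaic copying model: each haplotype copies a founder template and
#' switches templates with a small per-locus probability, so nearby loci are
#' correlated and whole haplotypes recur with appreciable frequency.  Uses
#' the current RNG state.
#'
#' @param n_hap number of haplotypes (2T for a diploid panel).
#' @param width number of raw loci.
#' @param n_founders founder pool size (>= 2).
#' @param switch_rate per-locus template switch probability.
#' @return 0/1 integer matrix `n_hap x width`.
#' @export
generate_snp_panel <- function(n_hap, width, n_founders = 8L,
                               switch_rate = 0.03) {
  if (n_founders < 2L) stop("founder pool must have at least 2 haplotypes")
  founders <- matrix(stats::rbinom(n_founders * width, 1L, 0.5),
                     nrow = n_founders)
  panel <- matrix(0L, nrow = n_hap, ncol = width)
  for (h in seq_len(n_hap)) {
    f <- sample.int(n_founders, 1L)
    sw <- stats::runif(width) < switch_rate
    for (i in seq_len(width)) {
      if (i > 1L && sw[i]) f <- sample.int(n_founders, 1L)
      panel[h, i] <- founders[f, i]
    }
  }
  panel
}

#' Filter loci by minor allele frequency
#'
#' @param panel 0/1 haplotype matrix.
#' @param maf_min minimum minor allele frequency; loci with MAF strictly
#'   below it are removed, the boundary is retained.
#' @param L truncate the filtered panel to the first `L` loci.
#' @return The filtered (and truncated) panel.
#' @export
maf_filter <- function(panel, maf_min = 0.05, L = NULL) {
  f <- colMeans(panel)
  keep <- which(pmin(f, 1 - f) >= maf_min)
  if (is.null(L)) L <- length(keep)
  if (length(keep) < L)
    stop(sprintf("only %d loci with MAF >= %g; increase raw panel width",
                 length(keep), maf_min))
  panel[, keep[seq_len(L)], drop = FALSE]
}

#' Extract the haplotype pool of a phased panel
#'
#' @param panel 0/1 haplotype matrix.
#' @return An object of class `hap_pool`: `states` (list of non-internal
#'   state-code vectors), `freq` (empirical frequencies summing to 1), and
#'   `dup_regions` (per-haplotype list of inserted duplications, empty here).
#' @export
extract_pool <- function(panel) {
  keys <- apply(panel, 1L, paste, collapse = "")
  tab <- table(keys)
  freq <- as.numeric(tab) / nrow(panel)
  o <- order(-freq, names(tab))
  uniq <- names(tab)[o]
  states <- lapply(uniq, function(k)
    as.integer(strsplit(k, "", fixed = TRUE)[[1L]]) + 2L)  # 0/1 -> codes 2/3
  structure(list(states = states, freq = freq[o],
                 dup_regions = rep(list(list()), length(uniq))),
            class = "hap_pool")
}

#' @export
print.hap_pool <- function(x, ...) {
  n_cnv <- sum(vapply(x$states, function(s) any(s == 1L | s >= 4L), logical(1)))
  cat(sprintf("haplotype pool: %d haplotypes (%d CNV-bearing), L = %d\n",
              length(x$states), n_cnv, length(x$states[[1L]])))
  invisible(x)
}

#' Insert CNV segments into pool haplotypes
#'
#' Haplotypes are selected for modification with probability proportional to
#' their frequency; each selected haplotype is scanned left to right, a CNV
#' region starts at each position with `cnv_start_prob`, its length is
#' uniform on `cnv_len_min..cnv_len_max` (truncated at the haplotype end),
#' the region becomes a deletion or duplication, and scanning resumes after
#' the region.  Uses the current RNG state.
#'
#' @param pool a `hap_pool`.
#' @param config a `sim_config`.
#' @return The modified `hap_pool`; duplicated regions record their two
#'   ordered copies (original and added allele strings) for internal-phasing
#'   truth.
#' @export
insert_cnvs <- function(pool, config) {
  n <- length(pool$states)
  L <- length(pool$states[[1L]])
  if (config$cnv_start_prob == 0 || config$modify_fraction == 0) return(pool)
  n_mod <- max(1L, round(config$modify_fraction * n))
  n_mod <- min(n_mod, n)
  selected <- sample.int(n, n_mod, replace = FALSE, prob = pool$freq)
  # allele-1 marginal of the pre-CNV pool, used for resampled duplications
  p1 <- vapply(seq_len(L), function(i)
    sum(pool$freq * vapply(pool$states, function(s) s[i] == 3L, numeric(1))),
    numeric(1))
  for (h in selected) {
    st <- pool$states[[h]]
    regions <- pool$dup_regions[[h]]
    pos <- 1L
    while (pos <= L) {
      if (stats::runif(1L) < config$cnv_start_prob) {
        len <- sample(config$cnv_len_min:config$cnv_len_max, 1L)
        end <- min(pos + len - 1L, L)
        if (stats::runif(1L) < config$dup_fraction) {
          span <- pos:end
          orig <- .NONINT_ONES[st[span]]           # resident allele (0/1)
          added <- if (config$dup_content == "tandem") orig else
            stats::rbinom(length(span), 1L, p1[span])
          lo <- pmin(orig, added); hi <- pmax(orig, added)
          st[span] <- 4L + lo + hi                  # (0,0)->4 (0,1)->5 (1,1)->6
          regions[[length(regions) + 1L]] <-
            list(start = pos - 1L, end = end,       # 0-based half-open
                 copies = rbind(orig, added, deparse.level = 0))
        } else {
          st[pos:end] <- 1L                         # deletion
        }
        pos <- end + 1L
      } else pos <- pos + 1L
    }
    pool$states[[h]] <- st
    pool$dup_regions[[h]] <- regions
  }
  pool
}

#' Draw individuals from a haplotype pool
#'
#' Each individual receives two haplotypes drawn independently with
#' probability equal to pool frequency (random mating); its genotype at each
#' locus is the summed copy number and summed allele-1 count.  Uses the
#' current RNG state.
#'
#' @param pool a `hap_pool`.
#' @param T number of individuals.
#' @return An object of class `cnv_truth`: `genotypes` (a `cnv_geno`),
#'   `assignments` (true 2-row state matrices, rows in draw order),
#'   `hap_idx` (T x 2 pool indices), `internal` (list of duplicated-region
#'   truth records), `gold` (gold-standard haplotype frequencies), `pool`.
#' @export
sample_individuals <- function(pool, T) {
  n <- length(pool$states)
  L <- length(pool$states[[1L]])
  idx <- matrix(sample.int(n, 2L * T, replace = TRUE, prob = pool$freq),
                ncol = 2L)
  cn <- matrix(0L, T, L); ones <- matrix(0L, T, L)
  assignments <- vector("list", T)
  internal <- list()
  for (t in seq_len(T)) {
    mat <- rbind(pool$states[[idx[t, 1L]]], pool$states[[idx[t, 2L]]])
    attr(mat, "mode") <- "noninternal"
    assignments[[t]] <- mat
    cn[t, ] <- colSums(matrix(.NONINT_COPIES[mat], nrow = 2L))
    ones[t, ] <- colSums(matrix(.NONINT_ONES[mat], nrow = 2L))
    for (r in 1:2) {
      for (reg in pool$dup_regions[[idx[t, r]]]) {
        internal[[length(internal) + 1L]] <-
          list(ind = t, chrom = r, start = reg$start, end = reg$end,
               copies = reg$copies)
      }
    }
  }
  structure(list(genotypes = new_genotypes(cn, ones),
                 assignments = assignments, hap_idx = idx,
                 internal = internal, gold = gold_frequencies(pool),
                 pool = pool),
            class = "cnv_truth")
}

#' Gold-standard haplotype frequencies of a pool
#'
#' @param pool a `hap_pool` (post CNV insertion).
#' @return Named numeric vector over haplotype state keys, aggregating pool
#'   entries with identical state strings; sums to 1.
#' @export
gold_frequencies <- function(pool) {
  keys <- vapply(pool$states, .hap_key, character(1))
  f <- tapply(pool$freq, keys, sum)
  out <- as.numeric(f)
  names(out) <- names(f)
  sort(out, decreasing = TRUE)
}

#' Simulate a full CNV/SNP dataset with known truth
#'
#' Runs the whole generator pipeline (panel, MAF filter, pool extraction, CNV
#' insertion, individual sampling) under `config$seed`.
#'
#' @param config a `sim_config`.
#' @return A `cnv_truth` (see [sample_individuals()]); `$config` records the
#'   configuration used.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- generate_snp_panel(2L * config$panel_T, config$raw_width,
                              config$n_founders, config$switch_rate)
  panel <- maf_filter(panel, config$maf_min, config$L)
  pool <- extract_pool(panel)
  pool <- insert_cnvs(pool, config)
  truth <- sample_individuals(pool, config$T)
  truth$config <- config
  truth
}

#' @export
print.cnv_truth <- function(x, ...) {
  cat(sprintf("synthetic truth set: %d individuals x %d loci, pool of %d haplotypes\n",
              n_individuals(x$genotypes), n_loci(x$genotypes),
              length(x$pool$states)))
  cat(sprintf("duplicated-region truth records: %d\n", length(x$internal)))
  invisible(x)
}
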