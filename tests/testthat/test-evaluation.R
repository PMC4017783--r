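test_that("ambiguous markers are identified", {
  expect_identical(ambiguous_sites(2L, 1L), 1L)          # het SNP
  expect_identical(ambiguous_sites(3L, 1L), 1L)          # any CN-3 genotype
  expect_identical(ambiguous_sites(1L, 0L), 1L)          # (-,0) orientation
  expect_length(ambiguous_sites(c(2L, 4L, 0L, 2L), c(0L, 0L, 0L, 2L)), 0L)
  expect_identical(ambiguous_sites(c(2L, 3L, 2L), c(0L, 3L, 1L)), c(2L, 3L))
})

test_that("switch error: zero on truth, counts a mid-sequence flip, label symmetric", {
  tr_mat <- sym_mat(c("0", "0", "0", "0"), c("1", "1", "1", "1"))
  geno <- make_geno(matrix(2L, 1, 4), matrix(1L, 1, 4))
  self <- switch_error_rate(list(tr_mat), list(tr_mat), geno)
  expect_identical(self$rate, 0)
  expect_identical(self$opportunities, 3L)
  # flip from site 3 onwards: one switch among three opportunities
  pred <- sym_mat(c("0", "0", "1", "1"), c("1", "1", "0", "0"))
  flip <- switch_error_rate(list(tr_mat), list(pred), geno)
  expect_equal(flip$rate, 1 / 3)
  expect_identical(flip$switches, 1L)
  # globally swapped chromosomes are the same phasing
  swapped <- tr_mat[2:1, ]; attr(swapped, "mode") <- "noninternal"
  expect_identical(switch_error_rate(list(tr_mat), list(swapped), geno)$rate, 0)
  # a flip at every site: alternating orientation
  alt <- sym_mat(c("0", "1", "0", "1"), c("1", "0", "1", "0"))
  expect_equal(switch_error_rate(list(tr_mat), list(alt), geno)$rate, 1)
})

test_that("inconsistent predictions are rejected with coordinates", {
  tr_mat <- sym_mat(c("0", "0"), c("1", "1"))
  geno <- make_geno(matrix(2L, 1, 2), matrix(1L, 1, 2))
  bad <- sym_mat(c("0", "0"), c("1", "0"))
  expect_error(switch_error_rate(list(tr_mat), list(bad), geno),
               "individual 1, locus 2")
  short <- sym_mat(c("0"), c("1"))
  expect_error(switch_error_rate(list(tr_mat), list(short), geno),
               "covers 1 loci")
})

test_that("by-CN table: partition property and a constructed junction error", {
  # SNP-only dataset populates only the (1,1) cell
  set.seed(70)
  tr <- simulate_dataset(sim_config(L = 10, T = 20, cnv_start_prob = 0,
                                    seed = 70))
  ph <- hierarchical_phase(tr$genotypes, K = 20)
  rep1 <- switch_error_rate(tr, ph)
  expect_identical(sum(rep1$by_cn$opportunities), rep1$opportunities)
  expect_identical(rep1$by_cn$opportunities["1", "1"], rep1$opportunities)
  # CNV dataset: cells partition the opportunities and aggregate to the rate
  tr2 <- simulate_dataset(sim_config(L = 15, T = 20, seed = 71))
  ph2 <- hierarchical_phase(tr2$genotypes, K = 20)
  rep2 <- switch_error_rate(tr2, ph2)
  expect_identical(sum(rep2$by_cn$opportunities), rep2$opportunities)
  expect_identical(sum(rep2$by_cn$switches), rep2$switches)
  # hand-built fixture: het SNP (class 1) then CN-3 site (class 2), one error
  tr_mat <- sym_mat(c("0", "0"), c("1", "01"))
  pred <- sym_mat(c("0", "01"), c("1", "0"))
  geno <- make_geno(matrix(c(2L, 3L), 1, 2), matrix(1L, 1, 2))
  rep3 <- switch_error_rate(list(tr_mat), list(pred), geno)
  expect_identical(rep3$by_cn$switches["1", "2"], 1L)
  expect_identical(sum(rep3$by_cn$switches), 1L)
  expect_identical(rep3$by_cn$opportunities["1", "2"], 1L)
})

test_that("by-CN cell rates average (weighted) to the overall rate", {
  tr <- simulate_dataset(sim_config(L = 20, T = 30, seed = 72))
  ph <- hierarchical_phase(tr$genotypes, K = 25)
  rp <- switch_error_rate(tr, ph)
  cells <- rp$by_cn
  agg <- sum(cells$rate * cells$opportunities, na.rm = TRUE) /
    sum(cells$opportunities)
  expect_equal(agg, rp$rate)
})

test_that("internal switch error scores duplicated-region copies", {
  # truth: one duplicated region with three internally het sites
  truth <- list(list(ind = 1L, chrom = 1L, start = 2L, end = 5L,
                     copies = rbind(c(0L, 0L, 0L), c(1L, 1L, 1L))))
  perfect <- truth
  expect_identical(internal_switch_error(truth, perfect)$rate, 0)
  # phased backwards from the second het site on: one switch in two chances
  back <- list(list(ind = 1L, chrom = 1L, start = 2L, end = 5L,
                    copies = rbind(c(0L, 1L, 1L), c(1L, 0L, 0L))))
  ie <- internal_switch_error(truth, back)
  expect_identical(ie$switches, 1L)
  expect_identical(ie$opportunities, 2L)
  # identical copies: no ambiguous internal position, region contributes nothing
  hom <- list(list(ind = 1L, chrom = 1L, start = 0L, end = 2L,
                   copies = rbind(c(1L, 0L), c(1L, 0L))))
  ie2 <- internal_switch_error(hom, hom)
  expect_identical(ie2$opportunities, 0L)
  expect_true(is.na(ie2$rate))
  # content mismatch means no match
  wrong <- list(list(ind = 1L, chrom = 1L, start = 2L, end = 5L,
                     copies = rbind(c(0L, 0L, 0L), c(1L, 0L, 1L))))
  expect_identical(internal_switch_error(truth, wrong)$unmatched, 1L)
})

test_that("internal phasing pipeline recovers copies inside duplications", {
  set.seed(75)
  tr <- simulate_dataset(sim_config(L = 15, T = 40, dup_fraction = 1,
                                    dup_content = "resampled",
                                    modify_fraction = 0.5, seed = 75))
  # phase internally from the TRUE chromosome-level assignments so that the
  # duplicated intervals line up with the truth records
  pred <- phase_internal(tr$assignments, K = 25)
  ie <- internal_switch_error(tr$internal, pred)
  expect_gt(ie$matched, 0L)
  # unmatched regions can only arise from adjacent insertions merging into
  # one maximal run, never from content disagreement here
  expect_lte(ie$unmatched, length(tr$internal) - ie$matched)
  if (ie$opportunities > 0) {
    expect_gte(ie$rate, 0)
    expect_lte(ie$rate, 1)
  }
})

test_that("frequency distances: hand values, identities, scaling", {
  g <- c(a = 0.25, b = 0.75)
  f <- c(a = 0.5, b = 0.5)
  expect_equal(as.numeric(chi2_distance(f, g)), 0.0625 / 0.25 + 0.0625 / 0.75)
  expect_equal(as.numeric(l1_distance(f, g)), 0.5)
  expect_equal(as.numeric(chi2_distance(g, g)), 0)
  expect_equal(as.numeric(l1_distance(g, g)), 0)
  # halving every gap quarters chi2
  fh <- g + (f - g) / 2
  expect_equal(as.numeric(chi2_distance(fh, g)),
               as.numeric(chi2_distance(f, g)) / 4)
  # disjoint supports: l1 over gold entries equals 1, stray mass reported
  fd <- c(x = 0.6, y = 0.4)
  expect_equal(as.numeric(l1_distance(fd, g)), 1)
  expect_equal(attr(l1_distance(fd, g), "stray_mass"), 1)
  expect_error(chi2_distance(f, numeric(0)), "empty gold")
  expect_error(chi2_distance(f, c(a = 0.5, b = 0)), "positive")
})
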