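---
title: "Phasing CNV/SNP genotypes with a deterministic particle sampler: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing CNV/SNP genotypes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Data model

A genotype observation at one locus is the pair *(total copy number,
allele-1 count)* with `0 <= allele1 <= total_cn <= 4`.  Each of the two
chromosomes carries per-locus copy number 0, 1 or 2 (a single deletion or a
single amplification), so chromosome-level states are `-`, `0`, `1`, `00`,
`01`, `11` (*non-internal* phasing).  Within a region of constant total
copy number `p`, the individual can instead be treated as `p`-ploid with
per-copy alleles `0`/`1` (*internal* phasing).

A deliberate modelling choice: the observation is the *(CN, count)* pair,
not the bare allele count.  A bare count of 2 cannot distinguish `0/11`
from `1/1` genotypes, yet every copy-number-stratified analysis the package
performs (ambiguity classification, the by-CN switch-error table) presumes
the total CN is known — which matches what CNV genotyping pipelines emit.

At total CN 2 the default enumeration treats the locus as two single-copy
chromosomes.  The masked states (a deletion on one chromosome hidden by a
duplication on the other, e.g. `-` with `01`) are excluded by default
(`diploid_at_cn2 = TRUE`) so that ambiguity counting matches conventional
SNP phasing; the flag restores full enumeration.  The simulator *can*
produce such masked loci (a deletion overlapping a duplication); the
switch-error scorer treats a truth/prediction disagreement on the unordered
state pair as a genotype-level error and drops the marker from the
orientation scan, reporting the count.

## Posterior predictive weighting

With universe `Z` (the deduplicated union of all haplotypes compatible with
any genotype in the block, built from all individuals before sampling) and
`theta ~ Dirichlet(rho)`, the marginal probability of an *ordered* haplotype
draw with counts `r` is `B(rho + r)/B(rho)`.  An unordered assignment is a
multiset, so its predictive mass is that ratio times the number of distinct
orderings of the multiset (`2` for a heterozygous pair, `p!/prod(r_m!)`
generally).  Without this multiplicity the sampler would favour homozygous
decompositions two-fold; with it, the per-individual solution weights form a
proper distribution over unordered assignments, and they agree with
exhaustive posterior enumeration on small datasets (checked to 1e-9 in log
space).  One consequence worth noting: under a fresh uniform prior on an
`M = 2` universe, a heterozygous pair and a homozygous pair receive *equal*
predictive mass (1/3 each) — confirmed against Monte-Carlo integration over
the Dirichlet prior.

All weights are carried as natural logs via `lgamma`; the Beta ratios
underflow after a few tens of individuals otherwise.  Normalization happens
by max-subtraction only where probabilities are needed.

**Prior pseudocount** `epsilon` (default 1): the uniform Dirichlet.  It is
proper, weakly informative, and makes the single-draw predictive equal the
posterior-mean frequency.  Phased reference haplotypes could be folded in as
larger per-haplotype pseudocounts, though no such interface is exposed.

## The sampler

`K` particles (default 50) each carry the assignment history of processed
individuals, the implied Dirichlet statistics, and a raw log weight.
Expansion pairs every particle with every compatible assignment of the next
individual; selection retains the `K` highest-weight children with ties
broken by (parent index, candidate enumeration index).  Selection is
deterministic — reproducibility was preferred over resampling-based
diversity, in keeping with the tree-based deterministic sampling family the
method belongs to.  Individuals are processed in input order by default; a
seeded shuffle is available (`shuffle_seed`), and on simulated data the
switch error varies only modestly across orders.  The sampler is single
pass: no individual is revisited.

The final hard phasing of an individual is the arg-max of its aggregated
(particle-weight-summed) assignment weights, ties to the lexicographically
smallest assignment.  Frequency estimates take the top particle's Dirichlet
counts, subtract the prior pseudocounts, and normalize (`subtract_prior`
and a particle-averaging variant are exposed as flags; top-particle is the
default because it reports the frequencies of one coherent joint solution).

## Partition–ligation

Blocks hold at most 5 loci — beyond that, exhaustive unordered enumeration
of compatible assignments becomes prohibitive.  Loci are tiled into
`floor(L/5)` full blocks plus a remainder.  Two adjacent block solutions are
merged per individual by pairing chromosomes across the junction; only
pairings achieving the minimal number of per-chromosome copy-number changes
at the boundary loci are kept.  When the two boundary copy numbers within a
block are equal the pairings tie and both are generated (identical merges
are deduplicated, with their ligation masses summed).  Each merged candidate
carries a *ligation weight* — the product of its source solution weights —
and the sampler is rerun over individuals with candidate weights offset by
the log ligation weight.  Ligation proceeds progressively left-to-right by
default, keeping the widest phased context in the growing left segment; a
pairwise (log-depth) order is available by flag.  Merged candidate lists are
capped per individual at `max_candidates` (default 256, by ligation weight)
with a logged message, since nothing in the method bounds their growth.

Two consequences of this weighting are documented rather than hidden:

* The block-level evidence enters twice (once through the ligation weight,
  once through the rerun's predictive).  For individuals whose block
  solution is decisive the merged arg-max is unchanged, but a near-tied
  solution (aggregated top weight barely above 1/2) can reorder during
  ligation with a fully unambiguous neighbouring block.  The test suite
  asserts bitwise invariance only for decisively phased individuals.
* Internal-mode assignments are never ligated: the minimal-change rule is a
  diploid notion.  Internal phasing is instead performed per fixed-ploidy
  region (below).

## Internal phasing

Non-internal phasing already fixes, per chromosome and locus, the unordered
allele content of a duplication (`00`, `01`, `11`).  What remains within a
maximal duplicated run of one chromosome is to string the two copies
together — structurally a two-haplotype SNP phasing problem whose
heterozygous sites are the `01` loci.  The package therefore extracts every
maximal duplicated run, groups runs covering the same locus interval across
individuals (sharing population information exactly as the main pass does),
and phases each group with the same sampler.  Runs are never extended
across copy-number breakpoints.  Evaluation matches predicted to true
regions by individual and interval, requires agreement on the unordered
content, and scores orientation switches over internally heterozygous
positions only.

## The synthetic-data generator

The generator emulates how CNV evaluation panels are built from a phased
SNP reference:

1. **Panel.** A mosaic copying model over a small founder pool
   (`n_founders = 8`, per-locus template switch rate 0.03) produces
   `2 * panel_T` haplotypes (default `panel_T = 88`, the size of a
   HapMap-CEU-style unrelated-parents panel).  Copying gives decaying
   linkage disequilibrium with distance and makes whole haplotypes recur
   with appreciable frequency — the two properties the phaser exploits.
   The founder count and switch rate were fixed once as a plausible
   common-variant regime: a handful of frequent regional haplotypes plus
   recombinant mosaics.
2. **MAF filter.** Loci with minor allele frequency strictly below 5% are
   removed (the boundary is kept), and the panel is truncated to `L` loci.
3. **Pool.** Distinct haplotypes with their empirical frequencies form the
   population pool; its (post-CNV) frequencies are the gold standard.
4. **CNV insertion.** Haplotypes are chosen with probability proportional
   to frequency (`modify_fraction = 0.3` of pool entries by default — the
   selection law is fixed by the construction, the count is not, and 0.3
   makes CNVs common without dominating).  Scanning left to right, a CNV
   region starts at each position with probability 0.1, its length is
   uniform on 3–8 SNPs (truncated at the end), and scanning resumes after
   the region.  A region becomes a deletion or a duplication with equal
   probability (`dup_fraction = 0.5`); duplication content is *tandem*
   (each resident allele doubled) by default, or *resampled* (second copy
   drawn from panel allele frequencies), the latter being the only mode
   that creates internally heterozygous duplications.  The mechanism
   parameters that the construction states (start probability, length law,
   MAF cut, panel size 88) are defaults; the content of a "CNV haplotype",
   nowhere specified, is exposed as the two options above.
5. **Individuals.** Each of `T` individuals draws two pool haplotypes
   independently (random mating); genotypes are the per-locus sums.

A deliberate decoupling: the panel size (`panel_T`) is *not* tied to the
number of sampled individuals `T`.  The panel defines a fixed population —
and hence gold-standard frequencies that do not change when an experiment
varies `T`.  Tying the panel to `T` makes every gold singleton's frequency
shrink as `1/(2T)`, so the chi-squared distance (which divides by the gold
frequency) stops improving with sample size for reasons that have nothing
to do with the estimator.

What the generator does **not** emulate: coalescent-realistic recombination
maps and mutation, genotyping error, trio structure, and CNV breakpoints
shared across haplotypes by descent (each insertion is independent).  A
green trend test therefore establishes that the estimator improves with
sample size *under this stated world*, not that it reaches any particular
accuracy on real array data.

## Evaluation conventions

* **Ambiguous marker:** at least two alternative orientation assignments —
  several compatible unordered state pairs (every total-CN-3 genotype), or
  a single pair of two distinct symbols (a heterozygous SNP).
* **Switch error:** per individual, the minimal number of orientation flips
  over its scorable ambiguous markers, pooled over individuals with at
  least two such markers; invariant to global chromosome relabelling.
* **By-CN stratification:** a site is classed 2 when a duplicated
  chromosome is involved at it, else 1; each consecutive scored pair feeds
  the (from, to) cell, so cells partition the opportunities and their
  weighted average is the overall rate.  This classing is this package's
  convention — the bookkeeping for mixed-CN junctions is not standardized.
* **Frequency distances:** `chi2(f,g) = sum_i (f_i - g_i)^2 / g_i` and
  `l1(f,g) = sum_i |f_i - g_i|`, both summed over the gold haplotypes only
  (a predicted haplotype absent from the gold set would divide by zero);
  the stray predicted mass is reported separately as a diagnostic.

## Numerical and degenerate-input choices

* Assignment enumeration is lexicographic over state codes, making particle
  expansion, tie-breaking, and hence entire runs bit-reproducible.
* Loci are 0-based with half-open intervals in all block/region APIs.
* A fully deleted region has nothing to phase internally and is rejected;
  varying copy number inside an internal-mode block is rejected with a
  pointer to region decomposition.
* Genotype cells are validated on construction and on file read, with the
  offending individual and locus named.
* `rho` sums up to 1e6 stay finite in the log predictive (lgamma-based).

## Known limitations

* Single-pass processing: an early individual phased before most evidence
  arrived is never revisited (a multi-pass variant would be a natural
  extension).
* Deterministic selection concentrates on modal solution streams; rare
  haplotypes can be dropped from frequency estimates (quantified by the
  trend tests, not hidden).
* Per-chromosome copy number above 2, genotype likelihoods (soft inputs),
  and CNV calling from intensities are out of scope.
* The ligation candidate cap trades exactness for bounded memory on long,
  highly ambiguous marker sets; it logs when it binds.
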