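---
title: "Differential activity-by-contact: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential activity-by-contact: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diffabc)
```

# Overview

`diffabc` implements a chromatin-level test for ancestry-associated
differences in gene regulation. The pipeline has five stages, each a module
of the package:

1. **Candidate element definition** (`define_cres()` and friends): a common
   CRE set is built from per-ancestry ATAC peak rankings, TSS windows and an
   artifact blacklist, and classified into promoters and enhancers.
2. **Scoring** (`score_pairs()`, `define_eg_pairs()`): per sample, every CRE
   within 5 Mb of a gene's TSS receives an ABC score and its three
   components (ATAC, ChIP, HiC), followed by candidacy filters.
3. **Differential testing** (`diff_scores()`, `estimate_fdr()`): Welch
   t-tests of EUR versus AFR samples per pair and score type, with a
   replicate-shuffle permutation FDR.
4. **Enrichment** (`de_overlap_test()`, `direction_match_test()`,
   `qtl_overlap_test()`, `qtl_direction_match_test()`, `sign_test()`):
   one-sided Fisher and binomial tests relating differential CREs to
   differential expression and binding QTL.
5. **Population genetics** (`wc_fst()`, `wilcoxon_compare()`,
   `decile_binned_tests()`): per-site Weir–Cockerham F_ST and its
   comparisons across CRE classes.

A synthetic-data module (`sim_config()`, `sim_abc_data()`) generates all
pipeline inputs with known injected effects, so every downstream claim made
by the test suite is computed, not assumed.

# The scoring model and its assumptions

The ABC premise is that an element's contribution to a gene's expression is
its activity scaled by its contact frequency with the gene's promoter,
normalized over all elements in the gene's neighbourhood. With H3K27ac
HiChIP, activity and contact are measured jointly; the package decomposes the
signal into:

* **A** — quantile-normalized ATAC reads-per-million at the element
  (accessibility);
* **H** — quantile-normalized total valid *cis*-pair count of the 5-kb bin
  overlapping an element or promoter; the geometric mean `sqrt(H_E * H_G)`
  (VC-sqrt) estimates the H3K27ac contribution of the two anchors;
* **C** — quantile-normalized valid *cis*-pair count connecting the element's
  bin to the promoter's bin;
* **Q** — the quantitative HiChIP signal: per gene, contacts sum-normalized
  then divided by their maximum, making the strongest contact of every gene
  comparable across genes.

The four scores (ABC, ATAC, ChIP, HiC) are fractions of regulatory input and
each sums to 1 over a gene's elements whenever its denominator is positive
(tested to 1e-9). Dividing C by the VC-sqrt in the HiC score removes the
H3K27ac component from contact frequency; algebraically the ChIP and HiC
numerators multiply back to C, an identity the tests assert directly.

Assumptions worth keeping in mind: quantile normalization assumes samples
share the same signal-shape distribution within an element class (it is run
separately for enhancers and promoters precisely because those classes
differ); the 5-Mb window and 5-kb bin size follow the resolution of the
contact data; and no explicit library-size model is used for HiChIP — the
combination of quantile normalization and per-gene score normalization
absorbs depth differences.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window` | 5e6 | bp | neighbourhood over which regulatory input is apportioned, measured TSS to element midpoint |
| `bin_size` | 5000 | bp | contact-map resolution |
| `abc_min` | 0.015 | score | minimum ABC in ≥ 1 sample for a candidate pair |
| `promoter_abc_min` | 0.1 | score | stricter floor for a gene's own promoter, where the model is less reliable |
| `alpha` | 0.05 | p | nominal diff-CRE threshold |
| `nondiff` | 0.5 | p | non-diff threshold; pairs in between are excluded from 2×2 tables |
| `k` | 150000 | elements | per-ancestry peak ranking depth (full peak set for synthetic runs) |
| `n_shuffles` | 1 | — | replicate-shuffle null draws per pair; raise to reduce FDR variance |
| `fst_quantile` | 0.95 | — | restricts QTL direction tests to the most ancestry-divergent sites |

# What the generator emulates — and what it does not

`sim_config()` defaults describe a desk-scale study shaped like the pooled
two-ancestry design: 7 populations (4 AFR, 3 EUR) × 2 replicates = 14
samples; a 16 × 6-Mb genome with 1,600 genes and 3,840 shared peak locations
per ancestry (70% at TSSs, as promoters dominate strong ATAC peaks); ATAC
counts negative-binomial (size 25) around log-normal per-peak means with
log-normal per-sample depth factors; HiChIP contacts Poisson with
exponential distance decay (2e-5 per bp), 4-fold anchor enrichment at active
bins, upper-triangle storage with diagonal. This yields roughly 11,000
candidate pairs after filtering — about one fifth of the real-scale 52k —
with a per-gene pair count (~4–8) chosen to keep both diff and non-diff
strata populated. Variant frequencies follow a Balding–Nichols model with a
single between-ancestry divergence knob that maps directly onto F_ST;
genotypes are Hardy–Weinberg draws so observed heterozygosity is real, as the
Weir–Cockerham estimator requires.

Injected effects multiply means by `2^effect_log2fc` in one ancestry, on the
ATAC count (atac channel), the contact-anchor weight of the element's bin
(chip channel — this deliberately shifts the whole bin marginal, and through
the compositional scores it perturbs sibling elements of the same gene, as a
real activity change would), or the single connecting bin pair (hic channel).
The `coupling` knob c sets the probability `(1 + c)/2` that DE signs and bQTL
high-affinity-allele directions match the injected activity direction, so
c = 0 gives exact independence (null calibration) and c = 1 forces matching
(positive controls); with c > 0 QTL are also over-sampled into flagged
elements (weight 1 + 4c), reflecting that binding variants are the putative
cause of the activity differences.

Not emulated: read-level artifacts (mapping bias, duplicates), linkage
disequilibrium between sites, peak-calling noise, batch effects, and the
cell-line (EBV transformation) biases of the real assay. Passing tests on
synthetic data therefore demonstrate the correctness and calibration of the
statistical machinery, not robustness to those real-data pathologies.

# Numerical choices and degenerate inputs

* **Coordinates** are 0-based half-open throughout; TSS windows for promoter
  classification are `[TSS − 500, TSS + 500]` inclusive, and classification
  is by interval overlap (the 500-bp TSS elements make an element-edge
  distance rule nearly equivalent, but overlap is unambiguous).
* **Edge clipping**: 500-bp windows at chromosome edges are clipped without
  re-centring, preserving summit positions at the cost of width.
* **Ranking ties** break by genomic coordinate; merged candidate elements
  keep the best (smallest) interleaved position among their constituents.
* **CRE→bin assignment** uses the bin containing the element midpoint — a
  500-bp element can straddle two 5-kb bins and the midpoint rule is
  deterministic and unique. Bins overlapping both element classes are
  normalized in the promoter class, since promoter signal dominates.
* **Quantile normalization** averages tied reference values (limma's
  `ties = TRUE`); an all-zero sample within a class is an error because its
  ranks carry no information.
* **Zero denominators** in score computation yield all-zero scores for that
  gene rather than errors — the candidacy filters remove such pairs anyway.
  A bin pair with contacts but zero bin total is an input inconsistency and
  aborts.
* **Degenerate t-tests**: both group variances zero with equal means gives
  t = 0, p = 1; with unequal means the p-value is the smallest representable
  double and the result is flagged. Zero group means make the log2 fold
  change an infinite sentinel, excluded from fold-change summaries.
* **Promoter pair threshold** (0.1) applies in at least one sample, for
  consistency with the 0.015 rule; both thresholds are arguments.
* **Fisher tests** report the sample odds ratio ad/bc (infinite when
  bc = 0), the exact upper-tail hypergeometric p, and the exact one-sided
  95% lower confidence bound from noncentral hypergeometric inversion.
  Implementations disagree here (conditional-MLE vs sample OR); the sample
  OR is reported because it is the directly interpretable cross-product.
* **Direction-matching 2×2 tables** cross the CRE score direction with the
  DE (or QTL) direction, so OR > 1 means "matching" and the one-sided test
  is a matching enrichment. An alternative binomial-against-0.5 formulation
  gives similar answers for balanced margins; the Fisher layout keeps every
  enrichment on the same footing.
* **Weir–Cockerham F_ST** pools the subpopulations of each continental group
  before estimation (the contrast of interest is between-continent), clamps
  negative estimates to zero, and returns NA for monomorphic sites. The
  empirical quantile threshold uses R's type-7 linear interpolation.
* **Replicate-shuffle FDR**: one AFR population is held out per pair with
  both replicates in the group of eight, each remaining population splits
  its replicates at random — preserving the 8-vs-6 structure so the null
  t-distribution matches the real contrast. One shuffle per pair by default;
  the seed is an argument and the procedure is deterministic given it.

# Calibration testing

Under a null configuration (no injected effects, no divergence) the test
suite checks three things. First, the rejection rate of the Welch tests at
p < 0.05 stays within 1.5 percentage points of nominal for all four score
types, and the shuffle FDR is close to 1. Second, the marginal p-value
distribution is uniform by a Kolmogorov–Smirnov test — applied to an
independence-thinned subsample (one pair per gene and per CRE) because pairs
sharing elements, bins or neighbourhoods are strongly dependent and t-tests
on quantile-normalized (rank-discretized) data are only approximately
uniform in the bulk; at the full 11k-pair scale the KS test has power to
detect these structural dependencies even though the error-rate calibration
that matters for inference is intact. Third, the enrichment machinery
rejects at ≈ 5% on independent null direction data over 200 seeds.

Positive controls inject 2-fold effects into 10% of elements with full
coupling: at least 90% of detected flagged accessibility pairs must match the
injected direction, and the DE-overlap, DE-direction and QTL-direction
enrichments must all return OR > 1 with p < 0.05.

# Problem sizes

Unit tests run on a 2 × 2-Mb genome (40 genes, 400 peaks; seconds per run).
Calibration and recovery tests use the default 16 × 6-Mb configuration
(~11,000 retained pairs; about a minute per study). These sizes were chosen
once as the smallest studies in which all strata of the 2×2 tables are
populated and Monte-Carlo error is small relative to the asserted tolerances.

# Known limitations

* The pipeline consumes called peaks with summits and binned contact maps;
  peak calling and read mapping are out of scope.
* ChIP-channel effects propagate to sibling elements through the
  compositional normalization — a feature of the score definition, but it
  means "number of diff-ChIP pairs" counts genes, not independent elements;
  the bin-level deduplication (`dedup_by_bin()`) exists for exactly this
  reason.
* iHS-style haplotype statistics are not computed; `wilcoxon_compare()` is
  generic enough to compare externally supplied scores.
* The generator treats pooled libraries as single samples with
  negative-binomial noise; within-pool growth variance of individual cell
  lines is not modelled.
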