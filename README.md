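# diffabc

Differential activity-by-contact (ABC) analysis of enhancer–gene regulation
between human ancestries.

## The problem

Most trait-associated and putatively adaptive variants in humans are
non-coding, and selection acting on *cis*-regulatory elements may be easier to
see at the level of chromatin than at the level of DNA sequence. `diffabc`
implements a chromatin-level selection test for pooled two-ancestry designs
(e.g. lymphoblastoid cell lines from African- and European-ancestry
populations assayed by ATAC-seq and H3K27ac HiChIP): it links candidate
*cis*-regulatory elements (CREs) to target genes with ABC scores, decomposes
each score into accessibility, activity and contact components, tests every
component for between-ancestry differences, and asks whether those differences
line up with differential expression, transcription-factor binding QTL and
allele-frequency divergence (F_ST) in ways that genetic drift would not
produce.

The package is aimed at regulatory/population genomicists who want to run the
pipeline on their own peak/contact tables, and it ships a fully specified
synthetic-data generator so that every stage can be exercised and calibrated
with known injected effects.

## The model

For every element E within 5 Mb of a gene G's TSS, per sample:

    ABC_{E,G}  =  A_E Q_{E,G}                 / Σ_e A_e Q_{e,G}
    ATAC_{E,G} =  A_E                         / Σ_e A_e
    ChIP_{E,G} =  √(H_E H_G)                  / Σ_e √(H_e H_G)
    HiC_{E,G}  =  (C_{E,G} / √(H_E H_G))      / Σ_e (C_{e,G} / √(H_e H_G))

where A is quantile-normalized ATAC reads-per-million at E, H the
quantile-normalized HiChIP 5-kb-bin total (the vanilla-coverage-sqrt, VC-sqrt,
estimate of H3K27ac signal), C the quantile-normalized valid *cis*-pair count
connecting E's bin to G's promoter bin, and Q the quantitative HiChIP signal
(per-gene sum-normalized, max-scaled contacts). Each score is the fraction of
the gene's regulatory input contributed by E, so scores sum to 1 over a gene's
elements.

Downstream: Welch t-tests per score type (EUR vs AFR samples), a
replicate-shuffle permutation FDR that preserves the 8-vs-6 group structure,
one-sided Fisher enrichment tests for differential-expression overlap and
direction matching, binding-QTL direction tests (optionally restricted to the
top 5% of per-site Weir–Cockerham F_ST), binomial sign tests, and one-sided
Wilcoxon comparisons of F_ST between CRE classes.

## Worked example

```r
library(diffabc)

cfg <- sim_config(effect_fraction = 0.1, effect_log2fc = 1, coupling = 1, seed = 11)
sim <- sim_abc_data(cfg)
res <- abc_pipeline(sim)
print(res)
#> <abc_analysis>
#>   2735 CREs; 265554 candidate pairs scored, 11237 retained after filters
#>   diff pairs at p<0.05: abc=1602, atac=995, chip=2382, hic=1060

estimate_fdr(res$pairs, sim$samples, seed = 7)   # shuffle FDR per score type

top <- top_diff_cres(res$diff, "atac", collapse_cre = TRUE)
direction_match_test(top, sim$de, context = "ctx01")
#> label                      a  b  c  d  odds_ratio  p
#> direction_match:ctx01:all  44 15 12 46   11.2      3.5e-09
```

The printed pipeline summary says how many candidate element–gene pairs
survived the candidacy filters (ABC ≥ 0.015 in ≥ 1 sample, promoter pairs
≥ 0.1, non-zero contact and ATAC support in all 14 samples) and how many are
nominally differential per score type. Because this run injected 2-fold
activity effects into 10% of elements with full coupling, the
direction-matching enrichment is strongly positive (OR ≈ 11): elements with
higher scores in one ancestry overwhelmingly have target genes more highly
expressed in the same ancestry. On a null configuration
(`effect_fraction = 0`) the same test rejects at the nominal 5% rate and the
shuffle FDR is ≈ 1.

Per-site F_ST uses the Weir–Cockerham (1984) estimator on pooled ancestry
genotype counts:

```r
wc_fst(n1 = 50, ac1 = 0, het1 = 0, n2 = 50, ac2 = 100, het2 = 0)  # fixed difference
#> [1] 1
wc_fst(n1 = 50, ac1 = 20, het1 = 16, n2 = 50, ac2 = 20, het2 = 16) # identical groups
#> [1] 0
```

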