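#' Per-site Weir-Cockerham F_ST between two pooled groups
#'
#' The Weir & Cockerham (1984) per-site estimator theta-hat = a / (a + b + c)
#' computed from the among-population (a), among-individual (b) and
#' within-individual (c) variance components over two groups (here the pooled
#' AFR and pooled EUR sample sets), using observed heterozygote counts.
#' Monomorphic sites (a + b + c = 0) return `NA`; negative estimates are
#' adjusted to zero, so a site fixed for different alleles in the two groups
#' gives exactly 1 and identical genotype counts give 0.
#'
#' @param n1,n2 Diploid sample sizes per group (vectors over sites).
#' @param ac1,ac2 Alternate-allele counts per group (0..2n).
#' @param het1,het2 Observed heterozygote counts per group.
#' @param clamp Adjust negative estimates to zero (default TRUE).
#' @return Numeric vector of F_ST values in \[0, 1\], `NA` where undefined.
#' @export
wc_fst <- function(n1, ac1, het1, n2, ac2, het2, clamp = TRUE) {
  if (any(n1 <= 0) || any(n2 <= 0)) {
    abort("wc_fst: both groups need at least one diploid individual")
  }
  r <- 2
  p1 <- ac1 / (2 * n1)
  p2 <- ac2 / (2 * n2)
  h1 <- het1 / n1
  h2 <- het2 / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  # finite-sample corrections with a zero numerator contribute nothing even
  # when nbar = 1 (avoids 0/0 at fixed differences with single individuals)
  corr_a <- pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4
  corr_b <- pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar
  a <- (nbar / nc) * (s2 - ifelse(corr_a == 0, 0, corr_a / (nbar - 1)))
  b <- ifelse(corr_b == 0, 0, (nbar / (nbar - 1)) * corr_b)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- ifelse(denom == 0, NA_real_, a / denom)
  if (clamp) fst <- pmin(pmax(fst, 0), 1)
  fst
}

#' Per-site F_ST for a variant table
#'
#' Convenience wrapper of [wc_fst()] over the pooled-ancestry genotype
#' summaries of a variant tibble (columns `n_AFR`, `ac_AFR`, `het_AFR`,
#' `n_EUR`, `ac_EUR`, `het_EUR`). Sites with undefined estimates are removed.
#'
#' @param variants Variant tibble (see [sim_variants()]).
#' @return The input restricted to defined sites, with an `fst` column.
#' @export
variant_fst <- function(variants) {
  variants |>
    mutate(fst = wc_fst(
      .data$n_AFR, .data$ac_AFR, .data$het_AFR,
      .data$n_EUR, .data$ac_EUR, .data$het_EUR
    )) |>
    filter(!is.na(.data$fst))
}

#' Maximum per-site F_ST per CRE
#'
#' @param variants Variant tibble with `chrom`, `pos`, `fst`.
#' @param cres CRE tibble.
#' @return Tibble `cre_id`, `fst_max` (`NA` for CREs containing no variant).
#' @export
max_fst_per_cre <- function(variants, cres) {
  hits <- purrr::map_dfr(unique(cres$chrom), function(ch) {
    vv <- variants[variants$chrom == ch, ]
    cc <- cres[cres$chrom == ch, ]
    if (nrow(vv) == 0 || nrow(cc) == 0) return(NULL)
    ov <- IRanges::findOverlaps(
      ir_of(vv$pos, vv$pos + 1), ir_of(cc$start, cc$end)
    )
    tibble(
      cre_id = cc$cre_id[S4Vectors::subjectHits(ov)],
      fst = vv$fst[S4Vectors::queryHits(ov)]
    )
  })
  hits |>
    group_by(.data$cre_id) |>
    summarise(fst_max = max(.data$fst), .groups = "drop") |>
    right_join(tibble(cre_id = cres$cre_id), by = "cre_id") |>
    arrange(match(.data$cre_id, cres$cre_id))
}

#' One-sided Wilcoxon rank-sum comparison of two F_ST distributions
#'
#' Tests the alternative that group A is stochastically greater than group B.
#' Small tie-free samples use the exact null distribution; larger samples or
#' ties use the normal approximation with mid-ranks and continuity
#' correction (the `stats::wilcox.test` conventions).
#'
#' @param a,b Numeric vectors.
#' @return One-row tibble `n_a`, `n_b`, `w`, `p` (`NA` if a group is empty).
#' @export
wilcoxon_compare <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    return(tibble(n_a = length(a), n_b = length(b), w = NA_real_, p = NA_real_))
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "greater"))
  tibble(n_a = length(a), n_b = length(b), w = unname(wt$statistic), p = wt$p.value)
}

#' Decile-binned diff vs non-diff F_ST comparisons
#'
#' Controls for allele frequency: the combined set of QTL records is split
#' into 10 decile bins of mean allele frequency across ancestries (ties at
#' boundaries resolved by rank; if every frequency is identical, all records
#' fall into bin 1), and a one-sided Wilcoxon test of diff versus non-diff
#' F_ST is run within each bin. Bins with fewer than two observations on
#' either side give `NA`.
#'
#' @param records Tibble with `fst`, `af_AFR`, `af_EUR` and a logical `diff`
#'   column marking records in diff-CREs.
#' @return Tibble `bin`, `n_diff`, `n_nondiff`, `mean_diff`, `mean_nondiff`,
#'   `p`, one row per decile.
#' @export
decile_binned_tests <- function(records) {
  af <- (records$af_AFR + records$af_EUR) / 2
  bin <- if (length(unique(af)) == 1) {
    rep(1L, length(af))
  } else {
    dplyr::ntile(af, 10)
  }
  records |>
    mutate(bin = bin) |>
    group_by(.data$bin) |>
    summarise(
      n_diff = sum(.data$diff),
      n_nondiff = sum(!.data$diff),
      mean_diff = mean(.data$fst[.data$diff]),
      mean_nondiff = mean(.data$fst[!.data$diff]),
      p = if (sum(.data$diff) >= 2 && sum(!.data$diff) >= 2) {
        wilcoxon_compare(.data$fst[.data$diff], .data$fst[!.data$diff])$p
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    tidyr::complete(bin = 1:10, fill = list(n_diff = 0L, n_nondiff = 0L))
}

#' Empirical F_ST quantile threshold
#'
#' Empirical quantile (linear interpolation of the empirical CDF, R type 7)
#' of per-site F_ST over the supplied variants, used to restrict direction
#' tests to the most ancestry-divergent sites (q = 0.95 keeps the top 5%).
#'
#' @param fst Numeric vector of per-site F_ST values of variants in CREs.
#' @param q Quantile in (0, 1\].
#' @return The threshold value.
#' @export
fst_quantile_threshold <- function(fst, q = 0.95) {
  fst <- fst[!is.na(fst)]
  if (length(fst) == 0) abort("fst_quantile_threshold: no F_ST values supplied")
  unname(quantile(fst, q, type = 7))
}
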