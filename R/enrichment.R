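#' One-sided Fisher's exact (hypergeometric) enrichment test
#'
#' Tests a 2x2 table `[[a, b], [c, d]]` for enrichment: the p-value is the
#' upper hypergeometric tail P(X >= a), the odds ratio is the sample estimate
#' ad/bc (infinite when bc = 0; this differs from the conditional MLE that
#' `fisher.test` reports), and `ci_lower` is the exact one-sided 95% lower
#' confidence bound on the odds ratio from noncentral hypergeometric
#' inversion. A zero margin makes the odds ratio undefined: p = 1 and
#' `degenerate = TRUE`.
#'
#' @param a,b,c,d Nonnegative integer cell counts: `a` successes among the
#'   focal group, `b` failures among it, `c`/`d` the same for the reference
#'   group.
#' @param label Optional test label.
#' @return One-row tibble of class `abc_enrichment`: counts, `odds_ratio`,
#'   `p`, `ci_lower`, `n_total`, `degenerate`.
#' @export
fisher_one_sided <- function(a, b, c, d, label = NA_character_) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    out <- tibble(
      label = label, a = a, b = b, c = c, d = d,
      odds_ratio = NA_real_, p = 1, ci_lower = NA_real_,
      n_total = a + b + c + d, degenerate = TRUE
    )
    return(structure(out, class = c("abc_enrichment", class(out))))
  }
  ft <- fisher.test(tab, alternative = "greater")
  out <- tibble(
    label = label, a = a, b = b, c = c, d = d,
    odds_ratio = if (b * c == 0) Inf else (a * d) / (b * c),
    p = ft$p.value, ci_lower = ft$conf.int[1],
    n_total = a + b + c + d, degenerate = FALSE
  )
  structure(out, class = c("abc_enrichment", class(out)))
}

#' CRE-level differential status for enrichment tests
#'
#' Collapses pair-level differential results of one score type to the CRE
#' level: a CRE's p is the minimum over its pairs (direction taken from the
#' minimizing pair), `status` is `"diff"` below `alpha`, `"nondiff"` at or
#' above `nondiff`, and `NA` in between (excluded from 2x2 tables). For the
#' bin-resolved ChIP/HiC scores set `dedup = TRUE` to count CREs from the
#' same 5-kb bin once (see [dedup_by_bin()]).
#'
#' @param diff_results An `abc_diff` tibble.
#' @param score_type Score type.
#' @param alpha,nondiff Thresholds (defaults 0.05 / 0.5).
#' @param dedup Apply bin deduplication first.
#' @return Tibble `cre_id`, `p`, `direction`, `element_class`, `status`.
#' @export
cre_diff_status <- function(diff_results, score_type, alpha = 0.05,
                            nondiff = 0.5, dedup = score_type %in% c("chip", "hic")) {
  d <- if (dedup) {
    dedup_by_bin(diff_results, score_type)
  } else {
    filter(diff_results, .data$score_type == !!score_type)
  }
  d |>
    arrange(.data$p, .data$pair_id) |>
    group_by(.data$cre_id) |>
    summarise(
      p = .data$p[1], direction = .data$direction[1],
      element_class = .data$element_class[1], .groups = "drop"
    ) |>
    mutate(status = case_when(
      .data$p < alpha ~ "diff",
      .data$p >= nondiff ~ "nondiff",
      TRUE ~ NA_character_
    ))
}

# per-CRE success flags for a DE context under a class filter
de_success_flags <- function(top, de_table, context = NULL, lfsr_max = 0.05) {
  de_genes <- de_table
  if (!is.null(context)) de_genes <- filter(de_genes, .data$context == !!context)
  de_genes <- de_genes |>
    filter(.data$lfsr < lfsr_max) |>
    distinct(.data$gene_id, .data$de_sign)
  top |>
    mutate(de_targets = purrr::map(
      .data$targets,
      ~ inner_join(.x, de_genes, by = "gene_id")
    ))
}

#' Enrichment of DE target genes among differential CREs
#'
#' One CRE counts once: per gene the most differential CRE is taken
#' ([top_diff_cres()] with `collapse_cre = TRUE`), then the 2x2 table crosses
#' differential status (diff: p < `alpha`; non-diff: p >= `nondiff`;
#' in-between excluded) with having at least one DE target gene
#' (LFSR < `lfsr_max`). `class_filter = "promoter"` restricts to
#' promoter-class CREs and requires the CRE to be the promoter of a DE target
#' to count as a success; `"enhancer"` counts a success only when the CRE is
#' the promoter of none of its DE targets, so a distal promoter of another
#' gene acts as an enhancer.
#'
#' @param top Collapsed top-CRE tibble from
#'   `top_diff_cres(..., collapse_cre = TRUE)`.
#' @param de_table Tibble `gene_id`, `context`, `de_sign`, `lfsr`.
#' @param context Context to test (`NULL` = whole table).
#' @param class_filter `"all"`, `"promoter"` or `"enhancer"`.
#' @param alpha,nondiff,lfsr_max Thresholds.
#' @return One-row `abc_enrichment` tibble (p = NA with a warning when a
#'   stratum is empty).
#' @export
de_overlap_test <- function(top, de_table, context = NULL,
                            class_filter = c("all", "promoter", "enhancer"),
                            alpha = 0.05, nondiff = 0.5, lfsr_max = 0.05) {
  class_filter <- match.arg(class_filter)
  u <- de_success_flags(top, de_table, context, lfsr_max) |>
    mutate(status = case_when(
      .data$p < alpha ~ "diff",
      .data$p >= nondiff ~ "nondiff",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$status))
  if (class_filter == "promoter") {
    u <- filter(u, .data$element_class == "promoter") |>
      mutate(success = purrr::map_lgl(.data$de_targets, ~ any(.x$is_promoter_pair)))
  } else if (class_filter == "enhancer") {
    u <- mutate(u, success = purrr::map_lgl(
      .data$de_targets, ~ nrow(.x) > 0 && !any(.x$is_promoter_pair)
    ))
  } else {
    u <- mutate(u, success = purrr::map_int(.data$de_targets, nrow) > 0)
  }
  label <- paste0("de_overlap", if (!is.null(context)) paste0(":", context), ":", class_filter)
  if (!any(u$status == "diff") || !any(u$status == "nondiff")) {
    warn(sprintf("de_overlap_test: empty stratum for %s", label))
    return(na_enrichment(label))
  }
  fisher_one_sided(
    sum(u$status == "diff" & u$success), sum(u$status == "diff" & !u$success),
    sum(u$status == "nondiff" & u$success), sum(u$status == "nondiff" & !u$success),
    label = label
  )
}

na_enrichment <- function(label) {
  out <- tibble(
    label = label, a = NA_integer_, b = NA_integer_, c = NA_integer_,
    d = NA_integer_, odds_ratio = NA_real_, p = NA_real_,
    ci_lower = NA_real_, n_total = 0L, degenerate = TRUE
  )
  structure(out, class = c("abc_enrichment", class(out)))
}

#' Enrichment of matching ancestry direction between diff-CREs and DE
#'
#' Universe: diff-CREs (p < `alpha`) whose DE target genes all share one DE
#' direction (CREs with opposite-sign targets are excluded). The 2x2 table
#' crosses the CRE's score direction (AFR/EUR) with the DE direction; an
#' odds ratio above 1 means directions match more often than chance, tested
#' one-sided.
#'
#' @inheritParams de_overlap_test
#' @return One-row `abc_enrichment` tibble.
#' @export
direction_match_test <- function(top, de_table, context = NULL,
                                 class_filter = c("all", "promoter", "enhancer"),
                                 alpha = 0.05, lfsr_max = 0.05) {
  class_filter <- match.arg(class_filter)
  u <- de_success_flags(top, de_table, context, lfsr_max) |>
    filter(.data$p < alpha) |>
    mutate(n_de = purrr::map_int(.data$de_targets, nrow)) |>
    filter(.data$n_de > 0) |>
    mutate(
      de_dirs = purrr::map(.data$de_targets, ~ unique(.x$de_sign)),
      consistent = purrr::map_int(.data$de_dirs, length) == 1
    ) |>
    filter(.data$consistent) |>
    mutate(de_direction = purrr::map_chr(.data$de_dirs, 1))
  if (class_filter == "promoter") {
    u <- filter(u, purrr::map_lgl(.data$de_targets, ~ any(.x$is_promoter_pair)))
  } else if (class_filter == "enhancer") {
    u <- filter(u, purrr::map_lgl(.data$de_targets, ~ !any(.x$is_promoter_pair)))
  }
  label <- paste0("direction_match", if (!is.null(context)) paste0(":", context), ":", class_filter)
  direction_table(u$direction, u$de_direction, label)
}

# 2x2 of (CRE direction) x (other direction); OR > 1 <=> matching enrichment
direction_table <- function(cre_dir, other_dir, label) {
  a <- sum(cre_dir == "AFR" & other_dir == "AFR")
  b <- sum(cre_dir == "AFR" & other_dir == "EUR")
  c <- sum(cre_dir == "EUR" & other_dir == "AFR")
  d <- sum(cre_dir == "EUR" & other_dir == "EUR")
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (sum(tab) < 2 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn(sprintf("direction test: margin too small for %s", label))
    return(na_enrichment(label))
  }
  fisher_one_sided(a, b, c, d, label = label)
}

# map QTL of one type to their containing CRE; keep the lowest-p QTL per CRE
qtl_in_cres <- function(qtl, variants, cres, qtl_type = NULL) {
  q <- qtl
  if (!is.null(qtl_type)) {
    if (!qtl_type %in% q$qtl_type) {
      abort(sprintf("unknown qtl_type '%s'", qtl_type))
    }
    q <- filter(q, .data$qtl_type == !!qtl_type)
  }
  q <- inner_join(q, select(variants, "variant_id", "chrom", "pos"),
    by = "variant_id"
  )
  hits <- purrr::map_dfr(unique(q$chrom), function(ch) {
    qq <- q[q$chrom == ch, ]
    cc <- cres[cres$chrom == ch, ]
    if (nrow(cc) == 0 || nrow(qq) == 0) return(NULL)
    ov <- IRanges::findOverlaps(
      ir_of(qq$pos, qq$pos + 1), ir_of(cc$start, cc$end)
    )
    bind_cols(
      qq[S4Vectors::queryHits(ov), ],
      tibble(cre_id = cc$cre_id[S4Vectors::subjectHits(ov)])
    )
  })
  hits
}

#' Enrichment of QTL-containing CREs among differential CREs
#'
#' The 2x2 table crosses CRE differential status (diff vs non-diff, see
#' [cre_diff_status()]) with containing at least one QTL of the given type.
#' When a CRE holds several QTL of the type, the one with the lowest QTL
#' p-value represents it (relevant for the downstream direction tests).
#'
#' @param diff_results An `abc_diff` tibble.
#' @param score_type Score type defining diff status (ChIP/HiC are bin-
#'   deduplicated).
#' @param cres CRE tibble.
#' @param qtl QTL tibble (`variant_id`, `qtl_type`, `qtl_p`, `direction`).
#' @param variants Variant tibble (`variant_id`, `chrom`, `pos`).
#' @param qtl_type QTL type to test.
#' @param class_filter Restrict the CRE universe by element class.
#' @param alpha,nondiff Thresholds.
#' @return One-row `abc_enrichment` tibble.
#' @export
qtl_overlap_test <- function(diff_results, score_type, cres, qtl, variants,
                             qtl_type,
                             class_filter = c("all", "promoter", "enhancer"),
                             alpha = 0.05, nondiff = 0.5) {
  class_filter <- match.arg(class_filter)
  status <- cre_diff_status(diff_results, score_type,
    alpha = alpha, nondiff = nondiff
  ) |>
    filter(!is.na(.data$status))
  if (class_filter != "all") {
    status <- filter(status, .data$element_class == class_filter)
  }
  hits <- qtl_in_cres(qtl, variants, cres, qtl_type) |>
    distinct(.data$cre_id)
  u <- mutate(status, success = .data$cre_id %in% hits$cre_id)
  fisher_one_sided(
    sum(u$status == "diff" & u$success), sum(u$status == "diff" & !u$success),
    sum(u$status == "nondiff" & u$success), sum(u$status == "nondiff" & !u$success),
    label = paste0("qtl_overlap:", qtl_type, ":", score_type, ":", class_filter)
  )
}

#' Enrichment of matching direction between diff-CRE scores and QTL alleles
#'
#' Universe: diff-CREs containing at least one QTL of the type with a defined
#' direction (the ancestry where the high-affinity allele is more frequent);
#' CREs whose QTL disagree in direction are excluded. The 2x2 table crosses
#' the QTL direction with the CRE score direction, one-sided for matching.
#' Optionally the universe is restricted to QTL whose per-site F_ST is at or
#' above the `fst_quantile` quantile of F_ST over all variants in CREs (the
#' top-5% test uses `fst_quantile = 0.95`).
#'
#' @inheritParams qtl_overlap_test
#' @param variant_fst Tibble `variant_id`, `fst` (required when
#'   `fst_quantile` is given; the threshold is computed over the variants
#'   located in CREs).
#' @param fst_quantile Optional quantile in (0, 1).
#' @return One-row `abc_enrichment` tibble.
#' @export
qtl_direction_match_test <- function(diff_results, score_type, cres, qtl,
                                     variants, qtl_type,
                                     class_filter = c("all", "promoter", "enhancer"),
                                     variant_fst = NULL, fst_quantile = NULL,
                                     alpha = 0.05, nondiff = 0.5) {
  class_filter <- match.arg(class_filter)
  hits <- qtl_in_cres(qtl, variants, cres, qtl_type) |>
    filter(!is.na(.data$direction))
  if (!is.null(fst_quantile)) {
    if (fst_quantile <= 0 || fst_quantile >= 1) {
      abort("qtl_direction_match_test: fst_quantile must be in (0, 1)")
    }
    if (is.null(variant_fst)) {
      abort("qtl_direction_match_test: variant_fst required with fst_quantile")
    }
    in_cre <- qtl_variants_in_cres(variants, cres)
    thr <- fst_quantile_threshold(
      variant_fst$fst[variant_fst$variant_id %in% in_cre], fst_quantile
    )
    hits <- hits |>
      left_join(variant_fst, by = "variant_id") |>
      filter(!is.na(.data$fst), .data$fst >= thr)
  }
  status <- cre_diff_status(diff_results, score_type,
    alpha = alpha, nondiff = nondiff
  ) |>
    filter(.data$status == "diff")
  if (class_filter != "all") {
    status <- filter(status, .data$element_class == class_filter)
  }
  per_cre <- hits |>
    inner_join(select(status, "cre_id", cre_direction = "direction"),
      by = "cre_id"
    ) |>
    group_by(.data$cre_id) |>
    filter(n_distinct(.data$direction) == 1) |>
    arrange(.data$qtl_p) |>
    slice(1) |>
    ungroup()
  direction_table(
    per_cre$cre_direction, per_cre$direction,
    paste0(
      "qtl_direction:", qtl_type, ":", score_type, ":", class_filter,
      if (!is.null(fst_quantile)) sprintf(":fst>=q%.2f", fst_quantile)
    )
  )
}

# variant ids located inside CREs
qtl_variants_in_cres <- function(variants, cres) {
  purrr::map(unique(cres$chrom), function(ch) {
    vv <- variants[variants$chrom == ch, ]
    cc <- cres[cres$chrom == ch, ]
    if (nrow(vv) == 0 || nrow(cc) == 0) return(character(0))
    keep <- IRanges::overlapsAny(
      ir_of(vv$pos, vv$pos + 1), ir_of(cc$start, cc$end)
    )
    vv$variant_id[keep]
  }) |>
    unlist()
}

#' Binomial sign test for ancestry bias of matching QTL alleles
#'
#' Tests whether, among QTL matching diff-CRE direction, the high-affinity
#' allele is at higher frequency in AFR more often than the background
#' proportion observed across all CREs: an exact two-sided binomial test of
#' k AFR-direction matches out of n, against the background AFR proportion
#' p0.
#'
#' @param matching_diff Character vector (or tibble with `direction`) of
#'   directions of matching QTL in diff-CREs.
#' @param background Same, for matching QTL across all CREs.
#' @return One-row tibble `k`, `n`, `p0`, `p` (`p` is `NA` when n = 0 or the
#'   background proportion is undefined).
#' @export
sign_test <- function(matching_diff, background) {
  dir_of <- function(x) if (is.data.frame(x)) x$direction else x
  d <- dir_of(matching_diff)
  bg <- dir_of(background)
  k <- sum(d == "AFR", na.rm = TRUE)
  n <- sum(d %in% c("AFR", "EUR"))
  nbg <- sum(bg %in% c("AFR", "EUR"))
  p0 <- if (nbg > 0) sum(bg == "AFR", na.rm = TRUE) / nbg else NA_real_
  p <- if (n > 0 && !is.na(p0)) binom.test(k, n, p0)$p.value else NA_real_
  tibble(k = k, n = n, p0 = p0, p = p)
}

#' Bonferroni-corrected significance stars
#'
#' Stars follow thresholds 0.05, 0.005, 5e-4 and 5e-5 on the
#' Bonferroni-corrected p-value.
#'
#' @param p Raw p-values.
#' @param n_tests Family size for the correction.
#' @return Tibble `bonferroni_p`, `stars`.
#' @export
enrichment_stars <- function(p, n_tests) {
  bp <- pmin(p * n_tests, 1)
  stars <- dplyr::case_when(
    bp < 5e-5 ~ "****",
    bp < 5e-4 ~ "***",
    bp < 0.005 ~ "**",
    bp < 0.05 ~ "*",
    TRUE ~ ""
  )
  tibble(bonferroni_p = bp, stars = stars)
}
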