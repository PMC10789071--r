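# Welch statistics from group summaries; vectorized over pairs.
welch_from_stats <- function(mE, vE, nE, mA, vA, nA) {
  se2 <- vE / nE + vA / nA
  t <- (mE - mA) / sqrt(se2)
  df <- se2^2 / ((vE / nE)^2 / (nE - 1) + (vA / nA)^2 / (nA - 1))
  p <- 2 * pt(-abs(t), df)
  degenerate <- se2 == 0
  # both variances zero: equal means -> no evidence; unequal -> off-scale
  t[degenerate & mE == mA] <- 0
  p[degenerate & mE == mA] <- 1
  t[degenerate & mE != mA] <- sign(mE - mA)[degenerate & mE != mA] * Inf
  p[degenerate & mE != mA] <- .Machine$double.xmin
  list(t = t, df = df, p = p, degenerate = degenerate)
}

group_stats <- function(x, idx) {
  n <- length(idx)
  m <- rowMeans(x[, idx, drop = FALSE])
  v <- rowSums((x[, idx, drop = FALSE] - m)^2) / (n - 1)
  list(m = m, v = v, n = n)
}

#' Welch two-sample test of one pair's scores between ancestries
#'
#' Unpaired, unequal-variance (Welch) t-test of EUR versus AFR samples with
#' the log2 fold change defined as log2(mean EUR / mean AFR). When both group
#' variances are zero the test is degenerate: equal means give t = 0, p = 1;
#' unequal means give the smallest representable p with `degenerate = TRUE`.
#' A zero group mean makes the fold change an infinite sentinel.
#'
#' @param values Numeric vector of per-sample scores.
#' @param ancestry Character vector (`"AFR"`/`"EUR"`) aligned with `values`.
#' @return One-row tibble with group stats, `t`, `df`, `p`, `log2fc`,
#'   `direction`, `diff_flag`, `nondiff_flag`, `degenerate`.
#' @export
diff_test <- function(values, ancestry) {
  stopifnot(length(values) == length(ancestry))
  iE <- which(ancestry == "EUR")
  iA <- which(ancestry == "AFR")
  if (length(iE) < 2 || length(iA) < 2) {
    abort("diff_test: need at least two samples per ancestry")
  }
  x <- matrix(values, nrow = 1)
  gE <- group_stats(x, iE)
  gA <- group_stats(x, iA)
  w <- welch_from_stats(gE$m, gE$v, gE$n, gA$m, gA$v, gA$n)
  lfc <- log2fc_of(gE$m, gA$m)
  tibble(
    mu_EUR = gE$m, mu_AFR = gA$m, var_EUR = gE$v, var_AFR = gA$v,
    n_EUR = gE$n, n_AFR = gA$n,
    t = w$t, df = w$df, p = w$p, log2fc = lfc,
    direction = ifelse(lfc < 0, "AFR", "EUR"),
    diff_flag = w$p < 0.05, nondiff_flag = w$p >= 0.5,
    degenerate = w$degenerate
  )
}

log2fc_of <- function(mE, mA) {
  lfc <- log2(mE / mA)
  lfc[mE == 0 & mA == 0] <- 0
  lfc
}

#' Differential score tests for all pairs and score types
#'
#' Runs the Welch test of [diff_test()] on every retained element-gene pair
#' for each score type, EUR versus AFR samples.
#'
#' @param scores (Filtered) score tibble from [define_eg_pairs()].
#' @param samples Sample sheet with `sample_id`, `ancestry`.
#' @param score_types Score columns to test.
#' @param alpha Nominal threshold defining diff pairs (default 0.05).
#' @param nondiff Threshold defining non-diff pairs (default 0.5).
#' @return Tibble of class `abc_diff`: one row per pair and score type with
#'   test statistics, `log2fc` (EUR over AFR), `direction`, flags and the
#'   element's 5-kb `bin_key` for deduplication.
#' @export
diff_scores <- function(scores, samples,
                        score_types = c("abc", "atac", "chip", "hic"),
                        alpha = 0.05, nondiff = 0.5) {
  meta <- scores |>
    distinct(
      .data$pair_id, .data$cre_id, .data$gene_id, .data$element_class,
      .data$is_promoter_pair,
      bin_key = .data$bin_E
    )
  iE <- which(samples$ancestry == "EUR")
  iA <- which(samples$ancestry == "AFR")
  out <- purrr::map_dfr(score_types, function(st) {
    wide <- scores |>
      select("pair_id", "sample_id", value = all_of(st)) |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
    x <- as.matrix(wide[, samples$sample_id, drop = FALSE])
    gE <- group_stats(x, iE)
    gA <- group_stats(x, iA)
    w <- welch_from_stats(gE$m, gE$v, gE$n, gA$m, gA$v, gA$n)
    lfc <- log2fc_of(gE$m, gA$m)
    tibble(
      pair_id = wide$pair_id, score_type = st,
      mu_EUR = gE$m, mu_AFR = gA$m,
      t = w$t, df = w$df, p = w$p, log2fc = lfc,
      direction = ifelse(lfc < 0, "AFR", "EUR"),
      diff_flag = w$p < alpha, nondiff_flag = w$p >= nondiff,
      degenerate = w$degenerate
    )
  })
  out <- left_join(out, meta, by = "pair_id")
  structure(out, class = c("abc_diff", class(out)), alpha = alpha, nondiff = nondiff)
}

#' Replicate-shuffle FDR for each score type
#'
#' Builds a null distribution that preserves the 8-versus-6 group structure
#' of the real AFR/EUR contrast while scrambling ancestry: for each pair, one
#' AFR population is held out at random and both of its replicates are placed
#' in the group of eight; every remaining population contributes one random
#' replicate to the group of eight and the other to the group of six. The
#' same Welch test is applied and the FDR at `alpha` is the ratio of null to
#' observed significant pairs.
#'
#' @param scores Filtered score tibble.
#' @param samples Sample sheet (must have two replicates per population).
#' @param score_types Score columns to test.
#' @param alpha Significance threshold (default 0.05).
#' @param n_shuffles Null tests per pair (default 1; more reduces the
#'   Monte-Carlo variance of the FDR estimate).
#' @param seed Integer seed for the shuffles.
#' @return Tibble `score_type`, `n_real_sig`, `n_null_sig`, `fdr_raw`, `fdr`
#'   (capped at 1; `NA` when no pair is significant in the real test).
#' @export
estimate_fdr <- function(scores, samples,
                         score_types = c("abc", "atac", "chip", "hic"),
                         alpha = 0.05, n_shuffles = 1, seed = 1L) {
  pops <- samples |>
    distinct(.data$population, .data$ancestry) |>
    arrange(.data$population)
  reps_per_pop <- samples |> count(.data$population)
  if (any(reps_per_pop$n != 2)) {
    abort("estimate_fdr: the replicate-shuffle null needs exactly 2 replicates per population")
  }
  afr_pops <- pops$population[pops$ancestry == "AFR"]
  other_idx <- function(held) setdiff(pops$population, held)
  # sample index pairs per population
  pop_samples <- split(seq_len(nrow(samples)), samples$population)

  wides <- lapply(score_types, function(st) {
    wide <- scores |>
      select("pair_id", "sample_id", value = all_of(st)) |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
    as.matrix(wide[, samples$sample_id, drop = FALSE])
  })
  names(wides) <- score_types
  n_pairs <- nrow(wides[[1]])
  iE <- which(samples$ancestry == "EUR")
  iA <- which(samples$ancestry == "AFR")
  n8 <- length(iA)
  n6 <- length(iE)

  real_sig <- vapply(score_types, function(st) {
    x <- wides[[st]]
    gE <- group_stats(x, iE)
    gA <- group_stats(x, iA)
    w <- welch_from_stats(gE$m, gE$v, gE$n, gA$m, gA$v, gA$n)
    sum(w$p < alpha)
  }, numeric(1))

  null_sig <- withr::with_seed(as.integer(seed), {
    totals <- setNames(numeric(length(score_types)), score_types)
    for (sh in seq_len(n_shuffles)) {
      held <- sample(afr_pops, n_pairs, replace = TRUE)
      m8 <- matrix(FALSE, n_pairs, nrow(samples))
      for (p in pops$population) {
        idx <- pop_samples[[p]]
        if (p %in% afr_pops) {
          rows <- held == p
          m8[rows, idx] <- TRUE # held-out population: both replicates in group of 8
          flip <- rbinom(sum(!rows), 1, 0.5) == 1
          m8[cbind(which(!rows), ifelse(flip, idx[1], idx[2]))] <- TRUE
        } else {
          flip <- rbinom(n_pairs, 1, 0.5) == 1
          m8[cbind(seq_len(n_pairs), ifelse(flip, idx[1], idx[2]))] <- TRUE
        }
      }
      stopifnot(all(rowSums(m8) == n8))
      for (st in score_types) {
        x <- wides[[st]]
        s8 <- rowSums(x * m8)
        q8 <- rowSums(x^2 * m8)
        m8m <- s8 / n8
        v8 <- (q8 - n8 * m8m^2) / (n8 - 1)
        s6 <- rowSums(x) - s8
        q6 <- rowSums(x^2) - q8
        m6m <- s6 / n6
        v6 <- (q6 - n6 * m6m^2) / (n6 - 1)
        w <- welch_from_stats(m8m, pmax(v8, 0), n8, m6m, pmax(v6, 0), n6)
        totals[st] <- totals[st] + sum(w$p < alpha)
      }
    }
    totals / n_shuffles
  })

  tibble(
    score_type = score_types,
    n_real_sig = as.integer(real_sig),
    n_null_sig = null_sig,
    fdr_raw = ifelse(real_sig > 0, null_sig / real_sig, NA_real_),
    fdr = ifelse(real_sig > 0, pmin(null_sig / real_sig, 1), NA_real_)
  )
}

#' Deduplicate differential calls sharing a 5-kb bin
#'
#' ChIP and HiC signal is resolved at 5-kb bins, so differential CREs from
#' the same bin are counted once: among diff-flagged results of the given
#' score type sharing a `bin_key`, the lowest-p representative is kept (ties
#' broken by smallest `pair_id`); non-flagged results pass through.
#'
#' @param diff_results An `abc_diff` tibble.
#' @param score_type One of `"chip"`, `"hic"` (any type accepted).
#' @return The deduplicated subset for that score type.
#' @export
dedup_by_bin <- function(diff_results, score_type) {
  d <- filter(diff_results, .data$score_type == !!score_type)
  flagged <- d |>
    filter(.data$diff_flag) |>
    arrange(.data$p, .data$pair_id) |>
    group_by(.data$bin_key) |>
    slice(1) |>
    ungroup()
  bind_rows(flagged, filter(d, !.data$diff_flag)) |>
    arrange(.data$pair_id)
}

#' Rank genes by their most differential CRE for gene-set enrichment
#'
#' Per gene, selects the top differential CRE of the given score type
#' (smallest p, ties by larger |log2fc| then coordinate) and ranks genes by
#' the Welch form statistic
#' \eqn{(\mu_{EUR} - \mu_{AFR}) / \sqrt{\sigma^2_{EUR}/n_{EUR} +
#' \sigma^2_{AFR}/n_{AFR}}} of that CRE's scores, from high-EUR to high-AFR.
#' Genes whose statistic is undefined (zero denominator) are dropped with a
#' warning.
#'
#' @param diff_results An `abc_diff` tibble.
#' @param score_type Which score type to rank on.
#' @return Tibble `gene_id`, `cre_id`, `stat`, sorted by decreasing
#'   statistic.
#' @export
gsea_rank_genes <- function(diff_results, score_type) {
  top <- top_diff_cres(diff_results, score_type, collapse_cre = FALSE)
  bad <- !is.finite(top$t)
  if (any(bad)) {
    warn(sprintf(
      "gsea_rank_genes: dropping %d gene(s) with undefined statistic", sum(bad)
    ))
    top <- top[!bad, ]
  }
  top |>
    transmute(.data$gene_id, .data$cre_id, stat = .data$t) |>
    arrange(desc(.data$stat))
}

#' Most differential CRE per gene
#'
#' For each gene with at least one candidate pair of the given score type,
#' selects the most differential CRE: smallest p, ties broken by larger
#' |log2fc|, then by coordinate (CRE id order).
#'
#' @param diff_results An `abc_diff` tibble.
#' @param score_type Score type to select on.
#' @param collapse_cre Collapse the per-gene selections to one row per CRE
#'   (keeping the minimum p and collecting target genes), the unit used by
#'   the enrichment tests.
#' @return Per-gene rows (default) or per-CRE rows with a `targets`
#'   list-column.
#' @export
top_diff_cres <- function(diff_results, score_type, collapse_cre = FALSE) {
  per_gene <- diff_results |>
    filter(.data$score_type == !!score_type) |>
    arrange(.data$p, desc(abs(.data$log2fc)), .data$cre_id) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup()
  if (!collapse_cre) {
    return(per_gene)
  }
  per_gene |>
    arrange(.data$p, .data$cre_id) |>
    group_by(.data$cre_id) |>
    summarise(
      p = .data$p[1], direction = .data$direction[1],
      log2fc = .data$log2fc[1], element_class = .data$element_class[1],
      bin_key = .data$bin_key[1],
      targets = list(tibble(
        gene_id = gene_id,
        is_promoter_pair = is_promoter_pair
      )),
      .groups = "drop"
    )
}
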