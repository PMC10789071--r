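#' Tidy a differential-score result
#'
#' @param x An `abc_diff` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-pair, per-score-type test results.
#' @method tidy abc_diff
#' @export
tidy.abc_diff <- function(x, ...) {
  as_tibble(x) |>
    select(
      "pair_id", "cre_id", "gene_id", "score_type", "t", "df", "p",
      "log2fc", "direction", "diff_flag", "nondiff_flag", "element_class"
    )
}

#' One-row summary of a differential-score result
#'
#' @param x An `abc_diff` tibble.
#' @param ... Unused.
#' @return Tibble with the pair count, thresholds and the fraction of
#'   diff-flagged tests per score type (wide).
#' @method glance abc_diff
#' @export
glance.abc_diff <- function(x, ...) {
  frac <- as_tibble(x) |>
    group_by(.data$score_type) |>
    summarise(prop = mean(.data$diff_flag), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "score_type", values_from = "prop",
      names_prefix = "prop_diff_"
    )
  bind_cols(
    tibble(
      n_pairs = dplyr::n_distinct(x$pair_id),
      n_tests = nrow(x),
      alpha = attr(x, "alpha") %||% 0.05,
      nondiff = attr(x, "nondiff") %||% 0.5
    ),
    frac
  )
}

#' Tidy an enrichment result
#'
#' @param x An `abc_enrichment` tibble (one or more rows).
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy abc_enrichment
#' @export
tidy.abc_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of an enrichment result
#'
#' @param x An `abc_enrichment` tibble.
#' @param ... Unused.
#' @return Tibble `label`, `odds_ratio`, `p`, `ci_lower`, `n_total`.
#' @method glance abc_enrichment
#' @export
glance.abc_enrichment <- function(x, ...) {
  as_tibble(x) |>
    select("label", "odds_ratio", "p", "ci_lower", "n_total")
}

#' Volcano plot of differential score tests
#'
#' @param diff_results An `abc_diff` tibble.
#' @param alpha Significance line.
#' @return A ggplot object, faceted by score type; log2 fold change (EUR
#'   over AFR) against -log10 p.
#' @export
plot_volcano <- function(diff_results, alpha = attr(diff_results, "alpha") %||% 0.05) {
  d <- as_tibble(diff_results) |>
    filter(is.finite(.data$log2fc), .data$p > 0)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$p),
    colour = .data$diff_flag
  )) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~score_type) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey40"), guide = "none"
    ) +
    ggplot2::labs(
      x = "log2 fold change (EUR / AFR)", y = "-log10 p",
      title = "Differential score tests"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot abc_diff
#' @export
autoplot.abc_diff <- function(object, ...) plot_volcano(object, ...)

#' Forest-style plot of enrichment odds ratios
#'
#' Odds ratios with the lower bound of the one-sided 95% confidence interval
#' (the upper bound of a one-sided test is infinite and is not drawn).
#'
#' @param enrichments Tibble of enrichment rows (e.g. several
#'   [fisher_one_sided()] results bound together).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichments) {
  d <- as_tibble(enrichments) |>
    filter(!.data$degenerate, is.finite(.data$odds_ratio))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$odds_ratio),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot abc_enrichment
#' @export
autoplot.abc_enrichment <- function(object, ...) plot_enrichment(object)

#' Boxplots of F_ST distributions by group
#'
#' @param records Tibble with `fst` and a grouping column `group`.
#' @return A ggplot object.
#' @export
plot_fst_compare <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$group, y = .data$fst)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = expression(F[ST])) +
    ggplot2::theme_minimal()
}
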