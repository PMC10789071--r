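#' Run the differential activity-by-contact pipeline on a synthetic study
#'
#' Convenience wrapper: defines CREs from the peak set, aggregates ATAC
#' counts per CRE, scores all candidate element-gene pairs, applies the pair
#' candidacy filters and runs the differential tests.
#'
#' @param sim An `abc_sim` from [sim_abc_data()] (or a list with the same
#'   elements built from real data files).
#' @param k Top elements retained in CRE definition (defaults to the full
#'   peak set).
#' @param window Scoring window in bp.
#' @param abc_min,promoter_abc_min Pair candidacy thresholds.
#' @param keep_universe Keep the unfiltered score table in the result
#'   (memory-heavy; default FALSE).
#' @return List of class `abc_analysis` with `cres`, `pairs` (filtered score
#'   table), `diff` (differential results), `n_universe` and the sample
#'   sheet.
#' @export
abc_pipeline <- function(sim, k = nrow(sim$peaks), window = 5e6,
                         abc_min = 0.015, promoter_abc_min = 0.1,
                         keep_universe = FALSE) {
  cres <- define_cres(
    sim$peaks, sim$atac_counts, sim$samples, sim$tss,
    sim$chrom_sizes, sim$blacklist,
    k = k
  )
  cre_counts <- cre_atac_counts(cres, sim$peaks, sim$atac_counts)
  scores <- score_pairs(
    cres, cre_counts, sim$contacts, sim$bins, sim$tss, sim$samples,
    window = window
  )
  pairs <- define_eg_pairs(scores, abc_min, promoter_abc_min)
  diff <- diff_scores(pairs, sim$samples)
  out <- list(
    cres = cres,
    pairs = pairs,
    diff = diff,
    n_universe = dplyr::n_distinct(scores$pair_id),
    samples = sim$samples
  )
  if (keep_universe) out$scores <- scores
  structure(out, class = "abc_analysis")
}

#' @export
print.abc_analysis <- function(x, ...) {
  cat("<abc_analysis>\n")
  cat(sprintf(
    "  %d CREs; %d candidate pairs scored, %d retained after filters\n",
    nrow(x$cres), x$n_universe, dplyr::n_distinct(x$pairs$pair_id)
  ))
  sig <- x$diff |>
    group_by(.data$score_type) |>
    summarise(n_diff = sum(.data$diff_flag), .groups = "drop")
  cat(sprintf(
    "  diff pairs at p<%.3g: %s\n", attr(x$diff, "alpha"),
    paste(sprintf("%s=%d", sig$score_type, sig$n_diff), collapse = ", ")
  ))
  invisible(x)
}
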