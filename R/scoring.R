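#' Quantile-normalize samples to the mean of their distributions
#'
#' Each sample (column) is normalized to the across-sample mean of order
#' statistics: a value at rank r is replaced by the mean of the r-th smallest
#' values over all samples, with ties receiving the average of the tied
#' reference values. When a `class` partition is supplied (enhancer/promoter),
#' normalization is carried out separately within each class, so the marginal
#' distribution is identical across samples within a class.
#'
#' @param x Numeric matrix, features in rows, samples in columns.
#' @param class Optional character/factor vector over rows partitioning the
#'   features (e.g. `"enhancer"`/`"promoter"`).
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(x, class = NULL) {
  x <- as.matrix(x)
  if (is.null(class)) class <- rep("all", nrow(x))
  stopifnot(length(class) == nrow(x))
  out <- x
  for (cl in unique(class)) {
    rows <- class == cl
    xi <- x[rows, , drop = FALSE]
    if (any(colSums(xi != 0) == 0) && nrow(xi) > 1) {
      abort(sprintf(
        "quantile_normalize: a sample has all-zero values in class '%s' (uninformative ranks)",
        cl
      ))
    }
    out[rows, ] <- limma::normalizeQuantiles(xi, ties = TRUE)
  }
  out
}

#' Assign CREs and gene promoters to contact-map bins
#'
#' Each CRE maps to the bin containing its midpoint; each gene maps to the
#' bin containing its TSS.
#'
#' @param cres CRE tibble (`cre_id`, `chrom`, `start`, `end`).
#' @param tss TSS tibble (`gene_id`, `chrom`, `tss`).
#' @param bins Bin tibble (`bin_id`, `chrom`, `start`, `end`), uniform width.
#' @return List with `cre_bins` (`cre_id`, `bin_id`) and `gene_bins`
#'   (`gene_id`, `bin_id`).
#' @export
assign_bins <- function(cres, tss, bins) {
  bs <- as.numeric(names(sort(table(bins$end - bins$start), decreasing = TRUE))[1])
  key <- function(chrom, pos) paste(chrom, (pos %/% bs) * bs)
  bin_key <- key(bins$chrom, bins$start)
  list(
    cre_bins = tibble(
      cre_id = cres$cre_id,
      bin_id = bins$bin_id[match(
        key(cres$chrom, (cres$start + cres$end) %/% 2), bin_key
      )]
    ),
    gene_bins = tibble(
      gene_id = tss$gene_id,
      bin_id = bins$bin_id[match(key(tss$chrom, tss$tss), bin_key)]
    )
  )
}

# symmetric per-bin contact totals (diagonal counted once), per sample
bin_totals <- function(contacts) {
  bind_rows(
    contacts |> select("sample_id", bin = "bin_i", "count"),
    contacts |>
      filter(.data$bin_i != .data$bin_j) |>
      select("sample_id", bin = "bin_j", "count")
  ) |>
    group_by(.data$sample_id, .data$bin) |>
    summarise(total = sum(.data$count), .groups = "drop")
}

#' Quantitative HiChIP signal per gene
#'
#' For each gene (and sample), the quantile-normalized contact counts of all
#' elements within the scoring window are normalized to sum to one and then
#' divided by their maximum, so the strongest contact of each gene has signal
#' 1 and everything is comparable across genes. A gene with no contacts gets
#' all-zero signal.
#'
#' @param components Tibble with at least `gene_id`, `sample_id` and `C`
#'   (quantile-normalized contact count per element-gene pair).
#' @return The input with a `Q` column appended.
#' @export
quantitative_hichip <- function(components) {
  components |>
    group_by(.data$gene_id, .data$sample_id) |>
    mutate(
      Q = {
        s <- sum(.data$C)
        if (s > 0) {
          q <- .data$C / s
          q / max(q)
        } else {
          rep(0, length(.data$C))
        }
      }
    ) |>
    ungroup()
}

#' Compute ABC, ATAC, ChIP and HiC scores from components
#'
#' For every element E within the scoring window of gene G (per sample):
#' \deqn{abc_E = A_E Q_{EG} / \sum_e A_e Q_{eG}}
#' \deqn{atac_E = A_E / \sum_e A_e}
#' \deqn{chip_E = \sqrt{H_E H_G} / \sum_e \sqrt{H_e H_G}}
#' \deqn{hic_E = (C_{EG}/\sqrt{H_E H_G}) / \sum_e (C_{eG}/\sqrt{H_e H_G})}
#' where A is quantile-normalized ATAC RPM, H the quantile-normalized HiChIP
#' bin total (VC-sqrt uses the geometric mean of the two anchors' totals), C
#' the quantile-normalized connecting contact count, and Q the quantitative
#' HiChIP signal. A zero denominator yields all-zero scores of that type for
#' the gene; each score type sums to 1 over a gene's elements otherwise.
#'
#' @param components Tibble with `gene_id`, `sample_id`, `A`, `Q`, `H_E`,
#'   `H_G`, `C`.
#' @return The input with `abc`, `atac`, `chip`, `hic` columns appended.
#' @export
compute_scores <- function(components) {
  vc <- sqrt(components$H_E * components$H_G)
  if (any(vc == 0 & components$C > 0)) {
    abort("compute_scores: a bin pair has contacts but zero bin total (inconsistent input)")
  }
  components |>
    mutate(
      .vc = vc,
      .hic_num = ifelse(.data$.vc > 0, .data$C / .data$.vc, 0)
    ) |>
    group_by(.data$gene_id, .data$sample_id) |>
    mutate(
      abc = norm_frac(.data$A * .data$Q),
      atac = norm_frac(.data$A),
      chip = norm_frac(.data$.vc),
      hic = norm_frac(.data$.hic_num)
    ) |>
    ungroup() |>
    select(-".vc", -".hic_num")
}

norm_frac <- function(x) {
  s <- sum(x)
  if (s > 0) x / s else rep(0, length(x))
}

#' Score all candidate element-gene pairs across samples
#'
#' End-to-end scoring: normalizes ATAC reads-per-million and HiChIP signals
#' by quantile normalization (separately for enhancer- and promoter-class
#' features), builds the pair universe of all CREs within `window` of each
#' gene's TSS (measured TSS to element midpoint), and computes the four
#' scores per sample.
#'
#' @param cres Classified CRE tibble from [define_cres()].
#' @param cre_counts Long tibble `cre_id`, `sample_id`, `count` (ATAC reads
#'   per CRE; see [cre_atac_counts()]).
#' @param contacts Contact tibble `sample_id`, `bin_i`, `bin_j`, `count`.
#' @param bins Bin tibble.
#' @param tss TSS tibble.
#' @param samples Sample sheet.
#' @param window Scoring window in bp (default 5 Mb).
#' @param total_reads Optional named vector of per-sample total mapped reads
#'   for the RPM normalization; defaults to each sample's total count over
#'   all CREs.
#' @return Score tibble: one row per (pair, sample) with ids, `element_class`
#'   (of E), `is_promoter_pair` (E is G's own promoter), `bin_E`, `bin_G`,
#'   components `A`, `Q`, `H_E`, `H_G`, `C` and scores `abc`, `atac`, `chip`,
#'   `hic`.
#' @export
score_pairs <- function(cres, cre_counts, contacts, bins, tss, samples,
                        window = 5e6, total_reads = NULL) {
  ba <- assign_bins(cres, tss, bins)
  cres <- left_join(cres, ba$cre_bins, by = "cre_id")

  # --- activity: quantile-normalized ATAC RPM per CRE
  cw <- cre_counts |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count") |>
    arrange(match(.data$cre_id, cres$cre_id))
  amat <- as.matrix(cw[, samples$sample_id, drop = FALSE])
  rownames(amat) <- cw$cre_id
  if (is.null(total_reads)) total_reads <- colSums(amat)
  rpm <- sweep(amat, 2, as.numeric(total_reads[colnames(amat)]) / 1e6, "/")
  aq <- quantile_normalize(rpm, cres$element_class[match(rownames(rpm), cres$cre_id)])

  # --- bin totals H over bins overlapping CREs / gene promoters
  used_bins <- sort(unique(c(ba$cre_bins$bin_id, ba$gene_bins$bin_id)))
  prom_bins <- unique(c(
    ba$cre_bins$bin_id[cres$element_class[match(ba$cre_bins$cre_id, cres$cre_id)] == "promoter"],
    ba$gene_bins$bin_id
  ))
  bt <- bin_totals(contacts) |>
    filter(.data$bin %in% used_bins) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "total")
  hmat <- matrix(0, length(used_bins), nrow(samples),
    dimnames = list(used_bins, samples$sample_id)
  )
  got <- intersect(samples$sample_id, colnames(bt))
  hmat[match(bt$bin, used_bins), got] <- as.matrix(bt[, got])
  hmat[is.na(hmat)] <- 0
  bin_class <- ifelse(used_bins %in% prom_bins, "promoter", "enhancer")
  hq <- quantile_normalize(hmat, bin_class)

  # --- pair universe: elements within `window` of each gene's TSS
  pairs <- inner_join(
    tss |> select("gene_id", "chrom", "tss"),
    cres |> select("cre_id", "chrom", "start", "end", "element_class", cre_bin = "bin_id"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    mutate(mid = (.data$start + .data$end) %/% 2) |>
    filter(abs(.data$tss - .data$mid) <= window) |>
    left_join(ba$gene_bins, by = "gene_id") |>
    rename(gene_bin = "bin_id") |>
    mutate(
      is_promoter_pair = .data$start < .data$tss + 501 & .data$end > .data$tss - 500,
      dist = abs(.data$tss - .data$mid),
      bin_lo = pmin(.data$cre_bin, .data$gene_bin),
      bin_hi = pmax(.data$cre_bin, .data$gene_bin),
      pair_id = paste(.data$cre_id, .data$gene_id, sep = ":")
    )

  # --- connecting contacts C, quantile-normalized over distinct bin pairs
  bp <- pairs |>
    group_by(.data$bin_lo, .data$bin_hi) |>
    summarise(
      class = if (any(bin_class[match(.data$cre_bin, used_bins)] == "promoter")) {
        "promoter"
      } else {
        "enhancer"
      },
      .groups = "drop"
    )
  craw <- matrix(0, nrow(bp), nrow(samples),
    dimnames = list(NULL, samples$sample_id)
  )
  cc <- contacts |>
    inner_join(bp |> mutate(row = row_number()),
      by = c(bin_i = "bin_lo", bin_j = "bin_hi")
    )
  craw[cbind(cc$row, match(cc$sample_id, samples$sample_id))] <- cc$count
  cq <- quantile_normalize(craw, bp$class)

  # --- assemble long component table
  bp_idx <- match(
    paste(pairs$bin_lo, pairs$bin_hi),
    paste(bp$bin_lo, bp$bin_hi)
  )
  n_s <- nrow(samples)
  long <- pairs[rep(seq_len(nrow(pairs)), each = n_s), ] |>
    mutate(sample_id = rep(samples$sample_id, times = nrow(pairs)))
  sidx <- match(long$sample_id, samples$sample_id)
  long$A <- aq[cbind(match(long$cre_id, rownames(aq)), sidx)]
  long$H_E <- hq[cbind(match(long$cre_bin, used_bins), sidx)]
  long$H_G <- hq[cbind(match(long$gene_bin, used_bins), sidx)]
  long$C <- cq[cbind(rep(bp_idx, each = n_s), sidx)]

  long |>
    quantitative_hichip() |>
    compute_scores() |>
    select(
      "pair_id", "cre_id", "gene_id", "sample_id", "element_class",
      "is_promoter_pair",
      bin_E = "cre_bin", bin_G = "gene_bin", "dist",
      "A", "Q", "H_E", "H_G", "C", "abc", "atac", "chip", "hic"
    )
}

#' Apply the element-gene pair candidacy filters
#'
#' A pair is retained iff (i) its ABC score is at least `abc_min` in at least
#' one sample, (ii) when the element is the gene's own promoter, its ABC
#' score reaches the stricter `promoter_abc_min` in at least one sample, and
#' (iii) its quantile-normalized contact count and ATAC value are non-zero in
#' every sample.
#'
#' @param scores Score tibble from [score_pairs()].
#' @param abc_min Minimum ABC score in at least one sample (default 0.015).
#' @param promoter_abc_min Minimum ABC score for promoter-gene pairs
#'   (default 0.1).
#' @return The filtered score tibble (all samples of the retained pairs).
#' @export
define_eg_pairs <- function(scores, abc_min = 0.015, promoter_abc_min = 0.1) {
  keep <- scores |>
    group_by(.data$pair_id) |>
    summarise(
      ok = (max(.data$abc) >= ifelse(.data$is_promoter_pair[1],
        promoter_abc_min, abc_min
      )) && all(.data$C > 0) && all(.data$A > 0),
      .groups = "drop"
    ) |>
    filter(.data$ok)
  semi_join(scores, keep, by = "pair_id")
}
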