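# Interval conventions: 0-based half-open [start, end) throughout. IRanges is
# 1-based closed, so [start, end) maps to IRanges(start + 1, end).

ir_of <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# overlap of 0-based half-open query intervals with subject intervals,
# chromosome-aware; returns logical vector over query rows
overlaps_subject <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  hit <- logical(length(q_start))
  for (ch in unique(q_chrom)) {
    qi <- which(q_chrom == ch)
    si <- which(s_chrom == ch)
    if (length(si) == 0) next
    hit[qi] <- IRanges::overlapsAny(
      ir_of(q_start[qi], q_end[qi]),
      ir_of(s_start[si], s_end[si])
    )
  }
  hit
}

# sweep-merge overlapping intervals within chromosomes; keeps the minimum of
# `order_pos` (and that member's summit) for each merged run
merge_intervals <- function(df) {
  if (!"order_pos" %in% names(df)) df$order_pos <- seq_len(nrow(df))
  if (!"summit" %in% names(df)) df$summit <- NA_real_
  if (!"source" %in% names(df)) df$source <- "atac_peak"
  df |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(
      run = cumsum(.data$start >= cummax(dplyr::lag(.data$end, default = -Inf)))
    ) |>
    group_by(.data$chrom, .data$run) |>
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      summit = .data$summit[which.min(.data$order_pos)],
      source = if (any(.data$source == "atac_peak")) "atac_peak" else "tss_added",
      order_pos = min(.data$order_pos),
      .groups = "drop"
    ) |>
    select(-"run")
}

#' Rank peaks by read count and resize to 500 bp around the summit
#'
#' Read counts are summed over the given ancestry's samples; peaks are sorted
#' by descending summed count (ties broken by genomic coordinate), the top `k`
#' retained, and each resized to 500 bp centered on its summit. Windows
#' running past a chromosome edge are clipped without re-centering, so edge
#' elements can be shorter than 500 bp.
#'
#' @param peaks Tibble `peak_id`, `chrom`, `start`, `end`, `summit`.
#' @param counts Long tibble `peak_id`, `sample_id`, `count`.
#' @param sample_ids Character vector of samples whose counts define the
#'   ranking (one ancestry's samples).
#' @param chrom_sizes Tibble `chrom`, `length` used for edge clipping.
#' @param k Number of top peaks to keep (default 150000).
#' @param width Resized element width in bp.
#' @return Tibble `peak_id`, `chrom`, `start`, `end`, `summit`,
#'   `total_count`, `rank`, sorted by rank.
#' @export
rank_resize_peaks <- function(peaks, counts, sample_ids, chrom_sizes,
                              k = 150000, width = 500) {
  if (any(is.na(peaks$summit))) {
    abort("rank_resize_peaks: every peak must have a summit")
  }
  sub <- counts |> filter(.data$sample_id %in% sample_ids)
  got <- sub |> count(.data$peak_id)
  if (nrow(got) < nrow(peaks) || any(got$n < length(sample_ids))) {
    abort("rank_resize_peaks: counts missing for some peak/sample combinations")
  }
  summed <- sub |>
    group_by(.data$peak_id) |>
    summarise(total_count = sum(.data$count), .groups = "drop")
  ranked <- peaks |>
    inner_join(summed, by = "peak_id") |>
    arrange(desc(.data$total_count), .data$chrom, .data$start)
  if (nrow(ranked) < k) {
    warn(sprintf(
      "rank_resize_peaks: only %d peaks available (k = %d); keeping all",
      nrow(ranked), k
    ))
  }
  half <- width %/% 2
  ranked |>
    head(k) |>
    left_join(chrom_sizes, by = "chrom") |>
    mutate(
      start = pmax(.data$summit - half, 0),
      end = pmin(.data$summit + (width - half), .data$length),
      rank = row_number()
    ) |>
    select("peak_id", "chrom", "start", "end", "summit", "total_count", "rank")
}

#' Interleave two ancestry peak rankings and merge overlaps
#'
#' The AFR and EUR rankings are interleaved evenly (AFR rank 1, EUR rank 1,
#' AFR rank 2, ...) so each ancestry contributes equally; overlapping
#' intervals are merged (union), a merged element keeping the best (smallest)
#' interleaved position among its constituents; the first `k` elements in
#' interleaved order are returned.
#'
#' @param afr_ranked,eur_ranked Rank-sorted outputs of [rank_resize_peaks()].
#' @param k Number of elements to keep after merging.
#' @return Tibble `chrom`, `start`, `end`, `summit`, `order_pos`, sorted by
#'   interleaved order.
#' @export
interleave_and_merge <- function(afr_ranked, eur_ranked, k = 150000) {
  if (nrow(afr_ranked) == 0 || nrow(eur_ranked) == 0) {
    abort("interleave_and_merge: both ancestry peak lists must be non-empty")
  }
  combined <- bind_rows(
    afr_ranked |> mutate(order_pos = 2 * .data$rank - 1),
    eur_ranked |> mutate(order_pos = 2 * .data$rank)
  ) |>
    select("chrom", "start", "end", "summit", "order_pos")
  merge_intervals(combined) |>
    arrange(.data$order_pos) |>
    head(k)
}

#' Add TSS-centered elements and remove blacklist overlaps
#'
#' Adds a 500-bp element centered on each gene TSS, merges any overlaps
#' created by the addition, then drops every element overlapping the
#' blacklist by at least 1 bp. Elements are returned coordinate-sorted with
#' stable ids.
#'
#' @param candidates Tibble `chrom`, `start`, `end` (plus optional `summit`,
#'   `order_pos`) of non-overlapping candidate elements.
#' @param tss Tibble `gene_id`, `chrom`, `tss`.
#' @param blacklist Optional tibble `chrom`, `start`, `end`; `NULL` or empty
#'   means no removals.
#' @param chrom_sizes Optional tibble `chrom`, `length` for clipping TSS
#'   windows at chromosome edges.
#' @return Tibble `cre_id`, `chrom`, `start`, `end`, `summit`, `source`.
#' @export
add_tss_and_blacklist <- function(candidates, tss, blacklist = NULL,
                                  chrom_sizes = NULL) {
  tss_el <- tss |>
    transmute(
      chrom = .data$chrom,
      start = .data$tss - 250,
      end = .data$tss + 250,
      summit = .data$tss,
      source = "tss_added",
      order_pos = Inf
    )
  if (!is.null(chrom_sizes)) {
    tss_el <- tss_el |>
      left_join(chrom_sizes, by = "chrom") |>
      mutate(start = pmax(.data$start, 0), end = pmin(.data$end, .data$length)) |>
      select(-"length")
  } else {
    tss_el <- mutate(tss_el, start = pmax(.data$start, 0))
  }
  merged <- merge_intervals(bind_rows(
    candidates |> mutate(source = "atac_peak"),
    tss_el
  ))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    if (any(blacklist$start >= blacklist$end) || any(blacklist$start < 0)) {
      abort("add_tss_and_blacklist: malformed blacklist intervals")
    }
    bad <- overlaps_subject(
      merged$chrom, merged$start, merged$end,
      blacklist$chrom, blacklist$start, blacklist$end
    )
    merged <- merged[!bad, ]
  }
  merged |>
    arrange(.data$chrom, .data$start) |>
    mutate(cre_id = sprintf("cre%06d", row_number())) |>
    select("cre_id", "chrom", "start", "end", "summit", "source")
}

#' Classify elements as promoter or enhancer
#'
#' An element is a promoter if its interval overlaps the window within 500 bp
#' of any annotated TSS (positions `tss - 500 .. tss + 500` inclusive);
#' everything else is an enhancer.
#'
#' @param cres Tibble with `chrom`, `start`, `end`.
#' @param tss Tibble `gene_id`, `chrom`, `tss`.
#' @return `cres` with an `element_class` column (`"promoter"`/`"enhancer"`).
#' @export
classify_elements <- function(cres, tss) {
  is_prom <- overlaps_subject(
    cres$chrom, cres$start, cres$end,
    tss$chrom, tss$tss - 500, tss$tss + 501
  )
  mutate(cres, element_class = ifelse(is_prom, "promoter", "enhancer"))
}

#' Build the candidate CRE set from per-ancestry peak rankings
#'
#' Convenience wrapper running [rank_resize_peaks()] per ancestry,
#' [interleave_and_merge()], [add_tss_and_blacklist()] and
#' [classify_elements()].
#'
#' @param peaks Peak tibble (shared locations; see [sim_peaks()]), or a list
#'   with elements `AFR` and `EUR` for ancestry-specific peak calls.
#' @param counts Long ATAC count tibble `peak_id`, `sample_id`, `count`.
#' @param samples Sample sheet with `sample_id`, `ancestry`.
#' @param tss TSS tibble.
#' @param chrom_sizes Tibble `chrom`, `length`.
#' @param blacklist Optional blacklist tibble.
#' @param k Elements retained per ranking and after merging.
#' @return Classified CRE tibble (see [classify_elements()]).
#' @export
define_cres <- function(peaks, counts, samples, tss, chrom_sizes,
                        blacklist = NULL, k = 150000) {
  pk <- function(anc) if (is.data.frame(peaks)) peaks else peaks[[anc]]
  ranked <- lapply(c(AFR = "AFR", EUR = "EUR"), function(anc) {
    rank_resize_peaks(
      pk(anc), counts,
      samples$sample_id[samples$ancestry == anc],
      chrom_sizes, k = k
    )
  })
  interleave_and_merge(ranked$AFR, ranked$EUR, k = k) |>
    add_tss_and_blacklist(tss, blacklist, chrom_sizes) |>
    classify_elements(tss)
}

#' Sum ATAC peak counts into CRE counts by summit membership
#'
#' Each peak contributes its counts to the CRE containing its summit; peaks
#' whose summit falls in no CRE are dropped, and CREs with no contributing
#' peak (pure TSS additions) get zero counts.
#'
#' @param cres CRE tibble.
#' @param peaks Peak tibble with `summit`.
#' @param counts Long count tibble `peak_id`, `sample_id`, `count`.
#' @return Long tibble `cre_id`, `sample_id`, `count` covering every
#'   CRE/sample combination.
#' @export
cre_atac_counts <- function(cres, peaks, counts) {
  assign <- purrr::map_dfr(unique(peaks$chrom), function(ch) {
    p <- peaks[peaks$chrom == ch, ]
    cc <- cres[cres$chrom == ch, ]
    if (nrow(cc) == 0 || nrow(p) == 0) return(NULL)
    ov <- IRanges::findOverlaps(
      ir_of(p$summit, p$summit + 1), ir_of(cc$start, cc$end)
    )
    tibble(
      peak_id = p$peak_id[S4Vectors::queryHits(ov)],
      cre_id = cc$cre_id[S4Vectors::subjectHits(ov)]
    )
  })
  samples <- unique(counts$sample_id)
  counts |>
    inner_join(assign, by = "peak_id") |>
    group_by(.data$cre_id, .data$sample_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::complete(
      cre_id = cres$cre_id, sample_id = samples,
      fill = list(count = 0L)
    )
}
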