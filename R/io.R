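#' Read a HiC-Pro sparse contact map
#'
#' The `.matrix` file is tab-separated `bin_i  bin_j  count` with 1-based
#' genome-wide bin indices and no header; the companion `.bed` file holds the
#' bin intervals as `chrom  start  end  bin_id` (0-based half-open).
#'
#' @param matrix_path Path to the `.matrix` file.
#' @param bed_path Path to the bin `.bed` file.
#' @return List with `contacts` (tibble `bin_i`, `bin_j`, `count`) and
#'   `bins` (tibble `bin_id`, `chrom`, `start`, `end`).
#' @export
read_hicpro <- function(matrix_path, bed_path) {
  contacts <- readr::read_tsv(
    matrix_path,
    col_names = c("bin_i", "bin_j", "count"),
    col_types = "iii", progress = FALSE
  )
  bins <- readr::read_tsv(
    bed_path,
    col_names = c("chrom", "start", "end", "bin_id"),
    col_types = "cddi", progress = FALSE
  ) |>
    select("bin_id", "chrom", "start", "end")
  list(contacts = contacts, bins = bins)
}

#' Read peak intervals written as BED6+summit
#'
#' @param path Path to a tab-separated file with columns chrom, start, end,
#'   name, score, strand, summit (no header).
#' @return Tibble `peak_id`, `chrom`, `start`, `end`, `summit`.
#' @export
read_peaks_bed <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand", "summit"),
    col_types = "cddcdcd", progress = FALSE
  ) |>
    transmute(
      peak_id = .data$name, chrom = .data$chrom,
      start = .data$start, end = .data$end, summit = .data$summit
    )
}

#' Write all synthetic-study files to a directory
#'
#' Emits the pipeline's on-disk input formats: peaks as BED6+summit, ATAC
#' counts as a peak-by-sample TSV, contact maps as per-sample HiC-Pro
#' `.matrix` files plus one shared `_abs.bed` bin file, and TSVs for the TSS
#' annotation, blacklist, samples, variants, genotype counts, QTL, DE tables
#' and the truth table.
#'
#' @param sim An `abc_sim` from [sim_abc_data()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_sim_data <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)

  peaks_bed <- sim$peaks |>
    transmute(
      .data$chrom, .data$start, .data$end, name = .data$peak_id,
      score = 0L, strand = ".", .data$summit
    )
  readr::write_tsv(peaks_bed, p("peaks.bed"), col_names = FALSE)

  counts_wide <- sim$atac_counts |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count")
  readr::write_tsv(counts_wide, p("atac_counts.tsv"))

  bins_bed <- sim$bins |> select("chrom", "start", "end", "bin_id")
  readr::write_tsv(bins_bed, p("bins_abs.bed"), col_names = FALSE)
  for (s in sim$samples$sample_id) {
    m <- sim$contacts |>
      filter(.data$sample_id == s) |>
      select("bin_i", "bin_j", "count")
    readr::write_tsv(m, p(paste0(s, ".matrix")), col_names = FALSE)
  }

  readr::write_tsv(sim$tss, p("tss.tsv"))
  readr::write_tsv(sim$samples, p("samples.tsv"))
  readr::write_tsv(sim$blacklist, p("blacklist.bed"), col_names = FALSE)
  readr::write_tsv(sim$variants, p("variants.tsv"))
  readr::write_tsv(sim$genotype_counts, p("genotype_counts.tsv"))
  readr::write_tsv(sim$qtl, p("qtl.tsv"))
  readr::write_tsv(sim$de, p("de_tables.tsv"))
  readr::write_tsv(sim$truth$pairs, p("truth_pairs.tsv"))
  readr::write_tsv(sim$truth$genes, p("truth_genes.tsv"))
  invisible(dir)
}
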