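# small study used by fast unit tests
tiny_cfg <- function(...) {
  defaults <- list(
    n_chroms = 2, chrom_length = 2e6, n_genes = 40,
    n_peaks_per_ancestry = 400, n_variants = 400, n_qtl = 120,
    seed = 42
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# memoized heavy studies shared across test files (built once per run)
.study_cache <- new.env(parent = emptyenv())

# default-size null study: no injected effects, no allele-frequency divergence
null_study <- function() {
  if (is.null(.study_cache$null)) {
    cfg <- sim_config(effect_fraction = 0, divergence_param = 0, seed = 7)
    sim <- sim_abc_data(cfg)
    res <- abc_pipeline(sim)
    .study_cache$null <- list(cfg = cfg, sim = sim, res = res)
  }
  .study_cache$null
}

# default-size study with injected |log2fc| = 1 effects and full coupling
effect_study <- function() {
  if (is.null(.study_cache$effect)) {
    cfg <- sim_config(
      effect_fraction = 0.1, effect_log2fc = 1, coupling = 1, seed = 11
    )
    sim <- sim_abc_data(cfg)
    res <- abc_pipeline(sim)
    .study_cache$effect <- list(cfg = cfg, sim = sim, res = res)
  }
  .study_cache$effect
}

# map truth-flagged peaks of one channel to the CREs containing their summit
truth_cre_map <- function(sim, cres, channel) {
  tp <- sim$truth$pairs[sim$truth$pairs$channel == channel, ]
  pk <- sim$peaks[sim$peaks$peak_id %in% tp$peak_id, ]
  hits <- purrr::map_dfr(unique(pk$chrom), function(ch) {
    p <- pk[pk$chrom == ch, ]
    cc <- cres[cres$chrom == ch, ]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(p$summit + 1, p$summit + 1),
      IRanges::IRanges(cc$start + 1, cc$end)
    )
    tibble::tibble(
      peak_id = p$peak_id[S4Vectors::queryHits(ov)],
      cre_id = cc$cre_id[S4Vectors::subjectHits(ov)]
    )
  })
  dplyr::inner_join(hits, tp[, c("peak_id", "gene_id", "sign")], by = "peak_id")
}

# build a minimal abc_diff tibble from tribble-style rows
mk_diff <- function(...) {
  rows <- tibble::tribble(...)
  structure(rows, class = c("abc_diff", class(rows)), alpha = 0.05, nondiff = 0.5)
}
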