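test_that("gene placement respects count, bounds and minimum spacing", {
  cfg <- tiny_cfg(n_genes = 50, n_chroms = 1, chrom_length = 1e7)
  ann <- sim_annotation(cfg)
  expect_equal(nrow(ann$tss), 50)
  expect_true(all(ann$tss$tss >= 0 & ann$tss$tss < 1e7))
  spacing <- diff(sort(ann$tss$tss))
  expect_true(all(spacing >= 10000))
})

test_that("infeasible gene spacing is a configuration error", {
  expect_error(
    sim_annotation(tiny_cfg(n_genes = 10000, n_chroms = 1, chrom_length = 1e6)),
    "spacing"
  )
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- tiny_cfg(effect_fraction = 0.2, divergence_param = 0.1, coupling = 0.5)
  s1 <- sim_abc_data(cfg)
  s2 <- sim_abc_data(cfg)
  expect_identical(s1$tss, s2$tss)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$atac_counts, s2$atac_counts)
  expect_identical(s1$contacts, s2$contacts)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$qtl, s2$qtl)
  expect_identical(s1$de, s2$de)
  # and byte-identical on disk
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim_data(s1, d1)
  write_sim_data(s2, d2)
  for (f in list.files(d1)) {
    expect_equal(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f)))
    )
  }
})

test_that("ATAC counts: one row per peak and sample, null log-ratios centred at zero", {
  cfg <- tiny_cfg(effect_fraction = 0)
  sim <- sim_abc_data(cfg)
  expect_equal(nrow(sim$atac_counts), nrow(sim$peaks) * nrow(sim$samples))
  expect_true(all(sim$atac_counts$count >= 0))
  lr <- sim$atac_counts |>
    dplyr::left_join(sim$samples, by = "sample_id") |>
    dplyr::group_by(peak_id, ancestry) |>
    dplyr::summarise(m = mean(count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = ancestry, values_from = m) |>
    dplyr::mutate(lr = log2((AFR + 0.5) / (EUR + 0.5)))
  expect_lt(abs(mean(lr$lr)), 0.05)
})

test_that("injected ATAC effects double the flagged ancestry's mean counts", {
  cfg <- sim_config(
    n_chroms = 2, chrom_length = 3e6, n_genes = 60,
    n_peaks_per_ancestry = 900, effect_fraction = 0.6, effect_log2fc = 1,
    seed = 5
  )
  ann <- sim_annotation(cfg)
  peaks <- sim_peaks(cfg, ann)
  truth <- sim_truth(cfg, ann, peaks)
  counts <- sim_atac(cfg, ann, peaks, truth)
  flags <- truth$pairs[truth$pairs$channel == "atac", ]
  expect_gt(nrow(flags), 100)
  ratios <- counts |>
    dplyr::inner_join(flags, by = "peak_id") |>
    dplyr::left_join(sim_samples(cfg), by = "sample_id") |>
    dplyr::group_by(peak_id, sign, hit = ancestry == sign) |>
    dplyr::summarise(m = mean(count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = hit, values_from = m) |>
    dplyr::mutate(ratio = `TRUE` / `FALSE`)
  # Monte-Carlo mean of the generative model: flagged / unflagged ancestry = 2
  expect_equal(mean(ratios$ratio), 2, tolerance = 0.1)
})

test_that("contact maps conserve totals through the HiC-Pro round trip", {
  sim <- sim_abc_data(tiny_cfg())
  dir <- withr::local_tempdir()
  write_sim_data(sim, dir)
  s1 <- sim$samples$sample_id[1]
  rt <- read_hicpro(file.path(dir, paste0(s1, ".matrix")), file.path(dir, "bins_abs.bed"))
  orig <- sim$contacts |> dplyr::filter(sample_id == s1)
  expect_equal(sum(rt$contacts$count), sum(orig$count))
  expect_equal(nrow(rt$contacts), nrow(orig))
  expect_identical(rt$bins, sim$bins)
  # upper triangle stored once, diagonal allowed
  expect_true(all(sim$contacts$bin_i <= sim$contacts$bin_j))
})

test_that("contact decay vanishes in the zero-rate limit", {
  cfg <- tiny_cfg(contact_decay_rate = 1e-12, contact_depth = 1)
  sim <- sim_abc_data(cfg)
  prof <- sim$contacts |>
    dplyr::mutate(d = bin_j - bin_i) |>
    dplyr::filter(d > 0) |>
    dplyr::group_by(band = cut(d, c(0, 30, 60, 100))) |>
    dplyr::summarise(m = mean(count), .groups = "drop")
  expect_lt(max(prof$m) / min(prof$m), 1.25)
})

test_that("ChIP-channel effects shift the flagged bin marginals about two-fold", {
  cfg <- sim_config(
    n_chroms = 2, chrom_length = 3e6, n_genes = 60,
    n_peaks_per_ancestry = 900, effect_fraction = 0.6, effect_log2fc = 1,
    seed = 5
  )
  ann <- sim_annotation(cfg)
  peaks <- sim_peaks(cfg, ann)
  truth <- sim_truth(cfg, ann, peaks)
  hc <- sim_hichip(cfg, ann, peaks, truth)
  chip <- truth$pairs[truth$pairs$channel == "chip", ]
  expect_gt(nrow(chip), 100)
  pk <- peaks[match(chip$peak_id, peaks$peak_id), ]
  bin_of <- hc$bins$bin_id[match(
    paste(pk$chrom, (pk$summit %/% cfg$bin_size) * cfg$bin_size),
    paste(hc$bins$chrom, hc$bins$start)
  )]
  samples <- sim_samples(cfg)
  totals <- dplyr::bind_rows(
    hc$contacts |> dplyr::select(sample_id, bin = bin_i, count),
    hc$contacts |>
      dplyr::filter(bin_i != bin_j) |>
      dplyr::select(sample_id, bin = bin_j, count)
  ) |>
    dplyr::group_by(sample_id, bin) |>
    dplyr::summarise(total = sum(count), .groups = "drop") |>
    dplyr::left_join(samples, by = "sample_id")
  ratios <- purrr::map_dbl(seq_len(nrow(chip)), function(i) {
    tt <- totals[totals$bin == bin_of[i], ]
    mean(tt$total[tt$ancestry == chip$sign[i]]) /
      mean(tt$total[tt$ancestry != chip$sign[i]])
  })
  expect_equal(mean(ratios, na.rm = TRUE), 2, tolerance = 0.2)
})

test_that("every truth-flagged pair has contact support in every sample", {
  cfg <- tiny_cfg(effect_fraction = 0.3)
  sim <- sim_abc_data(cfg)
  tp <- sim$truth$pairs |>
    dplyr::left_join(sim$peaks[, c("peak_id", "chrom", "summit")], by = "peak_id") |>
    dplyr::left_join(
      sim$tss |> dplyr::select(gene_id, tss_chrom = chrom, tss),
      by = "gene_id"
    )
  bs <- sim$config$bin_size
  key <- paste(sim$bins$chrom, (sim$bins$start %/% bs) * bs)
  b_pk <- sim$bins$bin_id[match(paste(tp$chrom, (tp$summit %/% bs) * bs), key)]
  b_g <- sim$bins$bin_id[match(paste(tp$tss_chrom, (tp$tss %/% bs) * bs), key)]
  want <- tidyr::crossing(
    tibble::tibble(bin_i = pmin(b_pk, b_g), bin_j = pmax(b_pk, b_g)),
    sample_id = sim$samples$sample_id
  )
  missing <- dplyr::anti_join(want, sim$contacts,
    by = c("sample_id", "bin_i", "bin_j")
  )
  expect_equal(nrow(missing), 0)
})

test_that("allele frequencies are undiverged at zero divergence and coupled QTL match truth", {
  sim0 <- sim_abc_data(tiny_cfg(divergence_param = 0, within_divergence = 0.005))
  expect_lt(mean(abs(sim0$variants$af_AFR - sim0$variants$af_EUR)), 0.05)

  simc <- sim_abc_data(tiny_cfg(
    effect_fraction = 0.5, coupling = 1, divergence_param = 0.05
  ))
  coupled <- simc$qtl |>
    dplyr::filter(!is.na(truth_sign), !is.na(direction))
  expect_gt(nrow(coupled), 10)
  expect_true(all(coupled$direction == coupled$truth_sign))
})

test_that("DE tables obey the coupling match probability and the null LFSR floor", {
  cfg <- sim_config(
    n_chroms = 4, chrom_length = 4e6, n_genes = 600,
    n_peaks_per_ancestry = 1200, effect_fraction = 0.9, seed = 3
  )
  ann <- sim_annotation(cfg)
  peaks <- sim_peaks(cfg, ann)
  truth <- sim_truth(cfg, ann, peaks)
  expect_gt(nrow(truth$genes), 200)

  # forced matching: every flagged gene DE with the injected sign
  de1 <- sim_de(cfg, ann, truth, n_contexts = 1, match_prob = 1)
  fl1 <- de1 |>
    dplyr::inner_join(truth$genes |> dplyr::rename(truth_sign = de_sign),
      by = "gene_id"
    )
  expect_true(all(fl1$lfsr < 0.05))
  expect_true(all(fl1$de_sign == fl1$truth_sign))

  # matched fraction ~ 0.5 at match_prob 0.5 over > 200 flagged genes
  de5 <- sim_de(cfg, ann, truth, n_contexts = 1, match_prob = 0.5)
  fl5 <- de5 |>
    dplyr::inner_join(truth$genes |> dplyr::rename(truth_sign = de_sign),
      by = "gene_id"
    )
  expect_equal(mean(fl5$de_sign == fl5$truth_sign), 0.5, tolerance = 0.1)

  # no flagged genes: nothing significant
  de0 <- sim_de(cfg, ann, NULL, n_contexts = 1)
  expect_true(all(de0$lfsr >= 0.05))
})
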