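#' Simulate the genome annotation: chromosome sizes and gene TSSs
#'
#' Genes are distributed evenly over chromosomes and placed uniformly at
#' random on a 10-kb grid, guaranteeing a minimum TSS spacing of 10 kb.
#'
#' @param config A [sim_config()].
#' @return List with `chrom_sizes` (tibble `chrom`, `length`) and `tss`
#'   (tibble `gene_id`, `chrom`, `tss`, `strand`; 0-based positions).
#' @export
sim_annotation <- function(config) {
  validate_sim_config(config)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- tibble(chrom = chroms, length = config$chrom_length)
  per_chrom <- rep(config$n_genes %/% config$n_chroms, config$n_chroms)
  extra <- config$n_genes %% config$n_chroms
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  slots <- seq(5000, config$chrom_length - 5000, by = 10000)
  if (any(per_chrom > length(slots))) {
    abort(paste0(
      "sim_annotation: chromosomes too short to place ",
      max(per_chrom), " genes at >= 10 kb spacing"
    ))
  }
  tss <- withr::with_seed(stage_seed(config, "annotation"), {
    purrr::map2_dfr(chroms, per_chrom, function(ch, n) {
      tibble(
        chrom = ch,
        tss = sort(sample(slots, n)),
        strand = sample(c("+", "-"), n, replace = TRUE)
      )
    })
  })
  tss <- tss |>
    mutate(gene_id = sprintf("g%04d", row_number())) |>
    select("gene_id", "chrom", "tss", "strand")
  list(chrom_sizes = chrom_sizes, tss = tss)
}

#' Simulate the master ATAC peak set
#'
#' A fraction of peaks (`tss_peak_frac`) is placed at gene TSSs (promoter
#' peaks, as in real ATAC data where promoters dominate the strongest peaks);
#' the rest are distal, on a 1-kb grid. Both ancestries share the same peak
#' locations; their rankings differ only through sampled read counts.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [sim_annotation()].
#' @return Tibble `peak_id`, `chrom`, `start`, `end`, `summit` (0-based
#'   half-open; summit is a bp position inside the interval).
#' @export
sim_peaks <- function(config, annotation) {
  validate_sim_config(config)
  chroms <- annotation$chrom_sizes$chrom
  len <- config$chrom_length
  per_chrom <- rep(config$n_peaks_per_ancestry %/% config$n_chroms, config$n_chroms)
  extra <- config$n_peaks_per_ancestry %% config$n_chroms
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  peaks <- withr::with_seed(stage_seed(config, "peaks"), {
    purrr::map2_dfr(chroms, per_chrom, function(ch, n) {
      ch_tss <- annotation$tss$tss[annotation$tss$chrom == ch]
      n_prom <- min(round(config$tss_peak_frac * n), n)
      prom_summits <- integer(0)
      if (n_prom > 0 && length(ch_tss) > 0) {
        at <- rep_len(ch_tss, n_prom)
        prom_summits <- at + sample(-100:100, n_prom, replace = TRUE)
      }
      n_dist <- n - length(prom_summits)
      grid <- seq(500, len - 500, by = 1000)
      grid <- setdiff(grid, round(ch_tss / 1000) * 1000 + 500)
      dist_summits <- sample(grid, min(n_dist, length(grid)))
      summits <- sort(c(prom_summits, dist_summits))
      half <- sample(150:400, length(summits), replace = TRUE)
      tibble(
        chrom = ch,
        start = pmax(summits - half, 0),
        end = pmin(summits + half, len),
        summit = summits
      )
    })
  })
  peaks |>
    mutate(peak_id = sprintf("pk%05d", row_number())) |>
    select("peak_id", "chrom", "start", "end", "summit")
}

#' Ground-truth table of injected ancestry effects
#'
#' Flags `effect_fraction` of the peaks with an injected effect, assigning
#' channels round-robin over atac (accessibility), chip (anchor H3K27ac
#' marginal) and hic (specific contact), a random high-activity ancestry, and
#' a target gene (the nearest gene within 1 Mb of the summit, falling back to
#' the nearest gene on the chromosome). Target genes inherit a DE sign equal
#' to the injected activity direction.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [sim_annotation()].
#' @param peaks Output of [sim_peaks()].
#' @return List of class `sim_truth` with tibbles `pairs` (`peak_id`,
#'   `gene_id`, `channel`, `sign`) and `genes` (`gene_id`, `de_sign`).
#' @export
sim_truth <- function(config, annotation, peaks) {
  n_flag <- round(config$effect_fraction * nrow(peaks))
  if (n_flag == 0) {
    out <- list(
      pairs = tibble(
        peak_id = character(0), gene_id = character(0),
        channel = character(0), sign = character(0)
      ),
      genes = tibble(gene_id = character(0), de_sign = character(0))
    )
    return(structure(out, class = "sim_truth"))
  }
  pairs <- withr::with_seed(stage_seed(config, "truth"), {
    flagged <- peaks[sort(sample.int(nrow(peaks), n_flag)), ]
    flagged$channel <- rep_len(c("atac", "chip", "hic"), n_flag)
    flagged$sign <- sample(c("AFR", "EUR"), n_flag, replace = TRUE)
    flagged$gene_id <- purrr::map2_chr(
      flagged$chrom, flagged$summit,
      function(ch, s) {
        g <- annotation$tss[annotation$tss$chrom == ch, ]
        d <- abs(g$tss - s)
        near <- which(d <= 1e6)
        if (length(near) > 0) g$gene_id[near[which.min(d[near])]] else g$gene_id[which.min(d)]
      }
    )
    flagged
  })
  genes <- pairs |>
    distinct(.data$gene_id, .data$sign) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup() |>
    rename(de_sign = "sign")
  structure(
    list(
      pairs = select(pairs, "peak_id", "gene_id", "channel", "sign"),
      genes = genes
    ),
    class = "sim_truth"
  )
}

#' Simulate per-sample ATAC peak read counts
#'
#' Per-peak baseline means are log-normal around `read_depth_mean`; counts are
#' negative binomial with size `nb_dispersion` and per-sample library-depth
#' factors. Peaks flagged in the truth table with channel `"atac"` have their
#' mean multiplied by `2^effect_log2fc` in the flagged ancestry's samples.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [sim_annotation()] (unused beyond validation;
#'   kept so the generators share one calling convention).
#' @param peaks Output of [sim_peaks()].
#' @param truth Output of [sim_truth()], or `NULL` for no effects.
#' @return Long tibble `peak_id`, `sample_id`, `count`.
#' @export
sim_atac <- function(config, annotation, peaks, truth = NULL) {
  samples <- sim_samples(config)
  n_pk <- nrow(peaks)
  n_s <- nrow(samples)
  withr::with_seed(stage_seed(config, "atac"), {
    lambda <- rlnorm(n_pk, log(config$read_depth_mean), 1)
    depth <- rlnorm(n_s, 0, config$sample_depth_sd)
    mu <- outer(lambda, depth)
    if (!is.null(truth) && nrow(truth$pairs) > 0) {
      atac_flags <- truth$pairs[truth$pairs$channel == "atac", ]
      idx <- match(atac_flags$peak_id, peaks$peak_id)
      for (k in seq_along(idx)) {
        hit <- samples$ancestry == atac_flags$sign[k]
        mu[idx[k], hit] <- mu[idx[k], hit] * 2^config$effect_log2fc
      }
    }
    counts <- matrix(
      rnbinom(n_pk * n_s, mu = as.vector(mu), size = config$nb_dispersion),
      nrow = n_pk
    )
    tibble(
      peak_id = rep(peaks$peak_id, times = n_s),
      sample_id = rep(samples$sample_id, each = n_pk),
      count = as.integer(counts)
    )
  })
}

# 5-kb bin table with HiC-Pro style genome-wide 1-based indices
sim_bins <- function(config, annotation) {
  bs <- config$bin_size
  purrr::pmap_dfr(annotation$chrom_sizes, function(chrom, length) {
    start <- seq(0, length - 1, by = bs)
    tibble(chrom = chrom, start = start, end = pmin(start + bs, length))
  }) |>
    mutate(bin_id = row_number()) |>
    select("bin_id", "chrom", "start", "end")
}

#' Simulate per-sample HiChIP contact maps
#'
#' Expected counts for a bin pair decay exponentially with genomic distance at
#' `contact_decay_rate` and are multiplied by each anchor bin's weight: 1 for
#' background bins and `active_enrichment` for bins containing a peak summit
#' or TSS (emulating the H3K27ac pulldown). Truth-flagged `"chip"` peaks
#' multiply their bin's anchor weight by `2^effect_log2fc` in the flagged
#' ancestry (shifting the whole bin marginal); `"hic"` pairs multiply the
#' single connecting bin-pair mean instead. Counts are Poisson; the upper
#' triangle (including the diagonal) is stored once. Every truth-flagged pair
#' is guaranteed at least one contact in every sample.
#'
#' @inheritParams sim_atac
#' @return List with `bins` (tibble `bin_id`, `chrom`, `start`, `end`) and
#'   `contacts` (tibble `sample_id`, `bin_i`, `bin_j`, `count`, `bin_i <=
#'   bin_j`).
#' @export
sim_hichip <- function(config, annotation, peaks, truth = NULL) {
  samples <- sim_samples(config)
  bins <- sim_bins(config, annotation)
  bs <- config$bin_size
  bin_of <- function(chrom, pos) {
    bins$bin_id[match(
      paste(chrom, (pos %/% bs) * bs),
      paste(bins$chrom, bins$start)
    )]
  }
  # sample-independent anchor weights
  w <- rep(1, nrow(bins))
  active <- unique(c(
    bin_of(peaks$chrom, peaks$summit),
    bin_of(annotation$tss$chrom, annotation$tss$tss)
  ))
  w[active] <- config$active_enrichment

  chip_flags <- hic_flags <- NULL
  if (!is.null(truth) && nrow(truth$pairs) > 0) {
    tp <- truth$pairs |>
      left_join(select(peaks, "peak_id", "chrom", "summit"), by = "peak_id") |>
      left_join(select(annotation$tss, "gene_id", tss_chrom = "chrom", "tss"),
        by = "gene_id"
      ) |>
      mutate(
        bin_pk = bin_of(.data$chrom, .data$summit),
        bin_g = bin_of(.data$tss_chrom, .data$tss),
        bi = pmin(.data$bin_pk, .data$bin_g),
        bj = pmax(.data$bin_pk, .data$bin_g)
      )
    chip_flags <- filter(tp, .data$channel == "chip")
    hic_flags <- filter(tp, .data$channel == "hic")
    truth_pairs_all <- distinct(tp, .data$bi, .data$bj)
  } else {
    truth_pairs_all <- tibble(bi = integer(0), bj = integer(0))
  }

  # pair grid per chromosome, shared across samples
  eff <- 2^config$effect_log2fc
  mu_cap <- config$contact_depth * (config$active_enrichment * eff)^2
  d_max <- log(mu_cap / 5e-4) / config$contact_decay_rate
  k_max <- max(1L, min(floor(d_max / bs), ceiling(config$chrom_length / bs)))
  grid <- bins |>
    group_by(.data$chrom) |>
    summarise(first = min(.data$bin_id), last = max(.data$bin_id)) |>
    purrr::pmap_dfr(function(chrom, first, last) {
      i <- rep(first:last, each = k_max + 1L)
      j <- i + rep(0:k_max, times = last - first + 1L)
      keep <- j <= last
      tibble(bin_i = i[keep], bin_j = j[keep])
    })
  mu_base <- config$contact_depth *
    exp(-config$contact_decay_rate * (grid$bin_j - grid$bin_i) * bs) *
    w[grid$bin_i] * w[grid$bin_j]

  contacts <- withr::with_seed(stage_seed(config, "hichip"), {
    depth <- rlnorm(nrow(samples), 0, config$sample_depth_sd)
    purrr::map_dfr(seq_len(nrow(samples)), function(s) {
      mu <- mu_base * depth[s]
      if (!is.null(chip_flags) && nrow(chip_flags) > 0) {
        hit_bins <- unique(chip_flags$bin_pk[chip_flags$sign == samples$ancestry[s]])
        if (length(hit_bins) > 0) {
          f <- rep(1, nrow(bins))
          f[hit_bins] <- eff
          mu <- mu * f[grid$bin_i] * f[grid$bin_j]
        }
      }
      if (!is.null(hic_flags) && nrow(hic_flags) > 0) {
        hf <- hic_flags[hic_flags$sign == samples$ancestry[s], ]
        if (nrow(hf) > 0) {
          idx <- match(
            paste(hf$bi, hf$bj),
            paste(grid$bin_i, grid$bin_j)
          )
          idx <- idx[!is.na(idx)]
          mu[idx] <- mu[idx] * eff
        }
      }
      cnt <- rpois(length(mu), mu)
      keep <- cnt > 0
      out <- tibble(
        sample_id = samples$sample_id[s],
        bin_i = grid$bin_i[keep], bin_j = grid$bin_j[keep],
        count = cnt[keep]
      )
      # guarantee signal at truth-flagged pairs
      if (nrow(truth_pairs_all) > 0) {
        miss <- anti_join(truth_pairs_all, out,
          by = c(bi = "bin_i", bj = "bin_j")
        )
        if (nrow(miss) > 0) {
          out <- bind_rows(out, tibble(
            sample_id = samples$sample_id[s],
            bin_i = miss$bi, bin_j = miss$bj, count = 1L
          ))
        }
      }
      arrange(out, .data$bin_i, .data$bin_j)
    })
  })
  list(bins = bins, contacts = contacts)
}

#' Simulate variants, per-population genotype counts, and QTL tables
#'
#' Allele frequencies follow a Balding-Nichols model: an ancestral frequency
#' drawn uniformly, ancestry-level frequencies drawn around it with
#' `divergence_param` as F, and population-level frequencies drawn around the
#' ancestry frequency with `within_divergence`. Genotypes are Hardy-Weinberg
#' draws of `n_individuals` diploids per population, so observed heterozygote
#' counts are real. A subset of variants inside peaks is labelled as QTL for
#' the configured TF types; with coupling `c`, a QTL inside a truth-flagged
#' activity peak has its high-affinity allele at higher frequency in the
#' flagged ancestry with probability `(1 + c)/2`.
#'
#' @param config A [sim_config()].
#' @param peaks Output of [sim_peaks()].
#' @param truth Output of [sim_truth()], or `NULL`.
#' @return List with `variants` (per-variant tibble incl. pooled ancestry
#'   genotype summaries `n_AFR`, `ac_AFR`, `het_AFR`, `n_EUR`, `ac_EUR`,
#'   `het_EUR` and pooled frequencies `af_AFR`, `af_EUR` of the alt allele),
#'   `genotype_counts` (per-population long tibble) and `qtl` (tibble
#'   `variant_id`, `qtl_type`, `qtl_p`, `high_allele`, `af_AFR`, `af_EUR` of
#'   the high-affinity allele, `direction`).
#' @export
sim_variants <- function(config, peaks, truth = NULL) {
  pops <- config$populations
  n_v <- config$n_variants
  n_ind <- config$n_individuals
  withr::with_seed(stage_seed(config, "variants"), {
    n_in <- round(0.6 * n_v)
    pk_idx <- sample.int(nrow(peaks), n_in, replace = TRUE)
    pos_in <- floor(runif(n_in, peaks$start[pk_idx], peaks$end[pk_idx]))
    chrom_in <- peaks$chrom[pk_idx]
    n_out <- n_v - n_in
    chroms <- unique(peaks$chrom)
    chrom_out <- sample(chroms, n_out, replace = TRUE)
    pos_out <- floor(runif(n_out, 0, config$chrom_length))
    variants <- tibble(
      chrom = c(chrom_in, chrom_out),
      pos = c(pos_in, pos_out),
      in_peak_id = c(peaks$peak_id[pk_idx], rep(NA_character_, n_out))
    ) |>
      arrange(.data$chrom, .data$pos) |>
      mutate(variant_id = sprintf("v%05d", row_number()))

    bn_draw <- function(p, f) {
      if (f == 0) return(p)
      rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
    }
    p0 <- runif(n_v, 0.05, 0.95)
    p_anc <- lapply(c(AFR = "AFR", EUR = "EUR"), function(a) {
      pmin(pmax(bn_draw(p0, config$divergence_param), 1e-4), 1 - 1e-4)
    })
    geno <- purrr::pmap_dfr(pops, function(population, ancestry) {
      p_pop <- pmin(pmax(
        bn_draw(p_anc[[ancestry]], config$within_divergence), 1e-4
      ), 1 - 1e-4)
      hom_alt <- rbinom(n_v, n_ind, p_pop^2)
      het <- rbinom(n_v, n_ind - hom_alt, pmin(
        2 * p_pop * (1 - p_pop) / pmax(1 - p_pop^2, 1e-12), 1
      ))
      tibble(
        variant_id = variants$variant_id, population = population,
        ancestry = ancestry, n = n_ind,
        alt_count = 2L * hom_alt + het, het_count = het
      )
    })
    pooled <- geno |>
      group_by(.data$variant_id, .data$ancestry) |>
      summarise(
        n = sum(.data$n), ac = sum(.data$alt_count),
        het = sum(.data$het_count), .groups = "drop"
      ) |>
      tidyr::pivot_wider(
        names_from = "ancestry",
        values_from = c("n", "ac", "het"), names_sep = "_"
      ) |>
      mutate(
        af_AFR = .data$ac_AFR / (2 * .data$n_AFR),
        af_EUR = .data$ac_EUR / (2 * .data$n_EUR)
      )
    variants <- left_join(variants, pooled, by = "variant_id")

    # QTL labelling; with coupling on, QTL preferentially land in
    # truth-flagged activity peaks (the variants driving the effects)
    elig <- which(!is.na(variants$in_peak_id))
    n_q <- min(config$n_qtl, length(elig))
    wts <- rep(1, length(elig))
    if (!is.null(truth) && nrow(truth$pairs) > 0 && config$coupling > 0) {
      act_peaks <- truth$pairs$peak_id[truth$pairs$channel %in% c("atac", "chip")]
      wts[variants$in_peak_id[elig] %in% act_peaks] <- 1 + 4 * config$coupling
    }
    q_idx <- sort(sample(elig, n_q, prob = wts))
    qtl <- variants[q_idx, c("variant_id", "in_peak_id", "af_AFR", "af_EUR")]
    qtl$qtl_type <- sample(config$qtl_types, n_q, replace = TRUE)
    qtl$qtl_p <- 10^runif(n_q, -10, -2)
    flag_sign <- rep(NA_character_, n_q)
    if (!is.null(truth) && nrow(truth$pairs) > 0) {
      act <- truth$pairs[truth$pairs$channel %in% c("atac", "chip"), ]
      m <- match(qtl$in_peak_id, act$peak_id)
      flag_sign <- act$sign[m]
    }
    force_match <- !is.na(flag_sign) & runif(n_q) < config$coupling
    alt_dir <- ifelse(qtl$af_AFR > qtl$af_EUR, "AFR",
      ifelse(qtl$af_AFR < qtl$af_EUR, "EUR", NA)
    )
    rand_allele <- sample(c("ref", "alt"), n_q, replace = TRUE)
    qtl$high_allele <- ifelse(
      force_match & !is.na(alt_dir),
      ifelse(alt_dir == flag_sign, "alt", "ref"),
      rand_allele
    )
    is_alt <- qtl$high_allele == "alt"
    qtl <- qtl |>
      mutate(
        af_AFR = ifelse(is_alt, .data$af_AFR, 1 - .data$af_AFR),
        af_EUR = ifelse(is_alt, .data$af_EUR, 1 - .data$af_EUR),
        direction = ifelse(.data$af_AFR > .data$af_EUR, "AFR",
          ifelse(.data$af_AFR < .data$af_EUR, "EUR", NA)
        ),
        truth_sign = flag_sign
      ) |>
      select(
        "variant_id", "qtl_type", "qtl_p", "high_allele",
        "af_AFR", "af_EUR", "direction", "truth_sign"
      )
    list(variants = variants, genotype_counts = geno, qtl = qtl)
  })
}

#' Simulate per-context differential-expression tables
#'
#' Genes targeted by truth-flagged peaks are DE (LFSR < 0.05) in every
#' context, with sign matching the injected activity direction with
#' probability `match_prob`; all other genes draw LFSR from a null far from
#' significance.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [sim_annotation()].
#' @param truth Output of [sim_truth()], or `NULL`.
#' @param n_contexts Number of contexts.
#' @param match_prob Probability a flagged gene's DE sign matches the
#'   injected direction; defaults to `(1 + coupling)/2` so that coupling 0
#'   gives independent signs and coupling 1 forces matching.
#' @return Tibble `gene_id`, `context`, `de_sign`, `lfsr`.
#' @export
sim_de <- function(config, annotation, truth = NULL,
                   n_contexts = config$n_contexts,
                   match_prob = (1 + config$coupling) / 2) {
  genes <- annotation$tss$gene_id
  flagged <- if (!is.null(truth)) truth$genes else tibble(gene_id = character(0), de_sign = character(0))
  withr::with_seed(stage_seed(config, "de"), {
    purrr::map_dfr(seq_len(n_contexts), function(k) {
      ctx <- sprintf("ctx%02d", k)
      sign <- sample(c("AFR", "EUR"), length(genes), replace = TRUE)
      lfsr <- runif(length(genes), 0.5, 1)
      m <- match(genes, flagged$gene_id)
      fl <- !is.na(m)
      if (any(fl)) {
        lfsr[fl] <- runif(sum(fl), 0, 0.049)
        keep <- runif(sum(fl)) < match_prob
        truth_sign <- flagged$de_sign[m[fl]]
        sign[fl] <- ifelse(keep, truth_sign,
          ifelse(truth_sign == "AFR", "EUR", "AFR")
        )
      }
      tibble(gene_id = genes, context = ctx, de_sign = sign, lfsr = lfsr)
    })
  })
}

#' Simulate artifact-blacklist intervals
#'
#' Random 10-kb intervals placed away from TSSs, emulating regions of known
#' signal artifacts.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [sim_annotation()].
#' @return Tibble `chrom`, `start`, `end` (possibly empty).
#' @export
sim_blacklist <- function(config, annotation) {
  n <- config$n_blacklist_per_chrom
  if (n == 0) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  withr::with_seed(stage_seed(config, "blacklist"), {
    purrr::map_dfr(annotation$chrom_sizes$chrom, function(ch) {
      ch_tss <- annotation$tss$tss[annotation$tss$chrom == ch]
      cand <- seq(0, config$chrom_length - 10000, by = 10000)
      bad <- unique(ch_tss %/% 10000 * 10000)
      cand <- setdiff(cand, c(bad, bad - 10000))
      start <- sample(cand, min(n, length(cand)))
      tibble(chrom = ch, start = start, end = start + 10000)
    })
  })
}

#' Generate a complete synthetic ABC study
#'
#' Runs every generator under the configured seed and returns all pipeline
#' inputs plus the ground-truth table.
#'
#' @param config A [sim_config()].
#' @return List of class `abc_sim` with elements `config`, `samples`,
#'   `chrom_sizes`, `tss`, `peaks`, `blacklist`, `truth`, `atac_counts`,
#'   `bins`, `contacts`, `variants`, `genotype_counts`, `qtl`, `de`.
#' @export
sim_abc_data <- function(config) {
  ann <- sim_annotation(config)
  peaks <- sim_peaks(config, ann)
  truth <- sim_truth(config, ann, peaks)
  atac <- sim_atac(config, ann, peaks, truth)
  hichip <- sim_hichip(config, ann, peaks, truth)
  vr <- sim_variants(config, peaks, truth)
  de <- sim_de(config, ann, truth)
  structure(
    list(
      config = config,
      samples = sim_samples(config),
      chrom_sizes = ann$chrom_sizes,
      tss = ann$tss,
      peaks = peaks,
      blacklist = sim_blacklist(config, ann),
      truth = truth,
      atac_counts = atac,
      bins = hichip$bins,
      contacts = hichip$contacts,
      variants = vr$variants,
      genotype_counts = vr$genotype_counts,
      qtl = vr$qtl,
      de = de
    ),
    class = "abc_sim"
  )
}

#' @export
print.abc_sim <- function(x, ...) {
  cat("<abc_sim>\n")
  cat(sprintf(
    "  %d samples, %d genes, %d peaks, %d contact records, %d variants (%d QTL)\n",
    nrow(x$samples), nrow(x$tss), nrow(x$peaks), nrow(x$contacts),
    nrow(x$variants), nrow(x$qtl)
  ))
  cat(sprintf("  truth: %d flagged pairs\n", nrow(x$truth$pairs)))
  invisible(x)
}
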