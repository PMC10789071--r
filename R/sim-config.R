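#' Default population design: four African and three European pooled populations
#'
#' Two replicate libraries per pooled population, giving the 14-sample design
#' used throughout (8 AFR vs 6 EUR libraries).
#'
#' @return A tibble with columns `population` and `ancestry`.
#' @export
default_populations <- function() {
  tibble::tibble(
    population = c("ESN", "GWD", "LWK", "YRI", "FIN", "IBS", "TSI"),
    ancestry   = c(rep("AFR", 4), rep("EUR", 3))
  )
}

#' Configuration for the synthetic ABC-study generator
#'
#' Bundles every knob of the synthetic-data module: genome geometry, the pooled
#' population design, sequencing-noise parameters, the HiChIP contact model and
#' the injected ancestry effects that serve as ground truth for downstream
#' recovery tests.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Total number of genes (split evenly across chromosomes).
#' @param n_peaks_per_ancestry Number of ATAC peaks in each ancestry's peak
#'   list (a shared master set of locations is used; counts differ by sample).
#' @param populations Tibble with columns `population`, `ancestry`
#'   (see [default_populations()]).
#' @param replicates_per_population Replicate libraries per pooled population.
#' @param read_depth_mean Mean ATAC reads per peak (per-peak means are
#'   log-normal around this value).
#' @param nb_dispersion Negative-binomial size parameter for ATAC counts;
#'   larger means less overdispersion.
#' @param sample_depth_sd Log-normal sd of per-sample library-depth factors.
#' @param contact_depth Expected HiChIP contact count for an unenriched bin
#'   pair at distance zero.
#' @param contact_decay_rate Exponential distance-decay rate of expected
#'   contact counts, per bp.
#' @param active_enrichment Multiplier applied to the contact-anchor weight of
#'   bins containing an active element (peak summit or TSS), emulating
#'   H3K27ac pulldown.
#' @param effect_fraction Fraction of peaks carrying an injected ancestry
#'   effect (split round-robin across the atac/chip/hic channels).
#' @param effect_log2fc Magnitude of the injected effect in log2 units.
#' @param divergence_param Balding-Nichols F governing between-ancestry
#'   allele-frequency divergence of simulated variants; 0 means no divergence.
#' @param within_divergence Balding-Nichols F for population scatter around
#'   each ancestry frequency.
#' @param coupling Strength in \[0, 1\] linking bQTL high-affinity-allele
#'   direction and DE sign to the injected activity effects. The probability
#'   that a coupled record matches the injected direction is `(1 + coupling)/2`,
#'   so 0 gives independence and 1 forces matching.
#' @param n_variants Number of biallelic variants to simulate.
#' @param n_qtl Number of variants (inside peaks) labelled as QTL.
#' @param qtl_types Character vector of QTL labels (TF names plus H3K4me3).
#' @param n_individuals Diploid individuals genotyped per population.
#' @param n_contexts Number of differential-expression contexts to emit.
#' @param bin_size HiChIP bin size in bp.
#' @param tss_peak_frac Fraction of peaks placed at gene TSSs (promoter peaks).
#' @param n_blacklist_per_chrom Artifact-blacklist intervals per chromosome.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output from every generator.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 16,
                       chrom_length = 6e6,
                       n_genes = 1600,
                       n_peaks_per_ancestry = 3840,
                       populations = default_populations(),
                       replicates_per_population = 2,
                       read_depth_mean = 100,
                       nb_dispersion = 25,
                       sample_depth_sd = 0.15,
                       contact_depth = 2,
                       contact_decay_rate = 2e-5,
                       active_enrichment = 4,
                       effect_fraction = 0,
                       effect_log2fc = 1,
                       divergence_param = 0.05,
                       within_divergence = 0.01,
                       coupling = 0,
                       n_variants = 4000,
                       n_qtl = 1200,
                       qtl_types = c("NFkB", "JunD", "PU1", "STAT1", "Oct1", "H3K4me3"),
                       n_individuals = 50,
                       n_contexts = 3,
                       bin_size = 5000,
                       tss_peak_frac = 0.7,
                       n_blacklist_per_chrom = 0,
                       seed = 1L) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || abs(seed) > 2^30) {
    abort("sim_config: `seed` must be a finite integer below 2^30 in magnitude")
  }
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.numeric(chrom_length),
    n_genes = as.integer(n_genes),
    n_peaks_per_ancestry = as.integer(n_peaks_per_ancestry),
    populations = tibble::as_tibble(populations),
    replicates_per_population = as.integer(replicates_per_population),
    read_depth_mean = read_depth_mean, nb_dispersion = nb_dispersion,
    sample_depth_sd = sample_depth_sd, contact_depth = contact_depth,
    contact_decay_rate = contact_decay_rate,
    active_enrichment = active_enrichment,
    effect_fraction = effect_fraction, effect_log2fc = effect_log2fc,
    divergence_param = divergence_param,
    within_divergence = within_divergence, coupling = coupling,
    n_variants = as.integer(n_variants), n_qtl = as.integer(n_qtl),
    qtl_types = qtl_types, n_individuals = as.integer(n_individuals),
    n_contexts = as.integer(n_contexts), bin_size = as.integer(bin_size),
    tss_peak_frac = tss_peak_frac,
    n_blacklist_per_chrom = as.integer(n_blacklist_per_chrom),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(
    "n_chroms", "chrom_length", "n_genes", "n_peaks_per_ancestry",
    "replicates_per_population", "read_depth_mean", "nb_dispersion",
    "contact_depth", "n_variants", "n_individuals", "n_contexts", "bin_size"
  )
  for (fld in counts) {
    if (!is.numeric(cfg[[fld]]) || length(cfg[[fld]]) != 1L ||
        is.na(cfg[[fld]]) || cfg[[fld]] <= 0) {
      abort(sprintf("sim_config: `%s` must be a single positive number", fld))
    }
  }
  for (fld in c("effect_fraction", "divergence_param", "within_divergence", "coupling")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("sim_config: `%s` must be in [0, 1]", fld))
    }
  }
  if (!all(c("population", "ancestry") %in% names(cfg$populations))) {
    abort("sim_config: `populations` needs columns `population` and `ancestry`")
  }
  if (!all(cfg$populations$ancestry %in% c("AFR", "EUR"))) {
    abort("sim_config: ancestry labels must be 'AFR' or 'EUR'")
  }
  if (is.na(cfg$seed) || abs(cfg$seed) > 2^30) {
    abort("sim_config: `seed` must be a finite integer below 2^30 in magnitude")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  n_samp <- nrow(x$populations) * x$replicates_per_population
  cat("<sim_config>\n")
  cat(sprintf(
    "  genome: %d chrom x %.3g bp; %d genes; %d peaks/ancestry\n",
    x$n_chroms, x$chrom_length, x$n_genes, x$n_peaks_per_ancestry
  ))
  cat(sprintf(
    "  design: %d populations (%d AFR / %d EUR) x %d replicates = %d samples\n",
    nrow(x$populations), sum(x$populations$ancestry == "AFR"),
    sum(x$populations$ancestry == "EUR"), x$replicates_per_population, n_samp
  ))
  cat(sprintf(
    "  effects: fraction %.3g at log2fc %.3g; divergence %.3g; coupling %.3g; seed %d\n",
    x$effect_fraction, x$effect_log2fc, x$divergence_param, x$coupling, x$seed
  ))
  invisible(x)
}

#' Sample sheet for a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Tibble with `sample_id`, `population`, `ancestry`, `replicate`.
#' @export
sim_samples <- function(config) {
  tidyr::crossing(
    config$populations,
    replicate = seq_len(config$replicates_per_population)
  ) |>
    mutate(sample_id = paste0(.data$population, "_rep", .data$replicate)) |>
    select("sample_id", "population", "ancestry", "replicate") |>
    arrange(.data$ancestry, .data$population, .data$replicate)
}

# deterministic sub-seed per generator stage
stage_seed <- function(config, stage) {
  offsets <- c(
    annotation = 101L, peaks = 202L, truth = 303L, atac = 404L,
    hichip = 505L, variants = 606L, de = 707L, blacklist = 808L
  )
  config$seed + offsets[[stage]]
}
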