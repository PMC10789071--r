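test_that("one-sided Fisher matches closed-form and enumerated hypergeometric tails", {
  # perfectly concordant table: point mass 1 / C(20, 10)
  r <- fisher_one_sided(10, 0, 0, 10)
  expect_equal(r$odds_ratio, Inf)
  expect_equal(r$p, 1 / choose(20, 10))

  # balanced table: odds ratio 1, tail ~ 0.6719
  r2 <- fisher_one_sided(5, 5, 5, 5)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p, oracle_hyper_upper(5, 5, 5, 5))
  expect_equal(r2$p, 0.6719, tolerance = 1e-4)

  # fully depleted table: opposite tail, p = 1
  r3 <- fisher_one_sided(0, 10, 10, 0)
  expect_equal(r3$p, 1)

  # zero margin: undefined odds ratio, flagged
  r4 <- fisher_one_sided(0, 0, 3, 4)
  expect_true(r4$degenerate)
  expect_equal(r4$p, 1)
  expect_true(is.na(r4$odds_ratio))
})

test_that("Fisher p and odds ratio agree with enumeration for all small tables", {
  set.seed(12)
  for (i in 1:300) {
    n <- sample(4:40, 1)
    cells <- as.vector(rmultinom(1, n, runif(4, 0.1, 1)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if (any(c(a + b, c + d, a + c, b + d) == 0)) next
    r <- fisher_one_sided(a, b, c, d)
    expect_equal(r$p, oracle_hyper_upper(a, b, c, d), tolerance = 1e-12)
    expect_equal(r$odds_ratio, if (b * c == 0) Inf else a * d / (b * c))
    expect_lte(r$ci_lower, r$odds_ratio)
  }
})

top_fixture <- function(rows) {
  # rows: list of list(cre, p, dir, class, targets = tibble(gene, prom))
  tibble::tibble(
    cre_id = purrr::map_chr(rows, "cre"),
    p = purrr::map_dbl(rows, "p"),
    direction = purrr::map_chr(rows, "dir"),
    log2fc = ifelse(purrr::map_chr(rows, "dir") == "EUR", 1, -1),
    element_class = purrr::map_chr(rows, "class"),
    bin_key = seq_along(rows),
    targets = purrr::map(rows, function(r) {
      tibble::tibble(
        gene_id = r$targets$gene,
        is_promoter_pair = r$targets$prom
      )
    })
  )
}

de_fix <- function(genes, signs) {
  tibble::tibble(
    gene_id = genes, context = "ctx", de_sign = signs, lfsr = 0.01
  )
}

test_that("a diff-CRE with several DE targets counts once in the overlap test", {
  rows <- list(
    list(cre = "c1", p = 0.01, dir = "EUR", class = "enhancer",
         targets = tibble::tibble(gene = c("g1", "g2", "g3"), prom = FALSE)),
    list(cre = "c2", p = 0.01, dir = "EUR", class = "enhancer",
         targets = tibble::tibble(gene = "g9", prom = FALSE)),
    list(cre = "c3", p = 0.9, dir = "EUR", class = "enhancer",
         targets = tibble::tibble(gene = "g1", prom = FALSE)),
    list(cre = "c4", p = 0.7, dir = "EUR", class = "enhancer",
         targets = tibble::tibble(gene = "g8", prom = FALSE)),
    # intermediate p: excluded from the table entirely
    list(cre = "c5", p = 0.2, dir = "EUR", class = "enhancer",
         targets = tibble::tibble(gene = "g1", prom = FALSE))
  )
  de <- de_fix(c("g1", "g2", "g3"), c("EUR", "EUR", "EUR"))
  r <- de_overlap_test(top_fixture(rows), de, context = "ctx")
  # c1 counts once despite three DE targets
  expect_equal(r$a, 1)
  expect_equal(r$b, 1)
  expect_equal(r$c, 1)
  expect_equal(r$d, 1)
})

test_that("promoter and enhancer class filters use promoter-for-target status", {
  rows <- list(
    # promoter CRE that is the promoter of its DE target
    list(cre = "c1", p = 0.01, dir = "EUR", class = "promoter",
         targets = tibble::tibble(gene = "g1", prom = TRUE)),
    # promoter-class CRE acting distally on its DE target (distal promoter)
    list(cre = "c2", p = 0.01, dir = "EUR", class = "promoter",
         targets = tibble::tibble(gene = "g2", prom = FALSE)),
    list(cre = "c3", p = 0.8, dir = "EUR", class = "promoter",
         targets = tibble::tibble(gene = "g9", prom = TRUE)),
    list(cre = "c4", p = 0.9, dir = "EUR", class = "enhancer",
         targets = tibble::tibble(gene = "g8", prom = FALSE))
  )
  de <- de_fix(c("g1", "g2"), c("EUR", "EUR"))
  rp <- de_overlap_test(top_fixture(rows), de, context = "ctx", class_filter = "promoter")
  # universe: promoter-class CREs only; success needs promoter-of-DE-target
  expect_equal(rp$a + rp$b + rp$c + rp$d, 3)
  expect_equal(rp$a, 1) # c1, not c2
  re <- de_overlap_test(top_fixture(rows), de, context = "ctx", class_filter = "enhancer")
  # success requires being the promoter of none of the DE targets: c2 yes, c1 no
  expect_equal(re$a, 1)
})

test_that("direction matching requires consistent DE signs and crosses directions", {
  rows <- list(
    list(cre = "c1", p = 0.01, dir = "AFR", class = "enhancer",
         targets = tibble::tibble(gene = "g1", prom = FALSE)),
    list(cre = "c2", p = 0.01, dir = "EUR", class = "enhancer",
         targets = tibble::tibble(gene = "g2", prom = FALSE)),
    # opposite-sign targets: excluded from the universe
    list(cre = "c3", p = 0.01, dir = "AFR", class = "enhancer",
         targets = tibble::tibble(gene = c("g3", "g4"), prom = FALSE)),
    list(cre = "c4", p = 0.01, dir = "EUR", class = "enhancer",
         targets = tibble::tibble(gene = "g5", prom = FALSE)),
    list(cre = "c5", p = 0.01, dir = "AFR", class = "enhancer",
         targets = tibble::tibble(gene = "g6", prom = FALSE))
  )
  de <- de_fix(
    c("g1", "g2", "g3", "g4", "g5", "g6"),
    c("AFR", "EUR", "AFR", "EUR", "AFR", "EUR")
  )
  r <- direction_match_test(top_fixture(rows), de, context = "ctx")
  expect_equal(r$n_total, 4) # c3 excluded
  expect_equal(r$a, 1) # c1 matches AFR/AFR
  expect_equal(r$d, 1) # c2 matches EUR/EUR

  # all matching: infinite odds ratio
  rows_m <- rows[c(1, 2)]
  rm <- direction_match_test(top_fixture(rows_m), de, context = "ctx")
  expect_equal(rm$odds_ratio, Inf)
})

qtl_fixture <- function() {
  list(
    variants = tibble::tibble(
      variant_id = c("v1", "v2", "v3", "v4"),
      chrom = "chr1", pos = c(150, 160, 1150, 5000)
    ),
    qtl = tibble::tibble(
      variant_id = c("v1", "v2", "v3", "v4"),
      qtl_type = c("PU1", "PU1", "PU1", "JunD"),
      qtl_p = c(1e-8, 1e-4, 0.01, 1e-6),
      high_allele = "alt",
      af_AFR = c(0.8, 0.2, 0.9, 0.5),
      af_EUR = c(0.2, 0.8, 0.1, 0.4),
      direction = c("AFR", "EUR", "AFR", "AFR")
    ),
    cres = tibble::tibble(
      cre_id = c("c1", "c2", "c3"), chrom = "chr1",
      start = c(100, 1100, 2100), end = c(600, 1600, 2600)
    )
  )
}

test_that("QTL overlap keeps the lowest-p QTL per CRE and handles absent QTL", {
  fx <- qtl_fixture()
  d <- mk_diff(
    ~pair_id, ~cre_id, ~gene_id, ~score_type, ~p, ~log2fc, ~direction, ~diff_flag, ~bin_key, ~element_class, ~is_promoter_pair,
    "c1:g1", "c1", "g1", "atac", 0.01, 1, "EUR", TRUE, 1L, "enhancer", FALSE,
    "c2:g1", "c2", "g1", "atac", 0.80, 0.1, "EUR", FALSE, 2L, "enhancer", FALSE,
    "c3:g1", "c3", "g1", "atac", 0.90, 0.1, "EUR", FALSE, 3L, "enhancer", FALSE
  )
  r <- qtl_overlap_test(d, "atac", fx$cres, fx$qtl, fx$variants, "PU1")
  expect_equal(r$a, 1) # c1 has PU.1 QTL
  expect_equal(r$c, 1) # c2 has, c3 has not
  expect_equal(r$d, 1)
  expect_error(
    qtl_overlap_test(d, "atac", fx$cres, fx$qtl, fx$variants, "NFkB"),
    "unknown qtl_type"
  )
  # a QTL type present nowhere near CREs gives a degenerate table
  fx2 <- fx
  fx2$variants$pos[4] <- 5000 # JunD variant outside all CREs
  r2 <- qtl_overlap_test(d, "atac", fx2$cres, fx2$qtl, fx2$variants, "JunD")
  expect_true(r2$degenerate)
  expect_equal(r2$p, 1)
})

test_that("QTL direction matching represents each CRE by its lowest-p QTL", {
  fx <- qtl_fixture()
  d <- mk_diff(
    ~pair_id, ~cre_id, ~gene_id, ~score_type, ~p, ~log2fc, ~direction, ~diff_flag, ~bin_key, ~element_class, ~is_promoter_pair,
    "c1:g1", "c1", "g1", "atac", 0.01, -1, "AFR", TRUE, 1L, "enhancer", FALSE,
    "c2:g1", "c2", "g1", "atac", 0.02, 1, "EUR", TRUE, 2L, "enhancer", FALSE
  )
  # c1 contains v1 (AFR) and v2 (EUR): directions disagree -> excluded;
  # the remaining single-CRE table has an empty margin and degenerates
  expect_warning(
    r <- qtl_direction_match_test(d, "atac", fx$cres, fx$qtl, fx$variants, "PU1"),
    "margin"
  )
  expect_true(r$degenerate)

  # richer universe: four CREs, each with one QTL, full margins
  cres4 <- tibble::tibble(
    cre_id = c("c1", "c2", "c3", "c4"), chrom = "chr1",
    start = c(100, 1100, 2100, 3100), end = c(600, 1600, 2600, 3600)
  )
  vars4 <- tibble::tibble(
    variant_id = paste0("w", 1:4), chrom = "chr1",
    pos = c(150, 1150, 2150, 3150)
  )
  qtl4 <- tibble::tibble(
    variant_id = paste0("w", 1:4), qtl_type = "PU1",
    qtl_p = c(1e-8, 1e-6, 1e-4, 1e-2), high_allele = "alt",
    af_AFR = c(0.9, 0.1, 0.9, 0.1), af_EUR = c(0.1, 0.9, 0.1, 0.9),
    direction = c("AFR", "EUR", "AFR", "EUR")
  )
  d4 <- mk_diff(
    ~pair_id, ~cre_id, ~gene_id, ~score_type, ~p, ~log2fc, ~direction, ~diff_flag, ~bin_key, ~element_class, ~is_promoter_pair,
    "c1:g1", "c1", "g1", "atac", 0.01, -1, "AFR", TRUE, 1L, "enhancer", FALSE,
    "c2:g1", "c2", "g1", "atac", 0.01, 1, "EUR", TRUE, 2L, "enhancer", FALSE,
    "c3:g1", "c3", "g1", "atac", 0.02, 1, "EUR", TRUE, 3L, "enhancer", FALSE,
    "c4:g1", "c4", "g1", "atac", 0.02, -1, "AFR", TRUE, 4L, "enhancer", FALSE
  )
  r2 <- qtl_direction_match_test(d4, "atac", cres4, qtl4, vars4, "PU1")
  expect_equal(r2$n_total, 4)
  expect_equal(r2$a, 1) # c1: CRE AFR, QTL AFR
  expect_equal(r2$d, 1) # c2: CRE EUR, QTL EUR

  expect_error(
    qtl_direction_match_test(d, "atac", fx$cres, fx$qtl, fx$variants, "PU1",
      fst_quantile = 1.5
    ),
    "fst_quantile"
  )
})

test_that("the F_ST restriction shrinks the QTL universe to the top quantile", {
  set.seed(5)
  sim <- sim_abc_data(tiny_cfg(divergence_param = 0.1))
  vf <- variant_fst(sim$variants)
  cres <- define_cres(
    sim$peaks, sim$atac_counts, sim$samples, sim$tss, sim$chrom_sizes,
    k = nrow(sim$peaks)
  )
  in_cre <- vf |>
    dplyr::semi_join(
      tibble::tibble(variant_id = diffabc:::qtl_variants_in_cres(vf, cres)),
      by = "variant_id"
    )
  thr <- fst_quantile_threshold(in_cre$fst, 0.95)
  frac <- mean(in_cre$fst >= thr)
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("the binomial sign test matches exact tail computations", {
  mk_dir <- function(k, n) c(rep("AFR", k), rep("EUR", n - k))
  r <- sign_test(mk_dir(5, 10), mk_dir(5, 10))
  expect_equal(r$p, 1)
  r2 <- sign_test(mk_dir(10, 10), mk_dir(5, 10))
  expect_equal(r2$p, 2 * 0.5^10)
  # p0 at the observed proportion maximizes the p-value
  for (k in c(2, 5, 8)) {
    p_at_mode <- sign_test(mk_dir(k, 10), mk_dir(k, 10))$p
    expect_gte(p_at_mode, sign_test(mk_dir(k, 10), mk_dir(3, 10))$p - 1e-12)
  }
  expect_true(is.na(sign_test(character(0), mk_dir(5, 10))$p))
})

test_that("Bonferroni stars follow the published thresholds", {
  s <- enrichment_stars(c(0.04, 0.004, 4e-4, 4e-5, 4e-6, 0.2), n_tests = 1)
  expect_equal(s$stars, c("*", "**", "***", "****", "****", ""))
  s22 <- enrichment_stars(0.04 / 22, n_tests = 22)
  expect_equal(s22$stars, "*")
})
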