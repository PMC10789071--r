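# Independent oracles, deliberately written in a different style from the
# package implementations they check.

# Weir & Cockerham (1984) per-site theta for two populations, scalar,
# following the component formulas term by term.
oracle_wc_fst <- function(n1, ac1, het1, n2, ac2, het2) {
  r <- 2
  n <- c(n1, n2)
  p <- c(ac1 / (2 * n1), ac2 / (2 * n2))
  h <- c(het1 / n1, het2 / n2)
  n_bar <- mean(n)
  n_c <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  p_bar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / sum(n)
  a <- (n_bar / n_c) *
    (s2 - 1 / (n_bar - 1) * (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# upper-tail hypergeometric probability P(X >= a) for a 2x2 table with fixed
# margins, by explicit enumeration of the support
oracle_hyper_upper <- function(a, b, c, d) {
  m1 <- a + b # focal row total
  k <- a + c # success column total
  n_tot <- a + b + c + d
  xs <- max(0, k - (n_tot - m1)):min(m1, k)
  pmf <- vapply(xs, function(x) {
    choose(m1, x) * choose(n_tot - m1, k - x)
  }, numeric(1))
  pmf <- pmf / sum(pmf)
  sum(pmf[xs >= a])
}

# direct loop evaluation of the four score formulas for one gene and sample
oracle_scores <- function(A, Q, H_E, H_G, C) {
  n <- length(A)
  abc <- atac <- chip <- hic <- numeric(n)
  s_abc <- sum(A * Q)
  s_atac <- sum(A)
  s_chip <- sum(sqrt(H_E * H_G))
  hic_num <- ifelse(sqrt(H_E * H_G) > 0, C / sqrt(H_E * H_G), 0)
  s_hic <- sum(hic_num)
  for (i in seq_len(n)) {
    abc[i] <- if (s_abc > 0) A[i] * Q[i] / s_abc else 0
    atac[i] <- if (s_atac > 0) A[i] / s_atac else 0
    chip[i] <- if (s_chip > 0) sqrt(H_E[i] * H_G[i]) / s_chip else 0
    hic[i] <- if (s_hic > 0) hic_num[i] / s_hic else 0
  }
  list(abc = abc, atac = atac, chip = chip, hic = hic)
}
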