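# Population diversity and differentiation metrics.

#' Weir-Cockerham FST
#'
#' Per-SNP variance-components estimator theta of Weir & Cockerham (1984)
#' for diploid data, with the multi-locus average taken as
#' `sum(a) / sum(a + b + c)` over SNPs polymorphic across the pooled sample.
#' Per-SNP values can be slightly negative by estimator construction.
#'
#' @param g a [genotype_matrix()].
#' @param pop_labels population per individual; defaults to `g$pop_labels`.
#' @return list with `theta_per_snp`, `theta_mean`, and the per-SNP
#'   components `a`, `b`, `c`.
#' @export
weir_cockerham_fst <- function(g, pop_labels = NULL) {
  pop_labels <- pop_labels %||% g$pop_labels
  pops <- unique(pop_labels)
  r <- length(pops)
  if (r < 2L) stop("need at least two populations")
  sizes <- table(pop_labels)
  if (any(sizes < 2L)) stop("every population needs at least two individuals")
  M <- ncol(g$dosages)
  # per-pop, per-SNP: sample size (non-missing), allele freq, het frequency
  n_i <- p_i <- h_i <- matrix(0, r, M)
  for (k in seq_len(r)) {
    d <- g$dosages[pop_labels == pops[k], , drop = FALSE]
    n_i[k, ] <- colSums(!is.na(d))
    p_i[k, ] <- colMeans(d, na.rm = TRUE) / 2
    h_i[k, ] <- colMeans(d == 1L, na.rm = TRUE)
  }
  n_tot <- colSums(n_i)
  nbar <- n_tot / r
  nc <- (n_tot - colSums(n_i^2) / n_tot) / (r - 1)
  pbar <- colSums(n_i * p_i) / n_tot
  s2 <- colSums(n_i * sweep(p_i, 2L, pbar, "-")^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / n_tot
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  poly <- pbar > 0 & pbar < 1
  theta[!poly] <- NA_real_
  theta_mean <- sum(a[poly]) / sum((a + b + cc)[poly])
  list(theta_per_snp = theta, theta_mean = theta_mean, a = a, b = b, c = cc)
}

#' Observed heterozygosity per population
#'
#' Fraction of non-missing genotypes that are heterozygous (dosage 1),
#' averaged over SNPs.
#'
#' @inheritParams weir_cockerham_fst
#' @return named numeric vector, one value per population.
#' @export
observed_heterozygosity <- function(g, pop_labels = NULL) {
  pop_labels <- pop_labels %||% g$pop_labels
  vapply(split(seq_along(pop_labels), pop_labels), function(rows) {
    d <- g$dosages[rows, , drop = FALSE]
    mean(d == 1L, na.rm = TRUE)
  }, numeric(1))
}

#' Nucleotide diversity per SNP and population
#'
#' Unbiased expected heterozygosity `2 * p * (1 - p) * n / (n - 1)` with
#' `n` the number of individuals with observed genotypes. SNP/population
#' cells with fewer than two observed individuals are `NA`.
#'
#' @inheritParams weir_cockerham_fst
#' @return matrix populations x SNPs of per-SNP pi.
#' @export
nucleotide_diversity <- function(g, pop_labels = NULL) {
  pop_labels <- pop_labels %||% g$pop_labels
  pops <- sort(unique(pop_labels))
  out <- matrix(NA_real_, length(pops), ncol(g$dosages),
                dimnames = list(pops, g$markers$id))
  for (k in seq_along(pops)) {
    d <- g$dosages[pop_labels == pops[k], , drop = FALSE]
    n <- colSums(!is.na(d))
    p <- colMeans(d, na.rm = TRUE) / 2
    pi_k <- 2 * p * (1 - p) * n / (n - 1)
    pi_k[n < 2L] <- NA_real_
    out[k, ] <- pi_k
  }
  out
}

#' All diversity metrics in one pass
#'
#' @inheritParams weir_cockerham_fst
#' @return list with `fst` (from [weir_cockerham_fst()]), `ho`
#'   ([observed_heterozygosity()]), and `pi` ([nucleotide_diversity()]) plus
#'   its per-population mean `pi_mean`.
#' @export
diversity_metrics <- function(g, pop_labels = NULL) {
  pi <- nucleotide_diversity(g, pop_labels)
  list(fst = weir_cockerham_fst(g, pop_labels),
       ho = observed_heterozygosity(g, pop_labels),
       pi = pi,
       pi_mean = rowMeans(pi, na.rm = TRUE))
}
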