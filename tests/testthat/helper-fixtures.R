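# Shared fixtures, built in code at test time.

# small simulated study (fast): fewer SNPs, everything else at defaults
small_cfg <- function(seed = 1L, n_snps = 500L, ...) {
  args <- list(n_snps = n_snps, seed = seed, ...)
  if (is.null(args$n_trait_loci))
    args$n_trait_loci <- max(2L, min(50L, n_snps %/% 12L))
  do.call(sim_config, args)
}

# tiny genotype matrix from explicit dosages
toy_genotypes <- function(dosages, pops = NULL, chrom = NULL, pos = NULL) {
  m <- ncol(dosages)
  markers <- data.frame(
    id = paste0("s", seq_len(m)),
    chrom = chrom %||% rep("chr1", m),
    pos = pos %||% seq_len(m) * 100L,
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  genotype_matrix(dosages, markers, pop_labels = pops)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# long-form counts from a doy -> count table for one population/year
counts_from_table <- function(doys, counts, population = "p1", year = 2000L) {
  data.frame(population = population, year = year, doy = doys,
             size_class = "combined", count = counts,
             stringsAsFactors = FALSE)
}

# independent Weir & Cockerham (1984) theta oracle, written from the
# variance-component definitions locus by locus (loops, no vectorization)
wc_theta_oracle <- function(dosage_list) {
  r <- length(dosage_list)
  n <- vapply(dosage_list, function(d) sum(!is.na(d)), numeric(1))
  p <- vapply(dosage_list, function(d) mean(d, na.rm = TRUE) / 2, numeric(1))
  h <- vapply(dosage_list, function(d) mean(d == 1, na.rm = TRUE), numeric(1))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# brute-force SNP-to-gene distances within a window
closest_genes_oracle <- function(snps, genes, window) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(genes))) {
      if (snps$chrom[i] != genes$chrom[j]) next
      p <- snps$pos[i]
      d <- if (p >= genes$start[j] && p <= genes$end[j]) 0L
        else if (p < genes$start[j]) genes$start[j] - p
        else p - genes$end[j]
      if (d <= window)
        out[[length(out) + 1L]] <- data.frame(
          snp_id = snps$id[i], gene_id = genes$gene_id[j],
          distance = as.integer(d), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      distance = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$snp_id, res$distance, res$gene_id), , drop = FALSE]
}

# reorder SNP columns of a genotype matrix (test-side helper)
subset_snps_for_test <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$markers[keep, , drop = FALSE],
                  g$individuals, g$pop_labels)
}

# mean silhouette width of a labelled 2-D embedding (no cluster package
# needed: direct definition)
silhouette_mean <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(unique(labels[!own]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
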