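# Genotype I/O, MAF filtering, LD, and diversity metrics.

test_that("VCF round-trip preserves dosages and skips multiallelic sites", {
  cfg <- small_cfg(seed = 21, n_snps = 40)
  g <- simulate_genotypes(cfg)$genotypes
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(g, path)
  g2 <- read_genotypes(path)
  expect_equal(unname(g2$dosages), unname(g$dosages))
  expect_equal(g2$markers$pos, g$markers$pos)
  # inject a multiallelic record (own ID, shifted position)
  lines <- readLines(path)
  f <- strsplit(lines[length(lines)], "\t")[[1]]
  f[2] <- as.integer(f[2]) + 1L; f[3] <- "multi1"; f[5] <- "G,T"
  writeLines(c(lines, paste(f, collapse = "\t")), path)
  expect_message(g3 <- read_genotypes(path), "skipped 1")
  expect_equal(ncol(g3$dosages), ncol(g$dosages))
})

test_that("dosage TSV round-trips and rejects invalid cells", {
  cfg <- small_cfg(seed = 22, n_snps = 10, missing_rate = 0.05)
  g <- suppressWarnings(simulate_genotypes(cfg))$genotypes
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path, format = "dosage")
  g2 <- read_genotypes(path, format = "dosage",
                       markers_path = sub("\\.tsv$", ".markers.tsv", path),
                       popmap = sub("\\.tsv$", ".popmap.tsv", path))
  expect_equal(unname(g2$dosages), unname(g$dosages))
  expect_equal(g2$pop_labels, g$pop_labels)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  tab[2, 3] <- 7
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(path, format = "dosage"), "invalid dosage")
})

test_that("MAF filter uses an inclusive boundary and is idempotent", {
  # columns engineered to MAFs 0, 0.005, 0.01, 0.2, 0.5 over 100 individuals
  n <- 100L
  make_col <- function(n_alt) c(rep(1L, n_alt), rep(0L, n - n_alt))
  d <- cbind(make_col(0), make_col(1), make_col(2), make_col(40), make_col(100))
  g <- toy_genotypes(d)
  expect_equal(unname(snp_maf(g)), c(0, 0.005, 0.01, 0.2, 0.5))
  kept <- maf_filter(g, 0.01)
  expect_equal(kept$markers$id, c("s3", "s4", "s5"))
  expect_equal(maf_filter(kept, 0.01)$markers$id, kept$markers$id)
  expect_equal(ncol(maf_filter(g, 0)$dosages), 5L)
})

test_that("pairwise r2 matches the correlation definition", {
  g <- toy_genotypes(cbind(c(0, 1, 2, 0), c(2, 1, 0, 2),
                           c(0, 2, 0, 2), c(0, 0, 2, 2), c(1, 1, 1, 1)))
  expect_equal(pairwise_r2(g, 1, 1), 1)
  expect_equal(pairwise_r2(g, 1, 2), 1)   # perfect negative correlation
  expect_equal(pairwise_r2(g, 3, 4), 0)   # orthogonal
  expect_true(is.na(pairwise_r2(g, 1, 5)))  # monomorphic partner
})

test_that("LD pruning removes duplicates and leaves no high-LD pair in windows", {
  set.seed(23)
  base <- matrix(rbinom(60 * 20, 2, 0.4), 60, 20)
  dup <- cbind(base[, 1], base)  # duplicate of the first SNP
  g <- toy_genotypes(dup)
  pruned <- ld_prune(g, window_snps = 10, step_snps = 3, r2_threshold = 0.5)
  expect_lt(ncol(pruned$dosages), ncol(g$dosages))
  expect_true(sum(c("s1", "s2") %in% pruned$markers$id) == 1L)
  # exhaustive post-check within every window of the pruned panel
  ids <- match(pruned$markers$id, g$markers$id)
  for (start in seq(1, ncol(g$dosages) - 9, by = 3)) {
    win <- intersect(ids, start:(start + 9))
    if (length(win) < 2) next
    for (i in win) for (j in win) if (i < j)
      expect_lte(pairwise_r2(g, i, j), 0.5 + 1e-12)
  }
  # marker order is preserved and output is a subset
  expect_true(all(diff(match(pruned$markers$id, g$markers$id)) > 0))
  # a panel already below threshold is untouched
  ortho <- toy_genotypes(diag(2, 8)[, 1:6])
  expect_equal(ncol(ld_prune(ortho, 10, 5, 0.5)$dosages), 6L)
})

test_that("Weir-Cockerham theta matches the variance-component oracle", {
  # toy counts: pop1 has 5 ref-hom and 5 alt-hom; pop2 has 9 ref-hom, 1 alt-hom
  d1 <- c(rep(0L, 5), rep(2L, 5))
  d2 <- c(rep(0L, 9), rep(2L, 1))
  g <- toy_genotypes(matrix(c(d1, d2), ncol = 1),
                     pops = rep(c("p1", "p2"), each = 10))
  oracle <- wc_theta_oracle(list(d1, d2))
  fit <- weir_cockerham_fst(g)
  expect_equal(fit$theta_per_snp[1], oracle[["theta"]], tolerance = 1e-12)
  expect_equal(fit$theta_per_snp[1], 0.24444444, tolerance = 1e-7)
})

test_that("theta hits the fixation and no-differentiation edges", {
  fixed <- toy_genotypes(matrix(c(rep(0L, 10), rep(2L, 10)), ncol = 1),
                         pops = rep(c("p1", "p2"), each = 10))
  expect_equal(weir_cockerham_fst(fixed)$theta_mean, 1)
  set.seed(24)
  block <- matrix(rbinom(40 * 30, 2, runif(30, 0.2, 0.8)), 40, 30,
                  byrow = FALSE)
  same <- toy_genotypes(rbind(block, block),
                        pops = rep(c("p1", "p2"), each = 40))
  th <- weir_cockerham_fst(same)$theta_mean
  expect_lte(th, 0)           # no differentiation: estimator noise only
  expect_lt(abs(th), 0.05)
})

test_that("theta is invariant to SNP order and allele-label swap", {
  cfg <- small_cfg(seed = 25, n_snps = 60)
  g <- simulate_genotypes(cfg)$genotypes
  fit <- weir_cockerham_fst(g)
  perm <- sample(60)
  fit_perm <- weir_cockerham_fst(subset_snps_for_test(g, perm))
  expect_equal(fit_perm$theta_mean, fit$theta_mean, tolerance = 1e-12)
  swapped <- g
  swapped$dosages <- 2L - g$dosages
  expect_equal(weir_cockerham_fst(swapped)$theta_per_snp, fit$theta_per_snp,
               tolerance = 1e-12)
})

test_that("heterozygosity and nucleotide diversity match counting oracles", {
  hom <- toy_genotypes(matrix(c(0L, 2L, 0L, 2L), 2), pops = c("p1", "p2"))
  expect_equal(unname(observed_heterozygosity(hom)), c(0, 0))
  het <- toy_genotypes(matrix(1L, 4, 3), pops = rep(c("p1", "p2"), 2))
  expect_equal(unname(observed_heterozygosity(het)), c(1, 1))
  # direct-count toy: p1 dosages {0,1,2} -> p = 0.5, n = 3
  d <- matrix(c(0L, 1L, 2L, 0L, 0L, 1L), ncol = 2)
  g <- toy_genotypes(d, pops = rep("p1", 3))
  expect_equal(unname(observed_heterozygosity(g)), mean(d == 1))
  pi <- nucleotide_diversity(g)
  p1 <- mean(d[, 1]) / 2
  expect_equal(pi[1, 1], 2 * p1 * (1 - p1) * 3 / 2, tolerance = 1e-12)
  mono <- toy_genotypes(matrix(0L, 3, 1), pops = rep("p1", 3))
  expect_equal(unname(nucleotide_diversity(mono)[1, 1]), 0)
})
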