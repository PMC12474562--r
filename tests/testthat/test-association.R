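# pRDA scans, permutation inference, candidate selection, LFMM, and
# two-method intersection.

test_that("unconditioned single-predictor scores match the covariance oracle", {
  set.seed(41)
  for (rep in 1:10) {
    d <- matrix(rbinom(20 * 200, 2, runif(200, 0.1, 0.9)), 20, 200)
    g <- toy_genotypes(d)
    y <- rnorm(20)
    fit <- partial_rda(g, y)
    prep <- scale(apply(d, 2, as.numeric))
    keep <- which(attr(prep, "scaled:scale") > 0)
    covs <- as.numeric(crossprod(prep[, keep], y - mean(y)))
    oracle <- covs / sqrt(sum(covs^2))
    got <- unname(fit$snp_scores)
    if (sum(oracle * got) < 0) oracle <- -oracle
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("a planted phenotype-defining SNP takes the top score", {
  set.seed(42)
  d <- matrix(rbinom(40 * 60, 2, 0.5), 40, 60)
  y <- d[, 17] + rnorm(40, sd = 0.05)
  fit <- partial_rda(toy_genotypes(d), y)
  expect_equal(which.max(abs(fit$snp_scores)), c(s17 = 17L))
})

test_that("an orthogonal phenotype leaves no constrained variance", {
  set.seed(43)
  d <- matrix(rbinom(12 * 5, 2, 0.5), 12, 5)
  g <- toy_genotypes(d)
  prep <- scale(apply(d, 2, as.numeric))
  y <- rnorm(12)
  y <- residuals(lm(y ~ prep))  # orthogonal to every SNP
  fit <- partial_rda(g, y)
  expect_lt(fit$constrained_var, 1e-20)
  expect_error(partial_rda(g, rep(1, 12)), "constant")
})

test_that("scores agree with vegan's RDA on a small instance", {
  skip_if_not_installed("vegan")
  set.seed(44)
  d <- matrix(rbinom(25 * 40, 2, runif(40, 0.2, 0.8)), 25, 40)
  g <- toy_genotypes(d)
  y <- rnorm(25)
  cond <- matrix(rnorm(25 * 2), 25)
  prep <- scale(apply(d, 2, as.numeric))
  vfit <- vegan::rda(prep ~ y + Condition(cond))
  vscores <- vegan::scores(vfit, display = "species", choices = 1)[, 1]
  fit <- partial_rda(g, y, condition = cond)
  expect_gt(abs(cor(unname(fit$snp_scores), unname(vscores))), 0.9999)
})

test_that("permutation p-values honour their bounds and edge cases", {
  set.seed(45)
  d <- matrix(rbinom(30 * 20, 2, 0.5), 30, 20)
  g <- toy_genotypes(d)
  y <- d[, 1] * 2 + d[, 2]  # strong real association
  pt <- rda_permutation_test(g, y, nperm = 999, seed = 1)
  expect_equal(pt$p, 1 / 1000)
  p1 <- rda_permutation_test(g, rnorm(30), nperm = 1, seed = 2)$p
  expect_true(p1 %in% c(0.5, 1))
  pnull <- rda_permutation_test(g, rnorm(30), nperm = 99, seed = 3)$p
  expect_gte(pnull, 1 / 100)
  expect_lte(pnull, 1)
})

test_that("top_fraction implements the ceiling count and tie rules", {
  expect_equal(length(top_fraction(runif(100), 0.01)), 1L)
  expect_equal(unname(top_fraction(rep(1, 10), 0.25)), 1:3)  # ceil(2.5), low idx
  sc <- c(a = 0.1, b = 0.9, c = -0.95, d = 0.2)
  expect_equal(unname(top_fraction(sc, 0.5)), c(2L, 3L))
})

test_that("BH q-values equal the hand step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04, 1.0)
  expect_equal(bh_fdr(p), c(0.05, 0.05, 0.05, 0.05, 1.0))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_equal(bh_fdr(0.32), 0.32)
  # brute-force step-up on a random vector
  set.seed(46)
  pr <- runif(25)
  o <- order(pr)
  stepped <- pmin(1, rev(cummin(rev(pr[o] * 25 / seq_len(25)))))
  oracle <- numeric(25); oracle[o] <- stepped
  expect_equal(bh_fdr(pr), oracle)
})

test_that("LFMM with K = 0 reduces to per-SNP regression", {
  set.seed(47)
  d <- matrix(rbinom(50 * 30, 2, runif(30, 0.2, 0.8)), 50, 30)
  g <- toy_genotypes(d)
  y <- rnorm(50)
  fit <- lfmm_ridge(g, y, K = 0, ridge_lambda = 1e-10)
  prep <- scale(apply(d, 2, as.numeric))
  yc <- y - mean(y)
  oracle_b <- as.numeric(crossprod(prep, yc)) / sum(yc^2)
  expect_equal(fit$effects, oracle_b, tolerance = 1e-6)
})

test_that("LFMM is calibrated on unstructured null data", {
  # study-scale null: K factors absorb a negligible share of iid noise
  gifs <- vapply(1:3, function(seed) {
    set.seed(seed * 100)
    d <- matrix(rbinom(297 * 4000, 2, runif(4000, 0.1, 0.9)), 297, 4000)
    lfmm_ridge(toy_genotypes(d), rnorm(297), K = 3)$gif
  }, numeric(1))
  expect_gt(mean(gifs), 0.8)
  expect_lt(mean(gifs), 1.2)
})

test_that("structure-conditioned pRDA drops pure-structure decoys", {
  # decoys differentiated only by region; truly clined loci carry within-
  # region signal too, so conditioning on PCs should purge decoys from the
  # candidate set
  cfg <- sim_config(seed = 48, n_snps = 1000, n_trait_loci = 25,
                    fst_between_regions = 0.05, fst_within_region = 0.005)
  s <- suppressWarnings(simulate_genotypes(cfg))
  g <- s$genotypes
  region <- rep(cfg$region, each = cfg$n_ind_per_pop)
  y_decoy <- as.numeric(scale(region))  # a pure region-membership phenotype
  pca <- run_pca(g, 3)
  fit <- partial_rda(g, y_decoy, condition = pca$scores)
  expect_lt(fit$constrained_var, 0.01)
})

test_that("method intersection reports doubly supported genes and SNPs", {
  expect_equal(intersect_methods(c("g1", "g2"), c("g3"))$genes, character(0))
  expect_equal(intersect_methods(c("g1", "g2"), c("g2", "g1"))$genes,
               c("g1", "g2"))
  recs <- data.frame(snp_id = c("s1", "s2", "s3"),
                     gene_id = c("g1", "g2", "g2"), distance = c(0, 10, 0))
  out <- intersect_methods(c("g1", "g2", "g4"), c("g2", "g5"), recs)
  expect_equal(out$genes, "g2")
  expect_equal(out$supported_snps, c("s2", "s3"))
})
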