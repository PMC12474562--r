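# Climate PCA, the loading-correlation gate, predictor decorrelation, and
# environmental offset.

test_that("climate PCA projects future rows onto present-day axes", {
  cfg <- small_cfg(seed = 61)
  clim <- simulate_climate(cfg, displacement = 0)
  cp <- climate_pca(clim, 3)
  expect_equal(cp$scores_future, cp$scores_present)
  # dense eigen oracle for the explained fractions
  z <- scale(clim$present)
  ev <- eigen(cov(z), symmetric = TRUE)$values
  expect_equal(cp$explained_var, (ev / sum(ev))[1:3], tolerance = 1e-8)
  # degenerate site count
  tiny <- list(sites = c("a", "b"), present = clim$present[1:2, ],
               future = clim$future[1:2, ])
  class(tiny) <- "climate_table"
  expect_error(climate_pca(tiny), "three sites")
  # constant variable is dropped with a warning
  const <- clim
  const$present[, "BIO3"] <- 1
  const$future[, "BIO3"] <- 1
  expect_warning(cp2 <- climate_pca(const, 2), "BIO3")
  expect_equal(cp2$dropped, "BIO3")
})

test_that("climate-clined loci rank at the top of the GEA scan", {
  cfg <- small_cfg(seed = 62, n_snps = 600, effect_size = 1.5)
  s <- suppressWarnings(simulate_genotypes(cfg))
  clim <- simulate_climate(cfg)
  top <- top_fraction(gea_rda(s$genotypes, clim)$snp_scores, 0.05)
  clined <- unlist(s$truth$trait_loci[c("early", "late")])
  enrich <- mean(top %in% clined) / (length(clined) / cfg$n_snps)
  expect_gt(enrich, 3)
})

test_that("the loading gate uses Bonferroni alpha 0.0167 and detects identity", {
  a <- setNames(rnorm(200), paste0("s", 1:200))
  gate <- correlate_loadings(
    structure(list(snp_scores = a), class = "rda_result"),
    structure(list(snp_scores = a), class = "rda_result"))
  expect_equal(round(gate$alpha_bonf, 4), 0.0167)
  expect_equal(gate$r, 1, tolerance = 1e-12)
  expect_true(gate$passed)
  expect_error(correlate_loadings(
    structure(list(snp_scores = c(x = 1)), class = "rda_result"),
    structure(list(snp_scores = c(y = 1)), class = "rda_result")),
    "shared loci")
})

test_that("the gate passes rarely for independent loadings", {
  set.seed(63)
  hits <- vapply(1:1000, function(i) {
    a <- setNames(rnorm(100), paste0("s", 1:100))
    b <- setNames(rnorm(100), paste0("s", 1:100))
    correlate_loadings(
      structure(list(snp_scores = a), class = "rda_result"),
      structure(list(snp_scores = b), class = "rda_result"))$passed
  }, logical(1))
  expect_lte(mean(hits), 0.03)  # nominal rate is alpha/3 = 0.0167
})

test_that("decorrelation drops the lower-importance member of tight pairs", {
  set.seed(64)
  n <- 40
  x1 <- rnorm(n)
  x <- cbind(a = x1, b = x1 + rnorm(n, sd = 1e-6), c = rnorm(n))
  imp <- c(a = 3, b = 1, c = 2)
  expect_equal(sort(decorrelate_predictors(x, imp, 0.7)), c("a", "c"))
  # all below threshold: unchanged
  y <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_equal(sort(decorrelate_predictors(y, imp, 0.99)), c("a", "b", "c"))
  # three-variable chain against an exhaustive oracle
  z1 <- rnorm(n)
  chain <- cbind(a = z1, b = 0.95 * z1 + rnorm(n, sd = 0.2),
                 c = rnorm(n) + 0.2 * z1)
  impc <- c(a = 1, b = 5, c = 3)
  got <- decorrelate_predictors(chain, impc, 0.7)
  # oracle: the only pair above 0.7 is (a, b); a has lower importance
  cm <- abs(cor(chain)); diag(cm) <- 0
  expect_true(cm["a", "b"] > 0.7 && cm["a", "c"] <= 0.7 && cm["b", "c"] <= 0.7)
  expect_equal(sort(got), c("b", "c"))
})

test_that("environmental offset matches the single-axis closed form", {
  cfg <- small_cfg(seed = 65)
  clim <- simulate_climate(cfg, displacement = 0)
  expect_equal(environmental_offset(clim)$environmental_offset,
               rep(0, cfg$n_pops))
  # shift one variable by delta: offset = |delta/sd| * ||rotation row||_2
  delta <- 0.8
  v <- "BIO3"
  clim2 <- clim
  clim2$future[, v] <- clim2$present[, v] + delta
  cp <- climate_pca(clim2, 2)
  closed <- abs(delta / sd(clim2$present[, v])) *
    sqrt(sum(cp$rotation[v, ]^2))
  eo <- environmental_offset(clim2, 2)
  expect_equal(eo$environmental_offset, rep(closed, cfg$n_pops),
               tolerance = 1e-8)
})

test_that("climate tables round-trip through the long-form TSV", {
  cfg <- small_cfg(seed = 67)
  clim <- simulate_climate(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_climate_table(clim, path)
  back <- read_climate_table(path)
  expect_equal(back$sites, clim$sites)
  expect_equal(back$present, clim$present, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(back$future, clim$future, ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("rank-sum comparison covers exact, tied, and extreme regimes", {
  expect_equal(compare_r2_distributions(c(1, 2, 3), c(1, 2, 3))$p, 1)
  out <- compare_r2_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_true(out$exact)
  expect_equal(out$p, 0.1)
  set.seed(66)
  big <- compare_r2_distributions(rnorm(200, 2), rnorm(200))
  expect_lt(big$p, 1e-6)
})
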