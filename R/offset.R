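# Genotype-environment association, the loading-correlation gate,
# predictor decorrelation, and environmental offset.

#' PCA of a climate table with future projection
#'
#' Standardizes the present-day variables (their means and SDs), drops
#' constant variables with a warning, and computes principal components;
#' future rows are standardized with the present-day parameters and
#' projected onto the same axes, so present and future scores share a space.
#'
#' @param climate a `climate_table` (see [simulate_climate()] or
#'   [read_climate_table()]).
#' @param n_pcs components to keep (3 for genotype-environment association,
#'   2 for environmental offset).
#' @return list of class `climate_pca`: `scores_present`, `scores_future`
#'   (sites x n_pcs), `rotation`, `explained_var`, `dropped`.
#' @export
climate_pca <- function(climate, n_pcs = 3L) {
  pres <- as.matrix(climate$present)
  fut <- as.matrix(climate$future)
  if (nrow(pres) < 3L) stop("need at least three sites for a climate PCA")
  sds <- apply(pres, 2L, sd)
  dropped <- colnames(pres)[sds == 0]
  if (length(dropped))
    warning("dropping constant climate variable(s): ",
            paste(dropped, collapse = ", "))
  keep <- sds > 0
  mu <- colMeans(pres[, keep, drop = FALSE])
  zp <- scale(pres[, keep, drop = FALSE], center = mu, scale = sds[keep])
  zf <- scale(fut[, keep, drop = FALSE], center = mu, scale = sds[keep])
  pc <- prcomp(zp, center = FALSE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  sp <- zp %*% rot
  sf <- zf %*% rot
  rownames(sp) <- rownames(sf) <- climate$sites
  list(scores_present = sp, scores_future = sf, rotation = rot,
       explained_var = pc$sdev[seq_len(n_pcs)]^2 / sum(pc$sdev^2),
       dropped = dropped)
}

#' Genotype-environment association RDA
#'
#' [partial_rda()] with the first `n_climate_pcs` climate principal
#' components (site-level, expanded to individuals through their population
#' labels) as predictors; optionally conditioned on structure PCs. Axis-1
#' SNP loadings are the climate-association scores.
#'
#' @param g a [genotype_matrix()] whose `pop_labels` match `climate$sites`.
#' @param climate a `climate_table`.
#' @param n_climate_pcs climate PCs used as predictors (default 3).
#' @param condition optional conditioning matrix (individuals x k).
#' @param scale scale SNPs to unit variance.
#' @return an `rda_result` (see [partial_rda()]) with the climate PC scores
#'   attached as attribute `climate_pcs`.
#' @export
gea_rda <- function(g, climate, n_climate_pcs = 3L, condition = NULL,
                    scale = TRUE) {
  cp <- climate_pca(climate, n_pcs = n_climate_pcs)
  idx <- match(g$pop_labels, climate$sites)
  if (anyNA(idx))
    stop("population labels missing from the climate table: ",
         paste(unique(g$pop_labels[is.na(idx)]), collapse = ", "))
  X <- cp$scores_present[idx, , drop = FALSE]
  fit <- partial_rda(g, X, condition = condition, scale = scale)
  attr(fit, "climate_pcs") <- cp
  fit
}

#' Correlation gate between trait and climate loadings
#'
#' Correlates axis-1 SNP loadings of a run-timing association with axis-1
#' loadings of the climate association over the loci common to both, using
#' Pearson's correlation when both loading vectors look normal
#' (Shapiro-Wilk p > 0.05 each) and Spearman's rank correlation otherwise.
#' The gate passes when the correlation p-value clears the
#' Bonferroni-corrected threshold `alpha / n_traits` (0.05 / 3 = 0.0167 for
#' the three run-timing phenotypes).
#'
#' @param trait_result `rda_result` for a run-timing phenotype.
#' @param climate_result `rda_result` from [gea_rda()].
#' @param alpha family-wise error target (default 0.05).
#' @param n_traits number of phenotypes tested (default 3).
#' @return list of class `correlation_gate`: `r`, `p`, `method`
#'   (`"pearson"`/`"spearman"`), `alpha_bonf`, `passed`, `n_shared`.
#' @export
correlate_loadings <- function(trait_result, climate_result, alpha = 0.05,
                               n_traits = 3L) {
  a <- trait_result$snp_scores
  b <- climate_result$snp_scores
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) stop("need at least three shared loci")
  a <- a[shared]; b <- b[shared]
  sw <- function(v) {
    if (length(v) > 5000L) v <- v[seq(1L, length(v), length.out = 5000L)]
    shapiro.test(v)$p.value
  }
  method <- if (sw(a) > 0.05 && sw(b) > 0.05) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(a, b, method = method, exact = FALSE))
  alpha_bonf <- alpha / n_traits
  structure(list(r = unname(ct$estimate), p = ct$p.value, method = method,
                 alpha_bonf = alpha_bonf, passed = ct$p.value < alpha_bonf,
                 n_shared = length(shared)),
            class = "correlation_gate")
}

#' Iteratively decorrelate climate predictors
#'
#' While any pair of remaining variables has absolute correlation above
#' `threshold` (computed on the present-day table), the pair with the
#' largest absolute correlation is found and its lower-importance member
#' dropped.
#'
#' @param climate a `climate_table`, or a sites x variables matrix.
#' @param importance named numeric vector of importance for every variable
#'   (e.g. from a preliminary gradient forest on all variables).
#' @param threshold absolute-correlation cutoff (default 0.7).
#' @return character vector of retained variable names.
#' @export
decorrelate_predictors <- function(climate, importance, threshold = 0.7) {
  x <- if (inherits(climate, "climate_table")) climate$present else
    as.matrix(climate)
  vars <- colnames(x)
  if (!all(vars %in% names(importance)))
    stop("importance must be named for every climate variable")
  keep <- vars
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(suppressWarnings(cor(x[, keep, drop = FALSE])))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- keep[ij]
    victim <- pair[which.min(importance[pair])]
    keep <- setdiff(keep, victim)
  }
  keep
}

#' Environmental offset
#'
#' Euclidean distance between each site's present and projected future
#' positions in the space of the first two climate principal components --
#' the expected climate change irrespective of genetics.
#'
#' @param climate a `climate_table`.
#' @param n_pcs PCs of the climate space (default 2).
#' @return data.frame: site, environmental_offset.
#' @export
environmental_offset <- function(climate, n_pcs = 2L) {
  cp <- climate_pca(climate, n_pcs = n_pcs)
  d <- sqrt(rowSums((cp$scores_future - cp$scores_present)^2))
  data.frame(site = climate$sites, environmental_offset = as.numeric(d),
             stringsAsFactors = FALSE)
}

#' Compare cross-validated R-squared distributions
#'
#' Two-sided Wilcoxon rank-sum test of per-locus cross-validated R-squared
#' for run-timing loci versus background climate loci. The exact null
#' distribution is enumerated when both samples have at most 10 values and
#' no ties; otherwise the tie-corrected normal approximation is used.
#'
#' @param r2_trait_loci,r2_background_loci numeric vectors.
#' @return list: `p`, `statistic` (rank-sum W of the first sample),
#'   `exact`.
#' @export
compare_r2_distributions <- function(r2_trait_loci, r2_background_loci) {
  a <- r2_trait_loci[!is.na(r2_trait_loci)]
  b <- r2_background_loci[!is.na(r2_background_loci)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- length(a) <= 10L && length(b) <= 10L &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact))
  list(p = wt$p.value, statistic = unname(wt$statistic), exact = exact)
}

#' Per-population allele frequencies at selected loci
#'
#' @param g a [genotype_matrix()].
#' @param loci marker ids or column indices.
#' @return loci x populations matrix of alternate-allele frequencies.
#' @export
population_allele_freqs <- function(g, loci = seq_len(ncol(g$dosages))) {
  if (is.character(loci)) loci <- match(loci, g$markers$id)
  pops <- unique(g$pop_labels)
  out <- vapply(pops, function(p) {
    colMeans(g$dosages[g$pop_labels == p, loci, drop = FALSE],
             na.rm = TRUE) / 2
  }, numeric(length(loci)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(loci))
  dimnames(out) <- list(g$markers$id[loci], pops)
  out
}

#' Read a climate table from TSV
#'
#' Long-form TSV with columns site, variable, present, future.
#'
#' @param path file path.
#' @return a `climate_table`.
#' @export
read_climate_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("site", "variable", "present", "future")
  if (!all(need %in% names(tab)))
    stop("climate TSV needs columns: ", paste(need, collapse = ", "))
  sites <- unique(tab$site)
  vars <- unique(tab$variable)
  shape <- function(col) {
    m <- matrix(NA_real_, length(sites), length(vars),
                dimnames = list(NULL, vars))
    m[cbind(match(tab$site, sites), match(tab$variable, vars))] <- tab[[col]]
    m
  }
  structure(list(sites = sites, present = shape("present"),
                 future = shape("future")), class = "climate_table")
}

#' Write a climate table as TSV
#' @param climate a `climate_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_climate_table <- function(climate, path) {
  vars <- colnames(climate$present)
  long <- data.frame(
    site = rep(climate$sites, times = length(vars)),
    variable = rep(vars, each = length(climate$sites)),
    present = as.numeric(climate$present),
    future = as.numeric(climate$future))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
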