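# Genome-wide association: partial redundancy analysis, ridge latent factor
# mixed models, candidate selection, and two-method intersection.

# residualize the columns of m on cbind(1, cond) by least squares
.residualize <- function(m, cond = NULL) {
  m <- as.matrix(m)
  X <- if (is.null(cond)) matrix(1, nrow(m), 1L) else cbind(1, as.matrix(cond))
  qr_x <- qr(X)
  m - qr.fitted(qr_x, m)
}

#' Partial redundancy analysis association scan
#'
#' Constrained ordination of the (mean-imputed, centred, optionally scaled)
#' genotype matrix on one or more predictors, after projecting both the
#' genotypes and the predictors out of a conditioning block (typically the
#' first structure PCs). Per-SNP association scores are the SNP loadings on
#' the first constrained axis; with a single predictor there is exactly one
#' constrained axis and (unconditioned) the scores are proportional to the
#' per-SNP covariance with the predictor.
#'
#' @param g a [genotype_matrix()].
#' @param phenotype numeric vector (length = individuals) or matrix of
#'   predictors (e.g. climate PCs).
#' @param condition optional conditioning matrix (individuals x k), e.g. PC
#'   scores; `NULL` for a simple RDA.
#' @param scale scale SNPs to unit variance.
#' @return object of class `rda_result`: `snp_scores` (named, unit-norm
#'   axis-1 loadings), `constrained_var` (fraction of conditioned variance
#'   explained by all constrained axes), `axis_var`, `kept`, `conditioned`,
#'   and the pieces needed by [rda_permutation_test()].
#' @export
partial_rda <- function(g, phenotype, condition = NULL, scale = TRUE) {
  X <- as.matrix(phenotype)
  if (nrow(X) != nrow(g$dosages))
    stop("phenotype length must equal the number of individuals")
  if (any(apply(X, 2L, var) == 0))
    stop("phenotype is constant; no constrained variance exists")
  prep <- impute_center_scale(g$dosages, scale = scale)
  Yr <- .residualize(prep$x, condition)
  Xr <- .residualize(X, condition)
  qr_x <- qr(Xr)
  if (qr_x$rank < ncol(Xr))
    stop("predictors are collinear after conditioning")
  fitted <- qr.fitted(qr_x, Yr)
  sv <- svd(fitted, nu = qr_x$rank, nv = qr_x$rank)
  v1 <- sv$v[, 1L]
  nz <- which(abs(v1) > 1e-12)[1L]
  if (!is.na(nz) && v1[nz] < 0) v1 <- -v1
  names(v1) <- g$markers$id[prep$kept]
  total <- sum(Yr^2)
  structure(list(
    snp_scores = v1,
    constrained_var = sum(sv$d[seq_len(qr_x$rank)]^2) / total,
    axis_var = sv$d[seq_len(qr_x$rank)]^2 / total,
    kept = prep$kept,
    conditioned = !is.null(condition),
    .Yr = Yr, .Xr = Xr
  ), class = "rda_result")
}

#' Permutation test of the (partial) RDA
#'
#' Permutes the rows of the residualized predictors (residualized-response
#' permutation under conditioning), recomputes the constrained variance, and
#' returns `p = (1 + #\{perm >= observed\}) / (1 + nperm)`.
#'
#' @inheritParams partial_rda
#' @param nperm number of permutations.
#' @param seed permutation seed.
#' @return list: `p`, `observed` (constrained SS), `perm` (permuted SS).
#' @export
rda_permutation_test <- function(g, phenotype, condition = NULL,
                                 nperm = 999L, seed = 1L, scale = TRUE) {
  stopifnot(nperm >= 1)
  fit <- partial_rda(g, phenotype, condition, scale = scale)
  Yr <- fit$.Yr
  Xr <- fit$.Xr
  n <- nrow(Yr)
  set.seed(seed)
  if (ncol(Xr) == 1L) {
    # single predictor: constrained SS = ||Y' x||^2 / ||x||^2, vectorizable
    x <- Xr[, 1L]
    obs <- sum(crossprod(Yr, x)^2) / sum(x^2)
    P <- vapply(seq_len(nperm), function(b) sample.int(n), integer(n))
    Xp <- matrix(x[P], n, nperm)
    S <- crossprod(Yr, Xp)                    # M x nperm
    perm <- colSums(S^2) / colSums(Xp^2)
  } else {
    obs_fit <- qr.fitted(qr(Xr), Yr)
    obs <- sum(obs_fit^2)
    perm <- vapply(seq_len(nperm), function(b) {
      Xp <- Xr[sample.int(n), , drop = FALSE]
      sum(qr.fitted(qr(Xp), Yr)^2)
    }, numeric(1))
  }
  list(p = (1 + sum(perm >= obs)) / (1 + nperm), observed = obs, perm = perm)
}

#' Top-fraction candidate selection
#'
#' Selects the `ceiling(fraction * M)` SNPs with the largest absolute
#' scores; ties broken by lower marker index. With M = 141,263 and the 1%
#' rule this yields 1,413 candidates.
#'
#' @param scores per-SNP numeric scores (names preserved).
#' @param fraction fraction in (0, 1).
#' @return integer vector of selected indices, sorted increasing; names
#'   carried over when `scores` is named.
#' @export
top_fraction <- function(scores, fraction = 0.01) {
  stopifnot(fraction > 0, fraction < 1)
  k <- top_count(length(scores), fraction)
  sel <- sort(order(-abs(scores), seq_along(scores))[seq_len(k)])
  if (!is.null(names(scores))) names(sel) <- names(scores)[sel]
  sel
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Ridge latent factor mixed model association scan
#'
#' Per-SNP association of genotype with a predictor while K latent factors
#' absorb unobserved structure. Alternates (1) rank-K truncated SVD of the
#' residual matrix after removing current fixed effects and (2) per-SNP
#' ridge regression of the latent-adjusted genotypes on the predictor.
#' z-scores are effect/SE; p-values come from a chi-square(1) reference
#' after genomic-inflation-factor calibration
#' (`gif = median(z^2) / 0.4549`, the chi-square(1) median), and q-values by
#' Benjamini-Hochberg.
#'
#' @param g a [genotype_matrix()].
#' @param phenotype numeric vector, one value per individual.
#' @param K latent factor count (0 reduces to ordinary per-SNP regression).
#' @param ridge_lambda ridge penalty on the per-SNP effect.
#' @param fdr_alpha candidate threshold on q.
#' @param scale scale SNPs to unit variance.
#' @param max_iter,tol alternation control.
#' @return object of class `lfmm_result`: `effects`, `z_scores`, `p_values`
#'   (calibrated), `q_values`, `gif`, `K`, `candidates` (indices with
#'   q < `fdr_alpha`), `kept`, `converged`.
#' @export
lfmm_ridge <- function(g, phenotype, K = 3L, ridge_lambda = 1e-5,
                       fdr_alpha = 0.05, scale = TRUE, max_iter = 50L,
                       tol = 1e-7) {
  stopifnot(length(phenotype) == nrow(g$dosages))
  if (K >= min(dim(g$dosages))) stop("K must be < min(individuals, SNPs)")
  prep <- impute_center_scale(g$dosages, scale = scale)
  Y <- prep$x
  x <- as.numeric(scale(phenotype, scale = FALSE))
  n <- nrow(Y)
  xtx <- sum(x^2)
  ridge_b <- function(R) as.numeric(crossprod(R, x)) / (xtx + ridge_lambda)
  # Latent factors are estimated from the genotype matrix projected off the
  # (ridge-damped) predictor direction, so structure collinear with the
  # predictor cannot swallow the fixed effects; effects are then re-estimated
  # by per-SNP ridge against the latent-adjusted matrix, and the pair is
  # refined by a short alternation that keeps the factors in the projected
  # space.
  b <- numeric(ncol(Y))
  L <- matrix(0, n, ncol(Y))
  converged <- TRUE
  if (K > 0L) {
    damp <- xtx / (xtx + ridge_lambda)
    proj_off_x <- function(M) M - tcrossprod(x, as.numeric(crossprod(M, x))) *
      (damp / xtx)
    obj_old <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Rlat <- proj_off_x(Y - tcrossprod(x, b))
      sv <- svd(Rlat, nu = K, nv = K)
      L <- sv$u %*% (sv$d[seq_len(K)] * t(sv$v))
      b <- ridge_b(Y - L)
      obj <- sum((Y - L - tcrossprod(x, b))^2)
      if (obj_old - obj <= tol * max(1, obj_old)) { converged <- TRUE; break }
      obj_old <- obj
    }
    if (!converged)
      warning("lfmm_ridge did not converge in ", max_iter,
              " iterations; returning best iterate")
  } else {
    b <- ridge_b(Y)
  }
  Resid <- Y - L - tcrossprod(x, b)
  df <- max(1L, n - 2L - K)
  sigma2 <- colSums(Resid^2) / df
  se <- sqrt(sigma2 * xtx) / (xtx + ridge_lambda)
  z <- b / se
  gif <- median(z^2) / qchisq(0.5, df = 1)
  p <- pchisq(z^2 / gif, df = 1, lower.tail = FALSE)
  q <- bh_fdr(p)
  names(z) <- names(p) <- names(q) <- g$markers$id[prep$kept]
  structure(list(effects = b, z_scores = z, p_values = p, q_values = q,
                 gif = gif, K = K, candidates = which(q < fdr_alpha),
                 kept = prep$kept, converged = converged),
            class = "lfmm_result")
}

#' Intersect gene-level support from two association methods
#'
#' Genes detected by both the RDA route and the LFMM route; RDA candidate
#' SNPs lying inside such doubly supported genes are flagged.
#'
#' @param rda_genes character vector of gene ids annotated to RDA candidates.
#' @param lfmm_genes character vector of gene ids annotated to LFMM
#'   candidates.
#' @param rda_records optional data.frame (snp_id, gene_id, distance) from
#'   [closest_genes()] for the RDA candidates.
#' @return list: `genes` (sorted intersection), `supported_snps` (snp ids of
#'   RDA candidates inside supported genes, if records given).
#' @export
intersect_methods <- function(rda_genes, lfmm_genes, rda_records = NULL) {
  genes <- sort(intersect(unique(rda_genes), unique(lfmm_genes)))
  supported <- character(0)
  if (!is.null(rda_records) && length(genes))
    supported <- sort(unique(rda_records$snp_id[rda_records$gene_id %in% genes]))
  list(genes = genes, supported_snps = supported)
}
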