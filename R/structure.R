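# Population structure: PCA, componentwise locus contributions, and
# NMF-based ancestry with masked cross-entropy K selection.

#' Principal component analysis of genotypes
#'
#' Mean-imputes missing dosages, centres and (by default) scales each SNP to
#' unit variance (zero-variance SNPs dropped), and takes the singular value
#' decomposition. Scores are left singular vectors times singular values.
#' Each PC is oriented so that its first nonzero SNP loading is positive.
#'
#' @param g a [genotype_matrix()].
#' @param n_pcs number of components to return.
#' @param scale scale SNPs to unit variance (in addition to centring).
#' @return object of class `pca_model`: `scores` (individuals x PCs),
#'   `loadings` (SNPs x PCs), `explained_var` (fraction per PC), `kept`
#'   (SNP columns used), `d` (singular values).
#' @export
run_pca <- function(g, n_pcs = 10L, scale = TRUE) {
  if (nrow(g$dosages) < 2L || ncol(g$dosages) < 2L)
    stop("need at least two individuals and two SNPs")
  prep <- impute_center_scale(g$dosages, scale = scale)
  x <- prep$x
  if (all(abs(x) < 1e-12)) stop("genotype matrix is constant after centring")
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  sv <- svd(x)
  total <- sum(sv$d^2)
  # orient: first loading of each PC with |loading| > tol made positive
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- sv$v[, j]
    nz <- which(abs(v) > 1e-12)[1L]
    if (is.na(nz) || v[nz] >= 0) 1 else -1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(n_pcs), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_pcs)], n_pcs), 2L, flip, "*")
  loadings <- sweep(sv$v[, seq_len(n_pcs), drop = FALSE], 2L, flip, "*")
  rownames(scores) <- g$individuals
  rownames(loadings) <- g$markers$id[prep$kept]
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_pcs))
  structure(list(scores = scores, loadings = loadings,
                 explained_var = sv$d[seq_len(n_pcs)]^2 / total,
                 kept = prep$kept, d = sv$d),
            class = "pca_model")
}

#' Componentwise outlier SNP sets
#'
#' Per principal component, SNPs are ranked by squared loading and the top
#' fraction selected with the ceiling count rule (ties broken by lower
#' marker index) -- the locus sets contributing most to each axis of
#' differentiation.
#'
#' @param model a [run_pca()] fit.
#' @param top_fraction fraction of SNPs per component.
#' @return named list, one integer vector of SNP indices (into the loading
#'   rows) per PC.
#' @export
componentwise_loadings <- function(model, top_fraction = 0.01) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  m <- nrow(model$loadings)
  k <- top_count(m, top_fraction)
  sets <- lapply(seq_len(ncol(model$loadings)), function(j) {
    sq <- model$loadings[, j]^2
    sort(order(-sq, seq_len(m))[seq_len(k)])
  })
  names(sets) <- colnames(model$loadings)
  sets
}

# weighted Frobenius objective ||W * (F - QG)||^2
.nmf_obj <- function(F, Q, G, W) sum(W * (F - Q %*% G)^2)

# one projected-gradient block update with backtracking (monotone)
.pg_update <- function(X, grad, project, objective, step0 = 1) {
  f0 <- objective(X)
  step <- step0
  for (it in 1:30) {
    Xn <- project(X - step * grad)
    if (objective(Xn) <= f0) return(list(X = Xn, step = step))
    step <- step / 2
  }
  list(X = X, step = step)
}

#' Ancestry estimation by constrained nonnegative matrix factorization
#'
#' Factorizes the individuals x SNPs frequency matrix (dosage / 2, missing
#' mean-imputed) as `Q %*% G` with `Q` rows on the probability simplex
#' (admixture proportions) and `G` in \[0, 1\] (ancestral allele
#' frequencies), by alternating projected-gradient descent with backtracking
#' line search, which makes the objective non-increasing. Entries listed in
#' `mask` are held out of the fit (used for cross-entropy K selection).
#'
#' @param g a [genotype_matrix()].
#' @param K number of ancestral clusters.
#' @param seed seed for the random initialization.
#' @param mask optional logical matrix (same shape as dosages); `TRUE`
#'   entries are excluded from the fitting objective.
#' @param max_iter,tol iteration cap and relative objective tolerance.
#' @return object of class `ancestry_model`: `Q`, `G`, `objective` (trace),
#'   `converged`.
#' @export
fit_ancestry <- function(g, K, seed = 1L, mask = NULL, max_iter = 200L,
                         tol = 1e-6) {
  stopifnot(K >= 1)
  F <- impute_center_scale(g$dosages, scale = FALSE)
  F <- sweep(F$x, 2L, F$center, "+") / 2  # back to frequencies in [0,1]
  n <- nrow(F); M <- ncol(F)
  W <- if (is.null(mask)) matrix(1, n, M) else (!mask) * 1
  set.seed(seed)
  Q <- matrix(runif(n * K), n, K)
  Q <- Q / rowSums(Q)
  G <- matrix(runif(K * M, 0.1, 0.9), K, M)
  obj <- .nmf_obj(F, Q, G, W)
  trace <- obj
  step_q <- step_g <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # Q block
    R <- W * (Q %*% G - F)
    gradQ <- 2 * (R %*% t(G))
    lipQ <- 2 * max(colSums(G^2)) * K + 1e-9
    up <- .pg_update(Q, gradQ,
                    function(X) {
                      if (ncol(X) == 1L) return(matrix(1, nrow(X), 1L))
                      t(apply(X, 1L, project_simplex))
                    },
                    function(X) .nmf_obj(F, X, G, W),
                    step0 = step_q %||% (1 / lipQ))
    Q <- up$X; step_q <- up$step * 2
    # G block
    R <- W * (Q %*% G - F)
    gradG <- 2 * (t(Q) %*% R)
    lipG <- 2 * max(colSums(Q^2)) * K + 1e-9
    up <- .pg_update(G, gradG,
                    function(X) pmin(pmax(X, 0), 1),
                    function(X) .nmf_obj(F, Q, X, W),
                    step0 = step_g %||% (1 / lipG))
    G <- up$X; step_g <- up$step * 2
    new_obj <- .nmf_obj(F, Q, G, W)
    trace <- c(trace, new_obj)
    if (obj - new_obj <= tol * max(1, obj)) { converged <- TRUE; obj <- new_obj; break }
    obj <- new_obj
  }
  if (!converged)
    warning("ancestry fit did not converge in ", max_iter,
            " iterations; returning best iterate")
  structure(list(Q = Q, G = G, objective = trace, converged = converged,
                 K = K), class = "ancestry_model")
}

# binomial cross-entropy of held-out dosages against predicted frequencies
.masked_cross_entropy <- function(dosages, Q, G, mask) {
  pred <- Q %*% G
  pred <- pmin(pmax(pred, 1e-6), 1 - 1e-6)
  x <- dosages[mask] / 2
  f <- pred[mask]
  ok <- !is.na(x)
  -mean(x[ok] * log(f[ok]) + (1 - x[ok]) * log(1 - f[ok]))
}

#' Choose the number of ancestral clusters by masked cross-entropy
#'
#' Masks a random fraction of dosage entries, fits [fit_ancestry()] for each
#' K in `K_range` on the unmasked entries, and scores each K by the binomial
#' cross-entropy of the masked entries against predicted frequencies
#' `Q %*% G`. Returns the elbow: the smallest K whose improvement over the
#' next K falls below `tol` relative cross-entropy.
#'
#' @param g a [genotype_matrix()].
#' @param K_range candidate K values (increasing).
#' @param holdout_fraction fraction of entries masked, in (0, 0.5).
#' @param seed seed (mask and every fit derive from it).
#' @param tol relative-improvement elbow tolerance.
#' @return list: `K` (chosen), `cross_entropy` (named per K), `fits`.
#' @export
choose_k <- function(g, K_range = 1:6, holdout_fraction = 0.1, seed = 1L,
                     tol = 0.02) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 0.5)
  set.seed(seed)
  mask <- matrix(runif(length(g$dosages)) < holdout_fraction,
                 nrow(g$dosages))
  mask[is.na(g$dosages)] <- FALSE
  ce <- numeric(length(K_range))
  fits <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    fits[[i]] <- fit_ancestry(g, K_range[i], seed = seed + i, mask = mask)
    ce[i] <- .masked_cross_entropy(g$dosages, fits[[i]]$Q, fits[[i]]$G, mask)
  }
  names(ce) <- K_range
  chosen <- K_range[length(K_range)]
  for (i in seq_len(length(K_range) - 1L)) {
    if ((ce[i] - ce[i + 1L]) <= tol * abs(ce[i])) { chosen <- K_range[i]; break }
  }
  list(K = chosen, cross_entropy = ce, fits = fits)
}
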