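# Shared numerical helpers.

#' Mean-impute, centre and optionally scale a dosage matrix
#'
#' Missing dosages are replaced by the per-SNP mean of observed dosages;
#' columns are then centred and (optionally) scaled to unit variance.
#' Zero-variance columns cannot be scaled and are dropped.
#'
#' @param dosages numeric matrix, individuals x SNPs, entries 0/1/2 or `NA`.
#' @param scale logical; divide each column by its standard deviation.
#' @return list with `x` (transformed matrix), `kept` (column indices
#'   retained), `center` and `scale` vectors for the kept columns.
#' @keywords internal
impute_center_scale <- function(dosages, scale = TRUE) {
  x <- as.matrix(dosages)
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2L]]
  }
  ctr <- colMeans(x)
  x <- sweep(x, 2L, ctr, "-")
  sds <- sqrt(colSums(x^2) / max(1L, nrow(x) - 1L))
  kept <- seq_len(ncol(x))
  if (scale) {
    kept <- which(sds > 0)
    if (length(kept) == 0L)
      stop("all SNPs have zero variance; nothing to analyse")
    x <- sweep(x[, kept, drop = FALSE], 2L, sds[kept], "/")
  }
  list(x = x, kept = kept, center = ctr[kept], scale = if (scale) sds[kept] else rep(1, length(kept)))
}

#' Euclidean projection of a vector onto the probability simplex
#' @param v numeric vector.
#' @return non-negative vector of the same length summing to 1.
#' @keywords internal
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# ceiling-count selection rule shared by top-fraction style selections
top_count <- function(m, fraction) as.integer(ceiling(fraction * m))

`%||%` <- function(a, b) if (is.null(a)) b else a
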