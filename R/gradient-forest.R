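# Gradient-forest turnover modelling: per-locus random forests of regression
# trees over few sites, split-importance accumulated along each predictor's
# gradient into monotone turnover functions.
#
# Written for the small-n regime of population-level allele frequencies
# (sites = populations), where each tree is tiny; trees record the predictor,
# split value (midpoint), and impurity reduction of every split.

# Fit one regression tree on (x: n x p matrix, y) over row indices `rows`.
# Returns a flat data.frame of nodes. mtry predictors are sampled per node.
.fit_tree <- function(x, y, rows, mtry, min_leaf) {
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  build <- function(rows) {
    id <- new_node()
    yv <- y[rows]
    n <- length(rows)
    node <- list(id = id, pred = mean(yv), var = NA_integer_,
                 split = NA_real_, delta = NA_real_, left = NA_integer_,
                 right = NA_integer_)
    nodes[[id]] <<- node  # reserve slot
    parent_ss <- sum((yv - mean(yv))^2)
    if (n < 2L * min_leaf || parent_ss <= 0) return(id)
    best <- list(delta = 0)
    for (j in sample.int(ncol(x), mtry)) {
      xv <- x[rows, j]
      ord <- order(xv)
      xs <- xv[ord]; ys <- yv[ord]
      cs <- cumsum(ys); css <- cumsum(ys^2)
      tot <- cs[n]; tots <- css[n]
      k <- seq_len(n - 1L)
      valid <- (xs[k] < xs[k + 1L]) & (k >= min_leaf) & ((n - k) >= min_leaf)
      if (!any(valid)) next
      ss_left <- css[k] - cs[k]^2 / k
      ss_right <- (tots - css[k]) - (tot - cs[k])^2 / (n - k)
      delta <- parent_ss - (ss_left + ss_right)
      delta[!valid] <- -Inf
      kb <- which.max(delta)
      if (delta[kb] > best$delta) {
        best <- list(delta = delta[kb], var = j,
                     split = (xs[kb] + xs[kb + 1L]) / 2,
                     left_rows = rows[ord[seq_len(kb)]],
                     right_rows = rows[ord[(kb + 1L):n]])
      }
    }
    if (best$delta <= 0) return(id)
    left_id <- build(best$left_rows)
    right_id <- build(best$right_rows)
    nodes[[id]]$var <<- best$var
    nodes[[id]]$split <<- best$split
    nodes[[id]]$delta <<- best$delta
    nodes[[id]]$left <<- left_id
    nodes[[id]]$right <<- right_id
    id
  }
  build(rows)
  nodes
}

.predict_tree <- function(nodes, x_new) {
  apply(x_new, 1L, function(row) {
    id <- 1L
    repeat {
      nd <- nodes[[id]]
      if (is.na(nd$var)) return(nd$pred)
      id <- if (row[nd$var] <= nd$split) nd$left else nd$right
    }
  })
}

# forest for one locus: OOB R^2 and per-split importance records
.fit_forest_one <- function(x, y, n_trees, mtry, min_leaf) {
  n <- nrow(x)
  oob_sum <- numeric(n)
  oob_n <- integer(n)
  splits <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    bag <- sample.int(n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(bag))
    nodes <- .fit_tree(x, y, bag, mtry, min_leaf)
    internal <- Filter(function(nd) !is.na(nd$var), nodes)
    if (length(internal))
      splits[[t]] <- data.frame(
        var = vapply(internal, `[[`, 0L, "var"),
        value = vapply(internal, `[[`, 0, "split"),
        delta = vapply(internal, `[[`, 0, "delta"))
    if (length(oob)) {
      pred <- .predict_tree(nodes, x[oob, , drop = FALSE])
      oob_sum[oob] <- oob_sum[oob] + pred
      oob_n[oob] <- oob_n[oob] + 1L
    }
  }
  seen <- oob_n > 0L
  r2 <- NA_real_
  if (any(seen)) {
    pred <- oob_sum[seen] / oob_n[seen]
    mse <- mean((y[seen] - pred)^2)
    r2 <- 1 - mse / mean((y - mean(y))^2)
  }
  sp <- do.call(rbind, splits[!vapply(splits, is.null, TRUE)])
  list(r2 = r2, splits = sp)
}

#' Fit a gradient-forest turnover model
#'
#' For each locus (row of `allele_freqs`) fits a random forest of `n_trees`
#' regression trees of allele frequency on the climate predictors (bootstrap
#' rows, `mtry` predictors per split). Loci with positive out-of-bag
#' R-squared are retained; each retained locus contributes its split
#' impurity reductions -- normalized within locus and weighted by its
#' R-squared -- at the predictor values where the splits occurred. The
#' per-predictor cumulative sums of these contributions, normalized to total
#' 1 across predictors, are the monotone turnover functions. Predictors with
#' zero accumulated importance are removed and the forests rebuilt.
#'
#' @param allele_freqs loci x sites matrix of per-population allele
#'   frequencies.
#' @param predictors sites x variables data.frame or matrix of climate
#'   values.
#' @param n_trees trees per locus (default 500).
#' @param mtry predictors sampled per split (default `ceiling(p / 3)`).
#' @param min_leaf minimum rows per leaf (default 2 -- the small-n regime of
#'   population-level frequencies).
#' @param seed forest seed.
#' @param drop_zero_importance remove predictors that accumulate no
#'   importance and rebuild (default TRUE).
#' @return object of class `turnover_model`: `functions` (per predictor, a
#'   data.frame value/cum of the cumulative importance step function),
#'   `importance` (total rise per predictor; sums to 1), `r2` (per-locus
#'   out-of-bag R-squared), `retained_loci`, `predictors` (names used),
#'   `train_range`, `n_trees`.
#' @export
fit_gradient_forest <- function(allele_freqs, predictors, n_trees = 500L,
                                mtry = NULL, min_leaf = 2L, seed = 1L,
                                drop_zero_importance = TRUE) {
  x <- as.matrix(predictors)
  if (nrow(x) < 5L) stop("need at least five sites")
  if (nrow(x) < 2L * min_leaf) stop("fewer sites than twice the leaf size")
  allele_freqs <- as.matrix(allele_freqs)
  if (ncol(allele_freqs) != nrow(x))
    stop("allele_freqs columns must match predictor rows (sites)")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(rownames(allele_freqs)))
    rownames(allele_freqs) <- paste0("locus", seq_len(nrow(allele_freqs)))
  build <- function(x) {
    mtry_use <- mtry %||% ceiling(ncol(x) / 3)
    res <- lapply(seq_len(nrow(allele_freqs)), function(l)
      .fit_forest_one(x, allele_freqs[l, ], n_trees, mtry_use, min_leaf))
    r2 <- vapply(res, `[[`, 0, "r2")
    names(r2) <- rownames(allele_freqs)
    retained <- which(!is.na(r2) & r2 > 0)
    # aggregate: per locus normalize split deltas to sum 1, weight by R^2
    agg <- list()
    for (l in retained) {
      sp <- res[[l]]$splits
      if (is.null(sp) || nrow(sp) == 0L) next
      sp$w <- r2[l] * sp$delta / sum(sp$delta)
      agg[[length(agg) + 1L]] <- sp[, c("var", "value", "w")]
    }
    agg <- if (length(agg)) do.call(rbind, agg) else
      data.frame(var = integer(0), value = numeric(0), w = numeric(0))
    list(r2 = r2, retained = retained, agg = agg)
  }
  set.seed(seed)
  fitres <- build(x)
  imp_by_var <- vapply(seq_len(ncol(x)), function(j)
    sum(fitres$agg$w[fitres$agg$var == j]), numeric(1))
  if (drop_zero_importance && any(imp_by_var == 0) && any(imp_by_var > 0)) {
    x <- x[, imp_by_var > 0, drop = FALSE]
    set.seed(seed)
    fitres <- build(x)
    imp_by_var <- vapply(seq_len(ncol(x)), function(j)
      sum(fitres$agg$w[fitres$agg$var == j]), numeric(1))
  }
  total_w <- sum(fitres$agg$w)
  if (total_w <= 0)
    warning("no split importance accumulated; turnover functions are flat")
  fns <- lapply(seq_len(ncol(x)), function(j) {
    sp <- fitres$agg[fitres$agg$var == j, , drop = FALSE]
    if (nrow(sp) == 0L)
      return(data.frame(value = numeric(0), cum = numeric(0)))
    w <- tapply(sp$w, sp$value, sum)
    v <- as.numeric(names(w))
    ord <- order(v)
    data.frame(value = v[ord],
               cum = cumsum(as.numeric(w)[ord]) / max(total_w, 1e-300))
  })
  names(fns) <- colnames(x)
  importance <- vapply(fns, function(f)
    if (nrow(f)) f$cum[nrow(f)] else 0, numeric(1))
  structure(list(functions = fns, importance = importance, r2 = fitres$r2,
                 retained_loci = names(fitres$r2)[fitres$retained],
                 predictors = colnames(x),
                 train_range = apply(x, 2L, range),
                 n_trees = n_trees),
            class = "turnover_model")
}

#' Evaluate a turnover function
#'
#' Piecewise-constant, right-continuous cumulative importance: 0 below the
#' first split value, the total rise above the last. Values outside the
#' training range are effectively clamped to the endpoints.
#'
#' @param model a [fit_gradient_forest()] fit.
#' @param predictor predictor name.
#' @param values numeric values at which to evaluate.
#' @return numeric vector of cumulative importance.
#' @export
turnover_at <- function(model, predictor, values) {
  f <- model$functions[[predictor]]
  if (is.null(f)) stop("unknown predictor: ", predictor)
  if (nrow(f) == 0L) return(rep(0, length(values)))
  idx <- findInterval(values, f$value)
  c(0, f$cum)[idx + 1L]
}

#' Trait-specific genomic offset
#'
#' Transforms each site's present and future climate through the turnover
#' functions and returns the per-site Euclidean distance between the two
#' transformed vectors -- the cumulative-importance change the population
#' must track. Future values beyond the training range are clamped at the
#' function endpoints (with a warning).
#'
#' @param model a [fit_gradient_forest()] fit.
#' @param present,future sites x predictors matrices (must contain the
#'   model's predictors as columns).
#' @return object of class `offset_result`: data.frame with site,
#'   genomic_offset; plus attribute `most_important_variable`.
#' @export
genomic_offset <- function(model, present, future) {
  present <- as.matrix(present)
  future <- as.matrix(future)
  vars <- model$predictors
  if (!all(vars %in% colnames(present)) || !all(vars %in% colnames(future)))
    stop("present/future tables must contain the model predictors")
  rng <- model$train_range
  outside <- vapply(vars, function(v)
    any(future[, v] < rng[1L, v] | future[, v] > rng[2L, v]), logical(1))
  if (any(outside))
    warning("future values outside the training range for: ",
            paste(vars[outside], collapse = ", "),
            "; turnover clamped at function endpoints")
  tp <- vapply(vars, function(v) turnover_at(model, v, present[, v]),
               numeric(nrow(present)))
  tf <- vapply(vars, function(v) turnover_at(model, v, future[, v]),
               numeric(nrow(future)))
  if (is.null(dim(tp))) { tp <- matrix(tp, 1L); tf <- matrix(tf, 1L) }
  off <- sqrt(rowSums((tf - tp)^2))
  out <- data.frame(site = rownames(present) %||% seq_len(nrow(present)),
                    genomic_offset = off, stringsAsFactors = FALSE)
  attr(out, "most_important_variable") <-
    model$predictors[which.max(model$importance)]
  class(out) <- c("offset_result", "data.frame")
  out
}

#' Multi-run gradient-forest protocol
#'
#' Runs three independently seeded forests; if all three agree on the most
#' important predictor, the first run's offsets are reported. Otherwise ten
#' runs are performed, the modal top predictor reported, and genomic offsets
#' averaged across all ten runs.
#'
#' @inheritParams fit_gradient_forest
#' @param present,future sites x predictors climate matrices.
#' @param n_initial,n_full run counts for the two stages (3 and 10).
#' @param seed base seed; run r uses `seed + r`.
#' @return list: `offsets` (data.frame site/genomic_offset),
#'   `most_important_variable`, `n_runs`, `top_by_run`.
#' @export
multi_run_protocol <- function(allele_freqs, predictors, present, future,
                               n_trees = 500L, n_initial = 3L, n_full = 10L,
                               seed = 1L, ...) {
  run_once <- function(r) {
    m <- fit_gradient_forest(allele_freqs, predictors, n_trees = n_trees,
                             seed = seed + r, ...)
    list(model = m, offset = genomic_offset(m, present, future),
         top = m$predictors[which.max(m$importance)])
  }
  runs <- lapply(seq_len(n_initial), run_once)
  tops <- vapply(runs, `[[`, "", "top")
  if (length(unique(tops)) == 1L) {
    return(list(offsets = runs[[1L]]$offset,
                most_important_variable = tops[1L],
                n_runs = n_initial, top_by_run = tops))
  }
  runs <- c(runs, lapply((n_initial + 1L):n_full, run_once))
  tops <- vapply(runs, `[[`, "", "top")
  mean_off <- rowMeans(vapply(runs, function(r) r$offset$genomic_offset,
                              numeric(nrow(runs[[1L]]$offset))))
  offsets <- runs[[1L]]$offset
  offsets$genomic_offset <- mean_off
  list(offsets = offsets,
       most_important_variable = names(sort(table(tops), decreasing = TRUE))[1L],
       n_runs = n_full, top_by_run = tops)
}
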