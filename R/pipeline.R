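# End-to-end orchestration and report formatting.

#' Default pipeline configuration
#'
#' Every threshold of the analysis, with the study's standard values as
#' defaults: MAF cutoff 0.01; LD pruning 50-SNP windows, 5-SNP step,
#' r-squared 0.5; three structure PCs; top 1% association candidates; FDR
#' q < 0.05; 50 kb gene window; predictor decorrelation at |r| > 0.7;
#' loading-correlation gate at 0.05/3; 500 regression trees.
#'
#' @param ... overrides of any default entry.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    maf = 0.01,
    prune = c(window = 50L, step = 5L, r2 = 0.5),
    n_pcs = 3L,
    top_fraction = 0.01,
    fdr_alpha = 0.05,
    lfmm_k = 3L,
    gene_window = 50000L,
    cor_threshold = 0.7,
    gate_alpha = 0.05,
    n_traits = 3L,
    n_trees = 500L,
    n_boot = 200L,
    k_range = 1:5,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages on a study bundle (real or from
#' [simulate_study()]): run-timing descriptors and trends; genotype QC;
#' structure (PCA + ancestry K); per-trait association by partial RDA and
#' ridge LFMM; gene annotation of candidates; the climate loading gate; and,
#' for traits whose gate passes, gradient-forest genomic offsets plus
#' environmental offsets and diversity metrics. Any stage failure aborts
#' with the stage name.
#'
#' @param study list with `genotypes`, `counts`, `climate`, `genes` (as from
#'   [simulate_study()]).
#' @param config a [pipeline_config()].
#' @param out optional directory; when given, stage tables are written as
#'   TSV and a provenance log (seeds, thresholds, package version) as JSON.
#' @return list of stage results: `run_timing`, `trends`, `qc`, `structure`,
#'   `association` (per trait), `annotation`, `gates`, `offset` (gated
#'   traits only), `diversity`.
#' @export
run_pipeline <- function(study, config = pipeline_config(), out = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()

  res$run_timing <- stage("runtiming", {
    summ <- summarize_populations(study$counts, n_boot = config$n_boot,
                                  seed = config$seed)
    med <- yearly_medians(study$counts)
    list(summary = summ, medians = med)
  })
  res$trends <- stage("trends",
    fit_trends(res$run_timing$medians))

  res$qc <- stage("qc", {
    g <- maf_filter(study$genotypes, config$maf)
    list(genotypes = g, n_input = ncol(study$genotypes$dosages),
         n_retained = ncol(g$dosages))
  })
  g <- res$qc$genotypes

  res$structure <- stage("structure", {
    pruned <- ld_prune(g, config$prune[["window"]], config$prune[["step"]],
                       config$prune[["r2"]])
    pca <- run_pca(pruned, n_pcs = max(3L, config$n_pcs))
    kc <- choose_k(pruned, K_range = config$k_range, seed = config$seed)
    list(pruned = pruned, pca = pca, chosen_k = kc$K,
         cross_entropy = kc$cross_entropy)
  })
  cond <- res$structure$pca$scores[, seq_len(config$n_pcs), drop = FALSE]

  # population-level phenotypes assigned to each fish
  summ <- res$run_timing$summary
  idx <- match(g$pop_labels, summ$population)
  phenos <- list(
    early = summ$early_doy[idx],
    late = summ$late_doy[idx],
    modality = as.integer(summ$modality[idx] == "multiple")
  )

  res$association <- stage("gwa", lapply(phenos, function(y) {
    rda <- partial_rda(g, y, condition = cond)
    lfmm <- lfmm_ridge(g, y, K = config$lfmm_k, fdr_alpha = config$fdr_alpha)
    list(rda = rda, lfmm = lfmm,
         rda_candidates = top_fraction(rda$snp_scores, config$top_fraction))
  }))

  res$annotation <- stage("annotate", lapply(res$association, function(a) {
    snps <- g$markers[g$markers$id %in% names(a$rda_candidates), ,
                      drop = FALSE]
    if (is.null(names(a$rda_candidates)))
      snps <- g$markers[a$rda_candidates, , drop = FALSE]
    recs <- closest_genes(snps, study$genes, window = config$gene_window)
    lf_snps <- g$markers[g$markers$id %in% names(a$lfmm$q_values)[a$lfmm$candidates], , drop = FALSE]
    lf_recs <- closest_genes(lf_snps, study$genes, window = config$gene_window)
    list(rda = recs, lfmm = lf_recs,
         both = intersect_methods(recs$gene_id, lf_recs$gene_id, recs))
  }))

  res$gea <- stage("gea", gea_rda(g, study$climate, condition = cond))
  res$gates <- stage("gates", lapply(res$association, function(a)
    correlate_loadings(a$rda, res$gea, alpha = config$gate_alpha,
                       n_traits = config$n_traits)))

  gated <- names(res$gates)[vapply(res$gates, `[[`, TRUE, "passed")]
  res$offset <- stage("offset", {
    if (length(gated) == 0L) {
      message("no trait passed the climate loading gate; offset stage skipped")
      NULL
    } else {
      env_off <- environmental_offset(study$climate)
      lapply(setNames(gated, gated), function(tr) {
        cand <- res$association[[tr]]$rda_candidates
        freqs <- population_allele_freqs(g, cand)
        pres <- study$climate$present
        rownames(pres) <- study$climate$sites
        fut <- study$climate$future
        rownames(fut) <- study$climate$sites
        pre_gf <- fit_gradient_forest(freqs, pres, n_trees = config$n_trees,
                                      seed = config$seed)
        imp <- setNames(rep(0, ncol(pres)), colnames(pres))
        imp[names(pre_gf$importance)] <- pre_gf$importance
        keep_vars <- decorrelate_predictors(study$climate, imp,
                                            threshold = config$cor_threshold)
        gf <- fit_gradient_forest(freqs, pres[, keep_vars, drop = FALSE],
                                  n_trees = config$n_trees,
                                  seed = config$seed)
        go <- genomic_offset(gf, pres, fut)
        list(model = gf, genomic = go, environmental = env_off,
             predictors = keep_vars)
      })
    }
  })

  res$diversity <- stage("diversity", diversity_metrics(g))

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write.table(res$run_timing$summary, file.path(out, "run_timing.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$trends$slopes, file.path(out, "trend_slopes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (tr in names(res$association)) {
      a <- res$association[[tr]]
      tab <- data.frame(snp = names(a$rda$snp_scores),
                        rda_score = unname(a$rda$snp_scores),
                        lfmm_z = unname(a$lfmm$z_scores),
                        lfmm_p = unname(a$lfmm$p_values),
                        lfmm_q = unname(a$lfmm$q_values))
      tab$rda_candidate <- seq_len(nrow(tab)) %in% a$rda_candidates
      tab$lfmm_candidate <- seq_len(nrow(tab)) %in% a$lfmm$candidates
      write.table(tab, file.path(out, paste0("association_", tr, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$offset)) {
      for (tr in names(res$offset))
        write.table(res$offset[[tr]]$genomic,
                    file.path(out, paste0("offset_", tr, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    prov <- list(package_version = as.character(utils::packageVersion("salmonrun")),
                 config = unclass(config), timestamp = format(Sys.time()))
    jsonlite::write_json(prov, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Format a count ratio as a percentage string
#'
#' One decimal place, rounding half away from zero -- the convention used
#' when reporting candidate-locus overlaps (741 of 1413 prints as
#' `"52.4%"`).
#'
#' @param numerator,denominator counts; the denominator must be positive.
#' @return character scalar like `"52.4%"`.
#' @export
format_percent <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  pct <- 100 * numerator / denominator
  rounded <- sign(pct) * floor(abs(pct) * 10 + 0.5) / 10
  sprintf("%.1f%%", rounded)
}
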