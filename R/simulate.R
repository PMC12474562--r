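# Synthetic study generator: hierarchically structured genotypes, a
# latitude-graded climate, and seasonal daily-count curves, with ground-truth
# records for recovery tests.

#' Simulation configuration
#'
#' Describes a desk-scale study: populations nested in regional clusters, a
#' two-level island (F) model for genotypes, latitude-graded climate, and
#' multi-year daily count series. Defaults emulate a survey of 11 North
#' American Atlantic salmon rivers in three regional groups (Maritimes,
#' Newfoundland, Labrador) with roughly 27 genotyped individuals per river
#' and a 28-year count record.
#'
#' @param n_pops number of populations.
#' @param pops_per_region integer vector partitioning populations into
#'   regions; must sum to `n_pops`.
#' @param n_ind_per_pop individuals sampled per population.
#' @param n_snps number of biallelic SNPs.
#' @param fst_between_regions drift variance parameter between regions,
#'   in (0, 1).
#' @param fst_within_region drift variance parameter of populations around
#'   their region, in (0, 1); must not exceed `fst_between_regions`.
#' @param n_trait_loci planted trait loci per phenotype (early, late,
#'   modality); sets are disjoint.
#' @param effect_size allele-frequency cline slope on the logit scale per
#'   unit of standardized climate.
#' @param latitudes degrees north, one per population (defines the climate
#'   gradient and run-timing geography).
#' @param modality_labels `"single"` or `"multiple"` per population; default
#'   marks the first region (Maritimes-like) as multiple-peaked.
#' @param n_years years of daily counts.
#' @param fish_per_year expected returning adults counted per population-year.
#' @param missing_rate fraction of dosages set missing at random.
#' @param seed integer seed; every generator is fully reproducible from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_pops = 11L,
                       pops_per_region = c(4L, 5L, 2L),
                       n_ind_per_pop = 27L,
                       n_snps = 5000L,
                       fst_between_regions = 0.015,
                       fst_within_region = 0.005,
                       n_trait_loci = 50L,
                       effect_size = 1.0,
                       latitudes = c(46.12, 46.88, 46.94, 47.57,
                                     47.29, 47.92, 48.55, 49.27, 51.19,
                                     53.56, 54.97),
                       modality_labels = NULL,
                       n_years = 28L,
                       fish_per_year = 300,
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(n_pops >= 1, n_ind_per_pop >= 1, n_snps >= 1, n_trait_loci >= 1,
            n_years >= 1, fish_per_year > 0,
            missing_rate >= 0, missing_rate < 1)
  if (sum(pops_per_region) != n_pops)
    stop("pops_per_region must sum to n_pops")
  if (length(latitudes) != n_pops)
    stop("latitudes must have one entry per population")
  if (!(fst_within_region > 0 && fst_within_region <= fst_between_regions &&
        fst_between_regions < 1))
    stop("need 0 < fst_within_region <= fst_between_regions < 1")
  if (3L * n_trait_loci >= n_snps)
    stop("too many trait loci for n_snps (three disjoint sets required)")
  region <- rep(seq_along(pops_per_region), times = pops_per_region)
  if (is.null(modality_labels))
    modality_labels <- ifelse(region == 1L, "multiple", "single")
  stopifnot(all(modality_labels %in% c("single", "multiple")),
            length(modality_labels) == n_pops)
  structure(list(
    n_pops = as.integer(n_pops),
    pops_per_region = as.integer(pops_per_region),
    region = as.integer(region),
    n_ind_per_pop = as.integer(n_ind_per_pop),
    n_snps = as.integer(n_snps),
    fst_between_regions = fst_between_regions,
    fst_within_region = fst_within_region,
    n_trait_loci = as.integer(n_trait_loci),
    effect_size = effect_size,
    latitudes = latitudes,
    modality_labels = modality_labels,
    n_years = as.integer(n_years),
    fish_per_year = fish_per_year,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Beta draw with mean p and variance f * p * (1 - p)  (Balding-Nichols)
.bn_draw <- function(p, f) {
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  rbeta(length(p), a, b)
}

#' Simulate genotypes under a two-level hierarchical F-model
#'
#' Ancestral allele frequencies are uniform on (0.05, 0.95); regional
#' frequencies drift around them with variance
#' `fst_between_regions * p * (1 - p)` (Balding-Nichols beta draws), and
#' population frequencies drift around their region with variance
#' `fst_within_region * p * (1 - p)`. Genotypes are binomial(2, p_pop).
#' Three disjoint sets of trait loci (early, late, modality) additionally
#' receive a deterministic cline: their population frequencies are shifted on
#' the logit scale by `effect_size` times the standardized driver of the
#' phenotype (standardized latitude for early/late, the standardized
#' single/multiple indicator for modality). Frequencies pushed outside
#' (0, 1) are clamped to [0.01, 0.99] with a warning.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth` (class
#'   `sim_truth`: per-phenotype trait-locus indices, the number of ancestral
#'   clusters, planted logit slopes, modality labels, and the per-population
#'   allele-frequency matrix actually used).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  M <- cfg$n_snps
  n_reg <- length(cfg$pops_per_region)
  p_anc <- runif(M, 0.05, 0.95)
  p_reg <- matrix(0, n_reg, M)
  for (r in seq_len(n_reg))
    p_reg[r, ] <- .bn_draw(p_anc, cfg$fst_between_regions)
  p_pop <- matrix(0, cfg$n_pops, M)
  for (k in seq_len(cfg$n_pops))
    p_pop[k, ] <- .bn_draw(p_reg[cfg$region[k], ], cfg$fst_within_region)

  # disjoint planted trait loci, one set per phenotype
  idx_all <- sample.int(M, 3L * cfg$n_trait_loci)
  trait_loci <- list(
    early    = sort(idx_all[seq_len(cfg$n_trait_loci)]),
    late     = sort(idx_all[cfg$n_trait_loci + seq_len(cfg$n_trait_loci)]),
    modality = sort(idx_all[2L * cfg$n_trait_loci + seq_len(cfg$n_trait_loci)])
  )
  z_lat <- as.numeric(scale(cfg$latitudes))
  z_mod <- as.numeric(scale(as.integer(cfg$modality_labels == "multiple")))
  if (anyNA(z_mod)) z_mod <- rep(0, cfg$n_pops)  # all labels identical
  drivers <- list(early = z_lat, late = z_lat, modality = z_mod)
  planted_slopes <- numeric(0)
  for (ph in names(trait_loci)) {
    loci <- trait_loci[[ph]]
    shift <- outer(drivers[[ph]], rep(cfg$effect_size, length(loci)))
    p_pop[, loci] <- inv_logit(logit(p_pop[, loci]) + shift)
    planted_slopes <- c(planted_slopes,
                        setNames(rep(cfg$effect_size, length(loci)),
                                 paste0("snp", loci)))
  }
  out_of_range <- p_pop < 0.01 | p_pop > 0.99
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " population frequencies clamped to [0.01, 0.99]")
    p_pop <- pmin(pmax(p_pop, 0.01), 0.99)
  }

  n <- cfg$n_pops * cfg$n_ind_per_pop
  dos <- matrix(0L, n, M)
  pop_labels <- rep(paste0("pop", seq_len(cfg$n_pops)), each = cfg$n_ind_per_pop)
  for (k in seq_len(cfg$n_pops)) {
    rows <- which(pop_labels == paste0("pop", k))
    dos[rows, ] <- matrix(rbinom(length(rows) * M, 2L,
                                 rep(p_pop[k, ], each = length(rows))),
                          length(rows), M)
  }
  if (cfg$missing_rate > 0) {
    miss <- runif(length(dos)) < cfg$missing_rate
    dos[miss] <- NA_integer_
  }
  # markers spread over 29 chromosomes, positions increasing
  chrom <- sprintf("Ssa%02d", ((seq_len(M) - 1L) %% 29L) + 1L)
  pos <- 1000L * (((seq_len(M) - 1L) %/% 29L) + 1L) + ((seq_len(M) - 1L) %% 29L)
  markers <- data.frame(
    id = paste0("snp", seq_len(M)), chrom = chrom, pos = pos,
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  ord <- order(markers$chrom, markers$pos)
  g <- genotype_matrix(dos[, ord, drop = FALSE], markers[ord, , drop = FALSE],
                       individuals = paste0("ind", seq_len(n)),
                       pop_labels = pop_labels)
  # remap trait locus indices to the sorted marker order
  remap <- match(paste0("snp", seq_len(M)), g$markers$id)
  truth <- structure(list(
    trait_loci = lapply(trait_loci, function(i) sort(remap[i])),
    ancestral_k = length(cfg$pops_per_region),
    planted_slopes = planted_slopes,
    modality_labels = setNames(cfg$modality_labels,
                               paste0("pop", seq_len(cfg$n_pops))),
    p_pop = p_pop[, ord, drop = FALSE],
    region = cfg$region
  ), class = "sim_truth")
  list(genotypes = g, truth = truth)
}

#' Simulate present and future bioclim-style climate tables
#'
#' Builds 19 variables (BIO1-BIO19) per population. A subset is a linear
#' function of standardized latitude plus Gaussian noise (temperature-like
#' variables with alternating sign, plus two precipitation-like ones); the
#' rest are pure noise. Two constructed near-duplicate pairs exceed |r| 0.7
#' to exercise predictor decorrelation. The future table displaces the
#' latitude-linked temperature variables by `displacement` times the
#' population's scaled latitude rank, so northern sites move furthest --
#' the pattern of greater projected change at high latitude.
#'
#' @param cfg a [sim_config()].
#' @param displacement size of the future shift (standardized units) at the
#'   northernmost site; 0 gives future identical to present.
#' @param noise_sd residual noise around the latitude trend.
#' @return object of class `climate_table`: `sites`, `present` and `future`
#'   (sites x 19 matrices), `latitudes`, and `lat_linked` (names of the
#'   variables tied to latitude).
#' @export
simulate_climate <- function(cfg, displacement = 1.5, noise_sd = 0.3) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 104729L)  # independent stream from the genotype draw
  z <- as.numeric(scale(cfg$latitudes))
  n <- cfg$n_pops
  vars <- paste0("BIO", 1:19)
  pres <- matrix(rnorm(n * 19, sd = 1), n, 19, dimnames = list(NULL, vars))
  lat_linked <- c("BIO1", "BIO4", "BIO7", "BIO10", "BIO11", "BIO12", "BIO16")
  sign_of <- setNames(c(-1, 1, 1, -1, -1, 1, 1), lat_linked)
  for (v in lat_linked)
    pres[, v] <- sign_of[[v]] * z + rnorm(n, sd = noise_sd)
  # constructed highly correlated pairs (target |r| > 0.7)
  pres[, "BIO6"] <- 0.97 * pres[, "BIO5"] + rnorm(n, sd = 0.1)
  pres[, "BIO15"] <- 0.95 * pres[, "BIO14"] + rnorm(n, sd = 0.12)
  fut <- pres
  if (displacement != 0) {
    lat01 <- (cfg$latitudes - min(cfg$latitudes)) /
      max(1e-12, diff(range(cfg$latitudes)))
    shift_vars <- c("BIO1", "BIO10", "BIO11")
    for (v in shift_vars) fut[, v] <- pres[, v] + displacement * lat01
  }
  structure(list(
    sites = paste0("pop", seq_len(n)),
    present = pres,
    future = fut,
    latitudes = cfg$latitudes,
    lat_linked = lat_linked
  ), class = "climate_table")
}

#' Simulate daily count series
#'
#' Per population and year, expected counts follow one Gaussian bump over day
#' of year (modality `"single"`) or a two-component mixture (`"multiple"`),
#' with the annual total set by `fish_per_year` and daily counts drawn
#' Poisson. The bump centre follows latitude (later runs further north),
#' jitters between years, and can advance linearly across years to plant
#' recoverable trends. Counts are split between small and large size classes.
#'
#' @param cfg a [sim_config()].
#' @param modality_labels optional per-population `"single"`/`"multiple"`
#'   overrides; defaults to `cfg$modality_labels`.
#' @param trend_slopes days/year advance of the bump centre per population
#'   (negative = earlier over time); default all 0.
#' @param year_jitter_sd between-year jitter of the bump centre (days).
#' @param run_sd within-season spread of a single bump (days).
#' @return data.frame with columns population, year, doy, size_class, count
#'   (long form; only days with at least one expected fish appear).
#' @export
simulate_counts <- function(cfg, modality_labels = NULL, trend_slopes = NULL,
                            year_jitter_sd = 3, run_sd = 12) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 224737L)
  modality_labels <- modality_labels %||% cfg$modality_labels
  trend_slopes <- trend_slopes %||% rep(0, cfg$n_pops)
  stopifnot(length(modality_labels) == cfg$n_pops,
            length(trend_slopes) == cfg$n_pops)
  base_doy <- 150 + 3.5 * (cfg$latitudes - min(cfg$latitudes))
  years <- 1994L + seq_len(cfg$n_years) - 1L
  doy_grid <- 1:366
  out <- vector("list", cfg$n_pops * cfg$n_years)
  i <- 0L
  for (k in seq_len(cfg$n_pops)) {
    for (yi in seq_along(years)) {
      centre <- base_doy[k] + trend_slopes[k] * (yi - 1L) +
        rnorm(1, sd = year_jitter_sd)
      if (modality_labels[k] == "multiple") {
        dens <- 0.55 * dnorm(doy_grid, centre - 22, run_sd * 0.7) +
                0.45 * dnorm(doy_grid, centre + 33, run_sd * 0.8)
      } else {
        dens <- dnorm(doy_grid, centre, run_sd)
      }
      lam <- cfg$fish_per_year * dens / sum(dens)
      cnt <- rpois(length(doy_grid), lam)
      keep <- cnt > 0
      if (!any(keep)) next
      n_small <- rbinom(sum(keep), cnt[keep], 0.6)
      i <- i + 1L
      out[[i]] <- data.frame(
        population = paste0("pop", k),
        year = years[yi],
        doy = rep(doy_grid[keep], 2L),
        size_class = rep(c("small", "large"), each = sum(keep)),
        count = c(n_small, cnt[keep] - n_small),
        stringsAsFactors = FALSE
      )
    }
  }
  counts <- do.call(rbind, out[seq_len(i)])
  counts[counts$count > 0, , drop = FALSE]
}

#' Simulate a complete desk-scale study
#'
#' Convenience wrapper: genotypes + truth, climate, daily counts, and simple
#' gene annotation intervals covering a fraction of the SNPs.
#'
#' @param cfg a [sim_config()].
#' @param displacement passed to [simulate_climate()].
#' @param trend_slopes passed to [simulate_counts()].
#' @return list with `genotypes`, `truth`, `climate`, `counts`, `genes`
#'   (data.frame gene_id/chrom/start/end/strand).
#' @export
simulate_study <- function(cfg, displacement = 1.5, trend_slopes = NULL) {
  gsim <- simulate_genotypes(cfg)
  clim <- simulate_climate(cfg, displacement = displacement)
  counts <- simulate_counts(cfg, trend_slopes = trend_slopes)
  set.seed(cfg$seed + 350377L)
  mk <- gsim$genotypes$markers
  # one gene straddling every third marker, 2 kb wide
  pick <- seq(1L, nrow(mk), by = 3L)
  genes <- data.frame(
    gene_id = paste0("gene", seq_along(pick)),
    chrom = mk$chrom[pick],
    start = pmax(1L, mk$pos[pick] - 1000L),
    end = mk$pos[pick] + 1000L,
    strand = sample(c("+", "-"), length(pick), replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(genotypes = gsim$genotypes, truth = gsim$truth, climate = clim,
       counts = counts, genes = genes)
}
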