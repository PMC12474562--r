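# Run-timing descriptors, trends, and modality from daily count data.
#
# Counts are long-form: population, year, doy, size_class, count. Small and
# large size classes are always pooled before computing descriptors.

.check_counts <- function(counts) {
  need <- c("population", "year", "doy", "count")
  if (!all(need %in% names(counts)))
    stop("counts need columns: ", paste(need, collapse = ", "))
  if (any(counts$count < 0)) stop("counts must be non-negative")
  if (any(counts$doy < 1 | counts$doy > 366)) stop("doy must be in 1..366")
  invisible(counts)
}

# sum counts per DOY (pooling years and size classes)
.pool_doy <- function(counts) {
  tot <- tapply(counts$count, counts$doy, sum)
  data.frame(doy = as.integer(names(tot)), count = as.numeric(tot))
}

#' Percentile day of a pooled count distribution
#'
#' Pools counts per day of year across all years and size classes, forms the
#' cumulative fraction, and returns the smallest DOY at which it reaches
#' `q`. No interpolation: counts are integers per day.
#'
#' @param counts daily counts for one population (columns population, year,
#'   doy, size_class, count).
#' @param q fraction in (0, 1).
#' @return integer DOY.
#' @export
percentile_day <- function(counts, q) {
  stopifnot(q > 0, q < 1)
  .check_counts(counts)
  pooled <- .pool_doy(counts)
  pooled <- pooled[order(pooled$doy), ]
  total <- sum(pooled$count)
  if (total == 0) stop("total count is zero; percentile undefined")
  cf <- cumsum(pooled$count) / total
  pooled$doy[which(cf >= q)[1L]]
}

#' Median run day for one population-year
#'
#' The day of year by which half of the counted fish had entered the river:
#' [percentile_day()] with `q = 0.5` on a single year's counts.
#'
#' @param counts daily counts for one population-year.
#' @return integer DOY.
#' @export
run_year_median <- function(counts) {
  if (length(unique(counts$year)) > 1L)
    stop("run_year_median expects a single year of counts")
  percentile_day(counts, 0.5)
}

#' Annual median run days for all populations
#'
#' @param counts long-form daily counts for any number of populations/years.
#' @return data.frame population, year, median_doy; (population, year) cells
#'   with zero total count are dropped with a warning.
#' @export
yearly_medians <- function(counts) {
  .check_counts(counts)
  tot <- aggregate(count ~ population + year, counts, sum)
  empty <- tot[tot$count == 0, , drop = FALSE]
  if (nrow(empty) > 0)
    warning("dropping ", nrow(empty), " population-year(s) with zero counts")
  keep <- tot[tot$count > 0, c("population", "year")]
  med <- mapply(function(p, y) {
    run_year_median(counts[counts$population == p & counts$year == y, ,
                           drop = FALSE])
  }, keep$population, keep$year)
  data.frame(population = keep$population, year = keep$year,
             median_doy = as.integer(med), row.names = NULL)
}

#' Population run-timing summary
#'
#' Early (5th percentile) and late (95th percentile) run timing from counts
#' pooled across years, with standard errors from a nonparametric bootstrap
#' over years, plus algorithmic modality classification.
#'
#' @param counts daily counts for one population.
#' @param n_boot bootstrap resamples over years for the SEs (`NA` SEs when
#'   only one year contributes).
#' @param seed seed for the bootstrap.
#' @param q_early,q_late percentile fractions (defaults 0.05 and 0.95).
#' @return one-row data.frame: population, early_doy, median_doy, late_doy,
#'   se_early, se_late, modality, n_years.
#' @export
summarize_population <- function(counts, n_boot = 1000L, seed = 1L,
                                 q_early = 0.05, q_late = 0.95) {
  .check_counts(counts)
  pop <- unique(counts$population)
  if (length(pop) != 1L) stop("summarize_population expects one population")
  tot_by_year <- tapply(counts$count, counts$year, sum)
  if (all(tot_by_year == 0)) stop("no non-zero counts for ", pop)
  if (any(tot_by_year == 0))
    warning("dropping ", sum(tot_by_year == 0),
            " year(s) with zero counts for ", pop)
  years <- as.integer(names(tot_by_year)[tot_by_year > 0])
  counts <- counts[counts$year %in% years, , drop = FALSE]
  early <- percentile_day(counts, q_early)
  medd <- percentile_day(counts, 0.5)
  late <- percentile_day(counts, q_late)
  se_early <- se_late <- NA_real_
  if (length(years) > 1L && n_boot > 0L) {
    set.seed(seed)
    by_year <- split(counts, counts$year)
    bs <- vapply(seq_len(n_boot), function(b) {
      res <- do.call(rbind, by_year[sample(length(by_year), replace = TRUE)])
      c(percentile_day(res, q_early), percentile_day(res, q_late))
    }, numeric(2))
    se_early <- sd(bs[1L, ])
    se_late <- sd(bs[2L, ])
  }
  data.frame(population = pop, early_doy = early, median_doy = medd,
             late_doy = late, se_early = se_early, se_late = se_late,
             modality = classify_modality(counts), n_years = length(years),
             stringsAsFactors = FALSE)
}

#' Summaries for every population in a count table
#' @inheritParams summarize_population
#' @param counts long-form daily counts (any number of populations).
#' @return data.frame with one row per population.
#' @export
summarize_populations <- function(counts, n_boot = 1000L, seed = 1L) {
  out <- lapply(split(counts, counts$population), summarize_population,
                n_boot = n_boot, seed = seed)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multi-year run-timing trends
#'
#' Ordinary least squares of annual median run day on Year, Site, and their
#' interaction; the Year-by-Site interaction is tested with a Type II ANOVA
#' (\pkg{car}). Per-population slopes (days/year) and their tests come from
#' \pkg{emmeans} trend contrasts on the fitted model, and slopes are
#' correlated with latitude (Pearson).
#'
#' @param medians data.frame population, year, median_doy (see
#'   [yearly_medians()]).
#' @param latitudes named vector of latitudes (names = populations), or
#'   unnamed in the order of `sort(unique(population))`.
#' @return list of class `trend_fit`: `model`, `interaction_F`,
#'   `interaction_p`, `slopes` (data.frame population, slope, se, p),
#'   `latitude_correlation`.
#' @export
fit_trends <- function(medians, latitudes = NULL) {
  stopifnot(all(c("population", "year", "median_doy") %in% names(medians)))
  pops <- sort(unique(medians$population))
  if (length(pops) < 2L) stop("need at least two populations")
  per_pop_years <- tapply(medians$year, medians$population,
                          function(y) length(unique(y)))
  if (any(per_pop_years < 3L)) stop("need at least three years per population")
  medians$population <- factor(medians$population, levels = pops)
  medians$year_c <- medians$year - mean(medians$year)
  fit <- lm(median_doy ~ year_c * population, data = medians)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient trend design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  an <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  if (is.null(an)) {
    # perfect fit (zero residual SS): compare against the additive model
    # directly; zero interaction SS then means no interaction evidence
    ss_int <- sum(residuals(lm(median_doy ~ year_c + population,
                               data = medians))^2) -
      sum(residuals(fit)^2)
    an <- data.frame("F value" = if (ss_int < 1e-10) 0 else Inf,
                     "Pr(>F)" = if (ss_int < 1e-10) 1 else 0,
                     row.names = "year_c:population", check.names = FALSE)
  }
  irow <- grep("year_c:population", rownames(an))
  tr <- emmeans::emtrends(fit, "population", var = "year_c")
  tt <- as.data.frame(emmeans::test(tr))
  slopes <- data.frame(population = as.character(tt$population),
                       slope = tt$year_c.trend, se = tt$SE,
                       p = tt$p.value, stringsAsFactors = FALSE)
  lat_cor <- NA_real_
  if (!is.null(latitudes)) {
    if (is.null(names(latitudes))) names(latitudes) <- pops
    lat_cor <- cor(slopes$slope, latitudes[slopes$population])
  }
  structure(list(model = fit,
                 interaction_F = an[irow, "F value"],
                 interaction_p = an[irow, "Pr(>F)"],
                 slopes = slopes,
                 latitude_correlation = lat_cor),
            class = "trend_fit")
}

# topographic prominence of local maxima in a regularly gridded series
.peak_prominence <- function(y) {
  n <- length(y)
  is_peak <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1L) y[i - 1L] else -Inf
    right <- if (i < n) y[i + 1L] else -Inf
    y[i] > left && y[i] >= right
  }, logical(1)))
  prom <- vapply(is_peak, function(i) {
    h <- y[i]
    # walk out each side until terrain exceeds h; prominence uses the higher
    # of the two valley minima (or series edge minima for border peaks)
    left_min <- if (i == 1L) h else {
      j <- max(c(0L, which(y[seq_len(i - 1L)] > h)))
      min(y[(j + 1L):i])
    }
    right_min <- if (i == n) h else {
      ahead <- y[(i + 1L):n]
      j <- which(ahead > h)
      upto <- if (length(j)) j[1L] else length(ahead)
      min(ahead[seq_len(upto)])
    }
    h - max(left_min, right_min)
  }, numeric(1))
  data.frame(index = is_peak, height = y[is_peak], prominence = prom)
}

#' Classify run-timing modality
#'
#' Pools counts to the mean daily count per DOY, smooths with a Gaussian
#' kernel, and finds local maxima whose topographic prominence is at least
#' `min_prominence` of the global maximum. Two or more qualifying peaks give
#' `"multiple"`, otherwise `"single"`.
#'
#' @param counts daily counts for one population.
#' @param bandwidth Gaussian kernel bandwidth in days.
#' @param min_prominence prominence threshold as a fraction of the global
#'   maximum of the smoothed curve.
#' @return `"single"` or `"multiple"`.
#' @export
classify_modality <- function(counts, bandwidth = 7, min_prominence = 0.2) {
  .check_counts(counts)
  n_years <- length(unique(counts$year))
  pooled <- .pool_doy(counts)
  if (nrow(pooled) == 0L || sum(pooled$count) == 0)
    stop("empty count series")
  grid <- seq(min(pooled$doy), max(pooled$doy))
  y <- numeric(length(grid))
  y[match(pooled$doy, grid)] <- pooled$count / n_years
  k <- dnorm(seq(-4 * bandwidth, 4 * bandwidth), sd = bandwidth)
  sm <- as.numeric(stats::filter(c(rep(0, length(k) %/% 2), y,
                                   rep(0, length(k) %/% 2)),
                                 k / sum(k), sides = 2))
  sm <- sm[!is.na(sm)]
  pk <- .peak_prominence(sm)
  qualifying <- sum(pk$prominence >= min_prominence * max(sm))
  if (qualifying >= 2L) "multiple" else "single"
}
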