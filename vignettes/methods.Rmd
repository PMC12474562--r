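---
title: "Methods: run-timing phenology, structure-aware association, and genomic offset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: run-timing phenology, structure-aware association, and genomic offset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`salmonrun` analyses the seasonal return migration of river-spawning salmon
at the population level: descriptive phenology from daily count series,
genome-wide association of phenology with SNP genotypes under population
structure, and the projection of candidate loci onto future climate through
gradient-forest turnover functions. This vignette records the models, their
assumptions, the tunable parameters, and the design choices made where more
than one defensible construction existed.

## Run-timing descriptors

Counts arrive long-form as (population, year, day-of-year, size-class,
count). Small and large size classes are always pooled, and a population's
*early*, *median*, and *late* run timing are the smallest days of year at
which the cumulative fraction of pooled counts reaches 0.05, 0.50, and 0.95.
No interpolation is applied: counts are integers attached to whole days, and
the published tables this convention mirrors report integer days. Percentile
days are therefore integers, monotone in the quantile, and invariant to how
counts are split across size classes.

Standard errors for the early and late descriptors come from a seeded
nonparametric bootstrap over years (default 1,000 resamples): years are the
natural exchangeable unit, and an analytic SE for a percentile of a pooled
multinomial would require assumptions about between-year dependence we
cannot check. With a single contributing year the SE is reported as `NA`
rather than a degenerate zero. Years with zero total count are dropped with
a warning before any descriptor is computed.

Multi-year trends are ordinary least squares of annual median day on
Year, Site, and Year × Site, with the interaction tested by Type II
sums-of-squares ANOVA (`car::Anova`) — Type II because the interaction is
the term of scientific interest and the design is unbalanced whenever
populations differ in observed years. Per-population slopes and their tests
come from `emmeans` trend contrasts on the same fit, so the reported slopes
are exactly the model's, not side regressions.

Modality — one versus multiple within-season peaks — is classified
algorithmically: the mean daily count series is smoothed with a Gaussian
kernel (bandwidth 7 days) and local maxima are kept when their topographic
prominence reaches 20% of the global maximum; two or more such peaks give
"multiple". The bandwidth spans roughly one week of stochastic day-to-day
variation without merging peaks a month apart; both thresholds are exposed
as arguments since visual classification, which this replaces, has no
single canonical parameterisation.

## Genotypes, diversity, and structure

Dosages live in \{0, 1, 2, NA\}. The MAF filter uses an inclusive boundary
(retain MAF ≥ cutoff, default 0.01), matching PLINK `--maf` semantics. LD
pruning is greedy within 50-SNP windows sliding by 5 with an r² threshold of
0.5; because the reference implementation's internal victim choice is not
documented, ours is stated: the member of the worst pair with the lower MAF
is removed, ties broken by removing the larger position. Missing dosages are
mean-imputed only inside PCA/RDA/LFMM computations; the stored matrix keeps
its missingness.

Weir–Cockerham θ is computed per SNP from the a/b/c variance components for
diploid data, with the multi-locus average `sum(a)/sum(a+b+c)` over SNPs
polymorphic in the pooled sample; per-SNP estimates may be slightly negative
by construction. Nucleotide diversity uses the small-sample correction
`2p(1−p)·n/(n−1)` with `n` the count of observed individuals, and cells with
fewer than two observed individuals are excluded.

PCA centres and scales each SNP (zero-variance SNPs dropped) and takes the
SVD; each axis is oriented so its first nonzero loading is positive, making
signs reproducible. Ancestry is a constrained nonnegative matrix
factorization of the individual × SNP frequency matrix: admixture rows on
the probability simplex, ancestral frequencies in [0, 1], fitted by
alternating projected-gradient descent with backtracking, which guarantees a
non-increasing objective. K is selected by masked prediction: a random 10%
of entries is held out, each K is scored by the binomial cross-entropy of
the held-out dosages against predicted frequencies, and the elbow is the
smallest K whose improvement over the next K falls below 2% relative
cross-entropy. The 2% tolerance is deliberately coarse — it finds the elbow
of a steep decline and refuses to chase marginal gains, consistent with how
cross-entropy curves are read in practice.

## Association scans

Population-level phenotypes (*early*, *late* as population mean days
assigned to every fish; *modality* as a 0/1 factor) are regressed against
all SNPs two ways.

**Partial RDA.** Genotypes and phenotype are residualized on the first
three structure PCs, the residual genotypes are regressed on the residual
phenotype, and the SVD of the fitted values yields the constrained axis;
per-SNP scores are the unit-norm axis-1 loadings. With one predictor there
is exactly one constrained axis, and without conditioning the scores are
proportional to per-SNP covariances with the phenotype — the identity the
test suite checks against an independent oracle and against `vegan::rda`.
Genotypes are scaled inside the RDA, consistent with the PCA; a flag exposes
the unscaled variant since either convention is seen in practice.
Significance uses residualized-response permutation: the residual phenotype
rows are permuted, the constrained variance recomputed, and
`p = (1 + #{perm ≥ obs}) / (1 + nperm)`.

Candidates are the top 1% by absolute score with the ceiling count rule —
`ceiling(0.01 × 141,263) = 1,413`, reproducing the published candidate count
for that panel size — with ties broken toward lower marker index so
selection is deterministic.

**Ridge LFMM.** K = 3 latent factors (matching the ancestry analysis) are
estimated by truncated SVD of the genotype matrix projected off the
(ridge-damped) predictor direction, so structure collinear with the
predictor cannot absorb the fixed effects; per-SNP effects are then ridge
regressions (λ = 1e-5) against the latent-adjusted matrix. z-scores are
calibrated by the genomic inflation factor `median(z²)/0.4549` (the median
of χ²₁) before Benjamini–Hochberg correction, and candidates are q < 0.05.
The projection-based factor estimate is the key numerical choice: iterating
factors and effects to a joint optimum lets rank-K structure swallow the
predictor-aligned signal entirely when the phenotype is constant within
populations, which is exactly the regime here.

Gene-level support intersects the two methods: candidate SNPs are annotated
to genes within 50 kb (inclusive boundary, strand ignored — upstream and
downstream are symmetric), genes are deduplicated per candidate set, and
genes hit by both methods flag the RDA candidates inside them. Coordinates
are 1-based inclusive internally; BED input is converted on read.

## Climate, turnover, and offsets

The 19 bioclim-style variables are standardized to present-day means and
SDs; future rows are standardized with the same parameters and projected
onto the present-day principal axes, so present and future scores share one
space. Genotype–environment association reuses the pRDA machinery with
climate PC1–3 as predictors. A trait's offset analysis is gated on the
correlation between its axis-1 loadings and the climate axis-1 loadings
over shared loci — Pearson when both vectors pass Shapiro–Wilk normality at
0.05, Spearman otherwise — at the Bonferroni threshold 0.05/3 ≈ 0.0167 for
the three phenotypes tested.

Predictors correlated above |r| = 0.7 are removed iteratively, dropping the
lower-importance member of the worst pair; importance for this first pass
comes from a preliminary gradient forest on all 19 variables, since the
reduced model does not yet exist.

Gradient forests fit, per candidate locus, 500 regression trees of
population allele frequency on the retained climate predictors (bootstrap
rows; `mtry = ceiling(p/3)`; minimum leaf 2 — the small-n regime of 11
population-level frequencies). Out-of-bag R² decides retention (R² > 0);
each retained locus contributes its split impurity reductions, normalized
within locus and weighted by its R², at the predictor values where splits
occurred. Per-predictor cumulative sums of these contributions, normalized
to total 1 across predictors, are the turnover functions: piecewise
constant, right-continuous, non-decreasing, with total rise equal to the
predictor's importance share. Density standardization of split importances
is off by default (a flag is reserved for it); with 11 sites the split-value
histogram is too sparse for a kernel correction to be meaningful.
Zero-importance predictors are removed and forests rebuilt once.

The genomic offset of a site is the Euclidean distance between its present
and future climate vectors after transformation through the turnover
functions; future values beyond the training range are clamped at the
function endpoints with a warning, since extrapolating a split-based
function into novel climates has no support. By construction the offset is
zero when climate does not move, symmetric, and a metric in turnover space.
Stability follows the three-then-ten protocol: three independently seeded
forests; if their top predictors agree, the first run is reported, otherwise
ten runs are averaged and the modal top predictor reported. The
environmental offset is the present-to-future Euclidean distance in climate
PC1–2, with no genetics involved.

Cross-validated R² distributions (candidate versus background loci) are
compared with a two-sided Wilcoxon rank-sum test, enumerated exactly when
both groups have ≤ 10 untied values and tie-corrected normal otherwise.

## The synthetic study

The generator emulates the statistical structure the analysis assumes, not
any particular dataset: 11 populations in three regional clusters (4 + 5 + 2,
a Maritimes/Newfoundland/Labrador-like geography spanning latitudes 46–55°N),
27 individuals per population (297 total), 5,000 biallelic SNPs, and a
28-year count record of ~300 fish per population-year.

Genotypes follow a two-level Balding–Nichols F-model: ancestral frequencies
uniform on (0.05, 0.95), regional frequencies beta-drifted with variance
`F_region · p(1−p)`, population frequencies beta-drifted around their region
with variance `F_pop · p(1−p)`, genotypes binomial. Three disjoint sets of
50 trait loci receive deterministic clines on the logit scale — planting on
the logit keeps frequencies in (0, 1), with clamping to [0.01, 0.99] and a
warning for the rare draw pushed outside — with slope 1.0 per unit of
standardized driver: standardized latitude for the early and late sets
(latitude is the climate gradient), the standardized single/multiple
indicator for the modality set. Because geography makes the three drivers
mutually correlated, recovery tests define their truth sets accordingly:
power counts recovery of loci clined on the tested driver, and only loci
with no planted cline at all count as false positives.

The drift defaults are `F_region = 0.015` and `F_pop = 0.005`. These are
calibrated jointly against the properties the generator must exhibit at
once: regional structure clearly detectable by PCA and by masked
cross-entropy, and planted clines of slope 1.0 recoverable over drift by a
structure-aware scan at n = 297. Stronger drift makes region-aligned allele
frequency noise statistically indistinguishable from a region-aligned cline
at 11 populations — no estimator can separate them — so the generator pins
the weak-drift, strong-cline regime that the association machinery is meant
to be validated in. Pairwise differentiation of this order is at the low
end of what anadromous fish surveys report; the generator is a validation
instrument, not a demographic reconstruction.

Climate tables tie a subset of variables (five temperature-like, two
precipitation-like) linearly to standardized latitude with noise SD 0.3,
leave the rest as noise, and plant two near-duplicate pairs (|r| > 0.7) to
exercise decorrelation. The future table displaces three temperature
variables by 1.5 standardized units times scaled latitude, so northern
sites move furthest — the high-latitude displacement pattern projected for
the Northwest Atlantic. Count curves are Poisson draws around one Gaussian
bump (SD 12 days) or a 55/45 two-bump mixture 55 days apart for
multiple-peaked populations, with between-year jitter (SD 3 days) and
optional linear advances for trend-recovery tests.

What the generator does *not* emulate: linkage disequilibrium between
markers (pruning is validated on explicit duplicated-column fixtures
instead; there is no recombination map), coalescent ancestry,
genotyping error, trap-efficiency variation, and within-season environmental
covariates of the counts. Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery under the stated
generative model — not robustness to those real-data complications.

## Problem sizes and determinism

Validation runs use the full synthetic study (297 × 5,000) for association
checks, 500-tree forests over 50-locus candidate sets for the offset
contrast, 500 small null datasets at 199 permutations for the test-size
check, and 20 replicate 28-year count series for trend recovery. Every
stochastic component takes an explicit seed, and identical seeds reproduce
results byte-for-byte; `scripts/acceptance.R` threads a single `--seed`
through all of them.

## Known limitations

Population-level phenotypes mean association operates on 11 effective
units however many fish are genotyped; standard errors describe association
at the population scale, and the latent-factor correction can only
distinguish cline from drift to the extent the cline has within-region
leverage. Gradient forests at 11 sites give coarse turnover functions —
typically a handful of split values per predictor — and out-of-bag R² at
this n is noisy, which is why the multi-run protocol and the R² > 0 filter
exist. The NMF ancestry model is a structure summary, not an admixture-graph
inference; its K selection is an elbow heuristic and is reported alongside
the cross-entropy curve rather than asserted as truth.
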