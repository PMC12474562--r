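# Genotype container, I/O, and QC filters.

#' Construct a genotype matrix
#'
#' Holds biallelic SNP dosages (count of alternate alleles, 0/1/2, `NA` for
#' missing) for a set of individuals with population labels, plus a marker
#' map.
#'
#' @param dosages individuals x SNPs matrix with entries in \{0, 1, 2, NA\}.
#' @param markers data.frame with columns id, chrom, pos, ref, alt.
#' @param individuals character vector of sample identifiers.
#' @param pop_labels population label per individual.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, markers, individuals = NULL,
                            pop_labels = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(individuals)) individuals <- rownames(dosages) %||%
      paste0("ind", seq_len(nrow(dosages)))
  if (is.null(pop_labels)) pop_labels <- rep("pop1", nrow(dosages))
  stopifnot(nrow(markers) == ncol(dosages),
            length(individuals) == nrow(dosages),
            length(pop_labels) == nrow(dosages),
            all(c("id", "chrom", "pos") %in% names(markers)))
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    w <- which(matrix(bad, nrow(dosages)), arr.ind = TRUE)[1L, ]
    stop("invalid dosage at individual ", individuals[w[1L]],
         ", marker ", markers$id[w[2L]], " (must be 0, 1, 2 or NA)")
  }
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(individuals, markers$id)
  rownames(markers) <- NULL
  structure(list(dosages = dosages, markers = markers,
                 individuals = individuals,
                 pop_labels = as.character(pop_labels)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs;",
      length(unique(x$pop_labels)), "populations;",
      sum(is.na(x$dosages)), "missing dosages\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# subset SNP columns, keeping the container consistent
subset_snps <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$markers[keep, , drop = FALSE],
                  g$individuals, g$pop_labels)
}

#' Per-SNP minor allele frequency
#' @param g a [genotype_matrix()].
#' @return numeric vector, `min(p, 1 - p)` of the alternate-allele frequency
#'   computed from non-missing dosages.
#' @export
snp_maf <- function(g) {
  p <- colMeans(g$dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Read genotypes from VCF or dosage-TSV
#'
#' VCF parsing is delegated to \pkg{vcfR}; only biallelic SNPs are retained
#' (multiallelic records are skipped and counted in a message). The dosage
#' format is a TSV of individuals x markers with an `individual` first
#' column, paired with a marker-map TSV (id, chrom, pos, ref, alt).
#'
#' @param path VCF path, or genotype TSV path for `format = "dosage"`.
#' @param format `"vcf"` or `"dosage"` (default guesses from the extension).
#' @param markers_path marker map TSV (dosage format only).
#' @param popmap optional TSV with columns individual, population.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage"),
                           markers_path = NULL, popmap = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
    if (any(multi))
      message("skipped ", sum(multi), " non-biallelic-SNP record(s)")
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    dose_of <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
                 "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
    dos <- matrix(dose_of[gt], nrow = nrow(gt))  # unknown codes -> NA
    dos <- t(dos)
    markers <- data.frame(
      id = ifelse(is.na(fix$ID) | fix$ID == ".",
                  paste0(fix$CHROM, "_", fix$POS), fix$ID),
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
    )
    individuals <- colnames(gt)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (names(tab)[1L] != "individual")
      stop("dosage TSV must have 'individual' as its first column")
    individuals <- tab$individual
    dos <- as.matrix(tab[, -1L, drop = FALSE])
    ok <- dos %in% c(0, 1, 2) | is.na(dos)
    if (!all(ok)) {
      w <- which(matrix(!ok, nrow(dos)), arr.ind = TRUE)[1L, ]
      stop("invalid dosage value '", dos[w[1L], w[2L]], "' at individual ",
           individuals[w[1L]], ", marker ", colnames(dos)[w[2L]])
    }
    storage.mode(dos) <- "integer"
    if (!is.null(markers_path)) {
      markers <- read.table(markers_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
      markers <- markers[match(colnames(dos), markers$id), , drop = FALSE]
    } else {
      markers <- data.frame(id = colnames(dos), chrom = "chrUn",
                            pos = seq_len(ncol(dos)), ref = "A", alt = "G",
                            stringsAsFactors = FALSE)
    }
  }
  pop_labels <- NULL
  if (!is.null(popmap)) {
    pm <- read.table(popmap, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    pop_labels <- pm$population[match(individuals, pm$individual)]
  }
  genotype_matrix(dos, markers, individuals, pop_labels)
}

#' Write genotypes as VCF 4.2 or dosage-TSV
#'
#' @param g a [genotype_matrix()].
#' @param path output file (VCF) or genotype TSV path (dosage; the marker map
#'   and population map are written next to it as `<stem>.markers.tsv` and
#'   `<stem>.popmap.tsv`).
#' @param format `"vcf"` or `"dosage"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "vcf") {
    gt_of <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(g$dosages), ncol(g$dosages))
    obs <- !is.na(g$dosages)
    gt[obs] <- gt_of[g$dosages[obs] + 1L]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", g$individuals),
                       collapse = "\t")), con)
    body <- paste(g$markers$chrom, g$markers$pos, g$markers$id,
                  g$markers$ref, g$markers$alt, ".", "PASS", ".", "GT",
                  apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  } else {
    stem <- sub("\\.tsv$", "", path)
    tab <- data.frame(individual = g$individuals, g$dosages,
                      check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(g$markers, paste0(stem, ".markers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(individual = g$individuals,
                           population = g$pop_labels),
                paste0(stem, ".popmap.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Minor-allele-frequency filter
#'
#' Retains SNPs whose MAF (from non-missing dosages) is at least `cutoff`
#' -- the inclusive boundary of PLINK's `--maf`.
#'
#' @param g a [genotype_matrix()].
#' @param cutoff frequency in \[0, 0.5\].
#' @return filtered [genotype_matrix()].
#' @export
maf_filter <- function(g, cutoff = 0.01) {
  stopifnot(cutoff >= 0, cutoff <= 0.5)
  subset_snps(g, which(snp_maf(g) >= cutoff))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage vectors over individuals
#' non-missing at both SNPs (PLINK `--r2` on dosages).
#'
#' @param g a [genotype_matrix()].
#' @param snp_i,snp_j column indices or marker ids.
#' @return r-squared in \[0, 1\], or `NA` if either SNP is monomorphic in the
#'   jointly observed subset.
#' @export
pairwise_r2 <- function(g, snp_i, snp_j) {
  if (is.character(snp_i)) snp_i <- match(snp_i, g$markers$id)
  if (is.character(snp_j)) snp_j <- match(snp_j, g$markers$id)
  x <- g$dosages[, snp_i]
  y <- g$dosages[, snp_j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Windowed LD pruning
#'
#' Greedy sliding-window pruning in the spirit of PLINK
#' `--indep-pairwise`: within each window of `window_snps` markers (sliding
#' by `step_snps`, within chromosome), while any retained pair has
#' r-squared above `r2_threshold`, the member with the lower MAF is removed
#' (ties broken by removing the larger position).
#'
#' @param g a [genotype_matrix()] with markers sorted by (chrom, pos).
#' @param window_snps,step_snps,r2_threshold pruning parameters; the
#'   defaults are the common 50-SNP window, 5-SNP step, r2 0.5.
#' @return pruned [genotype_matrix()]; marker order is preserved.
#' @export
ld_prune <- function(g, window_snps = 50L, step_snps = 5L,
                     r2_threshold = 0.5) {
  ord <- order(g$markers$chrom, g$markers$pos)
  if (any(ord != seq_along(ord)))
    stop("markers must be sorted by (chrom, pos) before pruning")
  maf <- snp_maf(g)
  keep <- rep(TRUE, ncol(g$dosages))
  imp <- impute_center_scale(g$dosages, scale = FALSE)$x
  for (chr in unique(g$markers$chrom)) {
    cols <- which(g$markers$chrom == chr)
    start <- 1L
    repeat {
      win <- cols[seq(start, min(start + window_snps - 1L, length(cols)))]
      active <- win[keep[win]]
      if (length(active) > 1L) {
        repeat {
          cm <- suppressWarnings(cor(imp[, active, drop = FALSE]))
          cm[!is.finite(cm)] <- 0
          diag(cm) <- 0
          r2 <- cm^2
          if (max(r2) <= r2_threshold) break
          ij <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
          a <- active[ij[1L]]; b <- active[ij[2L]]
          victim <- if (maf[a] < maf[b]) a
            else if (maf[b] < maf[a]) b
            else max(a, b)  # tie: drop larger position
          keep[victim] <- FALSE
          active <- setdiff(active, victim)
          if (length(active) < 2L) break
        }
      }
      if (start + window_snps - 1L >= length(cols)) break
      start <- start + step_snps
    }
  }
  subset_snps(g, which(keep))
}
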