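# Study-level fixture I/O: long-form counts and whole simulated studies.

#' Read a daily-count table
#'
#' TSV with columns population, year, doy, size_class, count.
#'
#' @param path file path.
#' @return validated data.frame of daily counts.
#' @export
read_counts <- function(path) {
  counts <- read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  need <- c("population", "year", "doy", "size_class", "count")
  if (!all(need %in% names(counts)))
    stop("counts TSV needs columns: ", paste(need, collapse = ", "))
  .check_counts(counts)
  key <- paste(counts$population, counts$year, counts$doy, counts$size_class)
  if (anyDuplicated(key))
    stop("duplicate (population, year, doy, size_class) rows in ", path)
  counts
}

#' Write a daily-count table
#' @param counts long-form daily counts.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Genotypes as VCF plus a population-map TSV, daily counts and climate as
#' TSV, gene intervals as BED, and the simulation ground truth as JSON.
#'
#' @param study a [simulate_study()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(study$genotypes, file.path(dir, "genotypes.vcf"))
  write.table(data.frame(individual = study$genotypes$individuals,
                         population = study$genotypes$pop_labels),
              file.path(dir, "popmap.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_counts(study$counts, file.path(dir, "daily_counts.tsv"))
  write_climate_table(study$climate, file.path(dir, "climate.tsv"))
  write_annotation_bed(study$genes, file.path(dir, "genes.bed"))
  truth <- study$truth
  jsonlite::write_json(
    list(trait_loci = truth$trait_loci, ancestral_k = truth$ancestral_k,
         planted_slopes = truth$planted_slopes,
         modality_labels = as.list(truth$modality_labels)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
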