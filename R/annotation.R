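# Gene annotation: interval readers and SNP-to-gene distance windows.
# Coordinates are 1-based inclusive internally (VCF/GFF convention); BED
# input (0-based half-open) is converted on read.

#' Read gene intervals from GFF3 or BED
#'
#' GFF3: only rows with feature type `gene` are kept (others are counted in
#' a message); the gene id comes from the `ID=` attribute (falling back to
#' `Name=`). BED4+: the 0-based half-open start is converted to 1-based
#' inclusive. Malformed lines raise an error naming the line number.
#'
#' @param path file path.
#' @param format `"gff3"`, `"bed"`, or `"auto"` (guess from extension).
#' @return data.frame: gene_id, chrom, start, end, strand.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", path)) "gff3" else "bed"
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (format == "gff3") {
    nf <- lengths(fields)
    if (any(nf < 9L))
      stop("malformed GFF3 line ", lineno[which(nf < 9L)[1L]],
           ": expected 9 tab-separated fields")
    type <- vapply(fields, `[[`, "", 3L)
    skipped <- sum(type != "gene")
    if (skipped > 0) message("skipped ", skipped, " non-gene feature row(s)")
    fields <- fields[type == "gene"]
    if (length(fields) == 0L)
      return(data.frame(gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0)))
    attr9 <- vapply(fields, `[[`, "", 9L)
    gid <- sub(".*ID=([^;]+).*", "\\1", attr9)
    no_id <- !grepl("ID=", attr9)
    gid[no_id] <- sub(".*Name=([^;]+).*", "\\1", attr9[no_id])
    out <- data.frame(
      gene_id = gid,
      chrom = vapply(fields, `[[`, "", 1L),
      start = as.integer(vapply(fields, `[[`, "", 4L)),
      end = as.integer(vapply(fields, `[[`, "", 5L)),
      strand = vapply(fields, `[[`, "", 7L),
      stringsAsFactors = FALSE
    )
  } else {
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop("malformed BED line ", lineno[which(nf < 3L)[1L]],
           ": expected at least 3 tab-separated fields")
    out <- data.frame(
      gene_id = vapply(seq_along(fields), function(i)
        if (nf[i] >= 4L) fields[[i]][4L] else paste0("interval", i), ""),
      chrom = vapply(fields, `[[`, "", 1L),
      start = as.integer(vapply(fields, `[[`, "", 2L)) + 1L,  # 0-based -> 1-based
      end = as.integer(vapply(fields, `[[`, "", 3L)),
      strand = vapply(seq_along(fields), function(i)
        if (nf[i] >= 6L) fields[[i]][6L] else "*", ""),
      stringsAsFactors = FALSE
    )
  }
  bad <- which(is.na(out$start) | is.na(out$end) | out$start > out$end)
  if (length(bad))
    stop("malformed interval on line ", lineno[bad[1L]],
         ": need numeric start <= end")
  rownames(out) <- NULL
  out
}

#' Write gene intervals as BED
#' @param genes data.frame as returned by [read_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(genes, path) {
  writeLines(paste(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
                   0L, genes$strand %||% "*", sep = "\t"), path)
  invisible(path)
}

#' Genes within a distance window of each SNP
#'
#' For every SNP, reports all genes on the same chromosome whose distance is
#' at most `window` base pairs: distance 0 when the SNP position lies inside
#' \[start, end\], otherwise `start - pos` or `pos - end`. The boundary is
#' inclusive (a gene exactly `window` bp away is reported) and strand is
#' ignored -- upstream and downstream are symmetric. Interval overlap is
#' found with \pkg{IRanges}; results are identical to a brute-force scan.
#' SNPs on chromosomes absent from the annotation simply yield no records.
#'
#' @param snps data.frame with columns id, chrom, pos (e.g.
#'   `g$markers[candidates, ]`).
#' @param genes data.frame from [read_annotation()].
#' @param window maximum distance in bp (default 50,000).
#' @return data.frame: snp_id, gene_id, distance; sorted by (snp_id,
#'   distance, gene_id).
#' @export
closest_genes <- function(snps, genes, window = 50000L) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (nrow(snps) == 0L || nrow(genes) == 0L)
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      distance = integer(0)))
  shared <- union(snps$chrom, genes$chrom)
  gr_snp <- GenomicRanges::GRanges(
    factor(snps$chrom, levels = shared),
    IRanges::IRanges(snps$pos, snps$pos))
  gr_gene <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = shared),
    IRanges::IRanges(genes$start, genes$end))
  # maxgap counts the gap between ranges (adjacent = 0), so maxgap = window
  # over-captures by one bp; the exact arithmetic filter below settles it.
  hits <- GenomicRanges::findOverlaps(gr_snp, gr_gene, maxgap = window)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pos <- snps$pos[qi]
  d <- pmax(genes$start[si] - pos, pos - genes$end[si], 0L)
  keep <- d <= window
  out <- data.frame(snp_id = snps$id[qi][keep],
                    gene_id = genes$gene_id[si][keep],
                    distance = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$snp_id, out$distance, out$gene_id), , drop = FALSE]
}

#' Genes with direct SNP overlap
#'
#' @param records data.frame from [closest_genes()].
#' @return sorted character vector of gene ids with at least one
#'   zero-distance SNP.
#' @export
direct_overlap_filter <- function(records) {
  sort(unique(records$gene_id[records$distance == 0L]))
}
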