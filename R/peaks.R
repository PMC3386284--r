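# Peak-gene association by the 1 bp overlap rule, peak summaries, saturation.

#' Associate peaks with genes by the 1 bp overlap rule
#'
#' A peak is associated with a gene whenever its interval overlaps any of the
#' gene's four region classes (\code{up20K}, \code{exon}, \code{intron},
#' \code{down20K}) by at least one base pair. A gene appears once with the
#' union of the region classes through which it is hit and the supporting
#' peak indices; the number of rows is the count of distinct genes related to
#' peaks.
#'
#' @param peaks peak data.frame in internal 0-based half-open coordinates
#'   (see [read_macs_peaks()]).
#' @param genes gene-model data.frame.
#' @param flank flank size in bp (default 20000).
#' @param genome_sizes optional named chromosome lengths (clips flanks).
#' @return data.frame with one row per associated gene: \code{gene_id},
#'   list columns \code{labels} and \code{peak_idx}, and \code{n_peaks}.
#' @export
associate_peaks_with_genes <- function(peaks, genes, flank = 20000L,
                                       genome_sizes = NULL) {
  .assert_genes(genes)
  lab_gr <- .gene_label_ranges(genes, flank, genome_sizes = genome_sizes)
  peak_gr <- .gr0(peaks$chrom, peaks$start, peaks$end,
                  peak_idx = seq_len(nrow(peaks)))
  ov <- GenomicRanges::findOverlaps(peak_gr, lab_gr, minoverlap = 1L,
                                    ignore.strand = TRUE)
  if (length(ov) == 0L) {
    out <- data.frame(gene_id = character(), n_peaks = integer())
    out$labels <- list(); out$peak_idx <- list()
    return(out[, c("gene_id", "labels", "peak_idx", "n_peaks")])
  }
  pk <- S4Vectors::mcols(peak_gr)$peak_idx[S4Vectors::queryHits(ov)]
  gi <- S4Vectors::mcols(lab_gr)$gene_idx[S4Vectors::subjectHits(ov)]
  lb <- S4Vectors::mcols(lab_gr)$label[S4Vectors::subjectHits(ov)]
  genes_hit <- sort(unique(gi))
  labels <- lapply(genes_hit, function(g)
    intersect(REGION_LABELS, unique(lb[gi == g])))
  peak_idx <- lapply(genes_hit, function(g) sort(unique(pk[gi == g])))
  out <- data.frame(gene_id = genes$gene_id[genes_hit],
                    n_peaks = lengths(peak_idx))
  out$labels <- labels
  out$peak_idx <- peak_idx
  out[, c("gene_id", "labels", "peak_idx", "n_peaks")]
}

#' Percentage of peak-associated genes per region class
#'
#' For each region class, the fraction of associated genes carrying that
#' label, as a percentage. Labels are not exclusive (a gene can be hit
#' through several classes), so the percentages may sum to more than 100.
#'
#' @param associations output of [associate_peaks_with_genes()].
#' @param n_genes_associated denominator; defaults to the number of
#'   associated genes.
#' @return named numeric vector of percentages for the four genic classes.
#' @export
peak_region_percentages <- function(associations,
                                    n_genes_associated = nrow(associations)) {
  if (n_genes_associated < 1L) .stopf("n_genes_associated must be >= 1")
  vapply(REGION_LABELS, function(L)
    100 * sum(vapply(associations$labels, function(x) L %in% x, logical(1))) /
      n_genes_associated,
    numeric(1))
}

#' Summary statistics of a peak set
#'
#' @param peaks peak data.frame (0-based half-open).
#' @return list with \code{n}, \code{mean_length_bp}, \code{total_length_bp}
#'   and \code{empty} flag (lengths reported as 0 when there are no peaks).
#' @export
peak_summary_stats <- function(peaks) {
  n <- nrow(peaks)
  if (n == 0L)
    return(list(n = 0L, mean_length_bp = 0, total_length_bp = 0, empty = TRUE))
  len <- peaks$end - peaks$start
  list(n = n, mean_length_bp = mean(len), total_length_bp = sum(len),
       empty = FALSE)
}

#' Read-subsampling saturation curve over fixed peak regions
#'
#' Subsamples the read set without replacement at each requested fraction and
#' reports the mean tag density (reads per bp) over the union of the supplied
#' peak regions. The peak regions are fixed (from the full data); peaks are
#' not re-called per fraction. Expected density scales linearly with the
#' fraction, so a plateauing curve relative to that line indicates saturated
#' coverage.
#'
#' @param reads read table.
#' @param fractions numeric vector of subsampling proportions in (0, 1].
#' @param peak_regions peak data.frame (0-based half-open) or GRanges.
#' @param seed integer seed; the subsample for a given (seed, fraction) pair
#'   is the same regardless of which other fractions are requested.
#' @return data.frame with \code{fraction}, \code{n_reads}, \code{density}.
#' @export
saturation_curve <- function(reads, fractions, peak_regions, seed = 1L) {
  .assert_reads(reads)
  if (any(fractions <= 0 | fractions > 1))
    .stopf("fractions must lie in (0, 1]")
  gr <- if (methods::is(peak_regions, "GRanges")) peak_regions
        else .gr0(peak_regions$chrom, peak_regions$start, peak_regions$end)
  gr <- GenomicRanges::reduce(gr)
  total_bp <- sum(as.numeric(GenomicRanges::width(gr)))
  if (total_bp == 0) .stopf("empty peak regions")
  n <- nrow(reads)
  res <- lapply(fractions, function(f) {
    .set_seed(seed + round(f * 1e6))
    take <- if (f == 1) seq_len(n) else sample.int(n, round(f * n))
    pts <- .read_points(reads[take, , drop = FALSE])
    data.frame(fraction = f, n_reads = length(take),
               density = sum(IRanges::overlapsAny(pts, gr)) / total_bp)
  })
  do.call(rbind, res)
}
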