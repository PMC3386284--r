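# Read distribution across region classes and abundance normalization.

#' Count reads per region class
#'
#' Each read is a point event at its 5' position. In multilabel mode every
#' label covering the point is incremented (so label counts can sum to more
#' than the number of reads); in exclusive mode the partition labels are
#' disjoint and each read increments exactly one. Reads on a chromosome absent
#' from the partition are counted as intergenic with a warning tally.
#'
#' @param reads read table.
#' @param index a \code{region_partition}.
#' @return named integer vector of counts for
#'   \code{up20K, exon, intron, down20K, intergenic}, with attributes
#'   \code{n_reads} and \code{n_unknown_chrom}.
#' @export
assign_reads_to_regions <- function(reads, index) {
  .assert_reads(reads)
  if (!inherits(index, "region_partition"))
    .stopf("index must be a region_partition")
  known <- reads$chrom %in% names(index$genome_sizes)
  n_unknown <- sum(!known)
  if (n_unknown > 0L)
    .warnf("%d read(s) on chromosomes absent from the partition counted intergenic",
           n_unknown)
  pts <- .read_points(reads[known, , drop = FALSE], index$genome_sizes)
  hit <- vapply(REGION_LABELS, function(L)
    IRanges::overlapsAny(pts, index$labels[[L]]), logical(length(pts)))
  if (length(pts) == 1L) hit <- matrix(hit, nrow = 1L,
                                       dimnames = list(NULL, REGION_LABELS))
  counts <- if (length(pts)) colSums(hit) else setNames(rep(0, 4), REGION_LABELS)
  none <- if (length(pts)) sum(rowSums(hit) == 0L) else 0L
  out <- c(counts, intergenic = none + n_unknown)
  storage.mode(out) <- "integer"
  attr(out, "n_reads") <- nrow(reads)
  attr(out, "n_unknown_chrom") <- n_unknown
  out
}

#' Normalize read percentages to abundance values
#'
#' Abundance of a region class is its read percentage divided by its genome
#' percentage: 1 means reads occur at genome-average density, above 1 means
#' enrichment. Undefined (and an error) when a class has reads but zero
#' genome share.
#'
#' @param read_pct named numeric, percentage of reads per label.
#' @param genome_pct named numeric, percentage of the genome per label
#'   (same names).
#' @return named numeric vector of abundance ratios.
#' @export
abundance_normalize <- function(read_pct, genome_pct) {
  if (is.null(names(read_pct)) || is.null(names(genome_pct)))
    .stopf("read_pct and genome_pct must be named")
  genome_pct <- genome_pct[names(read_pct)]
  if (anyNA(genome_pct))
    .stopf("genome_pct missing label(s): %s",
           paste(names(read_pct)[is.na(genome_pct)], collapse = ", "))
  undef <- genome_pct == 0 & read_pct > 0
  if (any(undef))
    .stopf("abundance undefined for label(s) with zero genome share: %s",
           paste(names(read_pct)[undef], collapse = ", "))
  out <- ifelse(genome_pct == 0, NA_real_, read_pct / genome_pct)
  setNames(out, names(read_pct))
}

#' Full per-region read distribution summary
#'
#' Combines [assign_reads_to_regions()], [region_genome_fractions()] and
#' [abundance_normalize()] into the standard summary table. Read percentages
#' use the total number of reads as denominator (not the sum of label counts),
#' so each label's percentage is interpretable on its own; in exclusive mode
#' they sum to 100.
#'
#' @param reads read table.
#' @param index a \code{region_partition}.
#' @return data.frame with columns \code{label}, \code{count},
#'   \code{read_pct}, \code{genome_pct}, \code{abundance}.
#' @export
region_read_summary <- function(reads, index) {
  counts <- assign_reads_to_regions(reads, index)
  n <- attr(counts, "n_reads")
  if (n == 0L) .stopf("no reads")
  read_pct <- 100 * counts / n
  genome_pct <- 100 * region_genome_fractions(index)[names(counts)]
  data.frame(
    label = names(counts),
    count = as.integer(counts),
    read_pct = as.numeric(read_pct),
    genome_pct = as.numeric(genome_pct),
    abundance = as.numeric(abundance_normalize(read_pct, genome_pct)),
    row.names = NULL
  )
}
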