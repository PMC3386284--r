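# Tag-density profiling: TSS-anchored windows, metagene bins, promoter windows.
#
# All offsets are in transcription orientation: negative = upstream of the
# anchor, and windows are left-closed right-open in oriented offset space, so
# the TSS sits at the left edge of the first downstream column.

.new_profile_matrix <- function(counts, gene_ids, offsets, bp, geometry,
                                window = NA_integer_, span = NA_integer_) {
  dimnames(counts) <- list(gene_ids, as.character(offsets))
  structure(list(counts = counts, gene_ids = gene_ids, offsets = offsets,
                 bp_per_window = bp, geometry = geometry,
                 window = window, span = span),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix (%s): %d genes x %d windows, %d counts total\n",
              x$geometry, nrow(x$counts), ncol(x$counts),
              sum(x$counts, na.rm = TRUE)))
  invisible(x)
}

# oriented offsets of reads relative to each gene's TSS, restricted to
# [lo, hi); returns data.frame(gene_idx, offset)
.oriented_tss_hits <- function(reads, genes, lo, hi) {
  tss <- .gene_tss(genes)
  plus <- genes$strand == "+"
  s0 <- ifelse(plus, tss + lo, tss - hi + 1)
  e0 <- ifelse(plus, tss + hi, tss - lo + 1)
  spans <- .gr0(genes$chrom, pmax(s0, 0), e0, gene_idx = seq_len(nrow(genes)))
  pts <- .read_points(reads)
  ov <- GenomicRanges::findOverlaps(pts, spans, ignore.strand = TRUE)
  g <- S4Vectors::mcols(spans)$gene_idx[S4Vectors::subjectHits(ov)]
  p <- reads$pos5[S4Vectors::queryHits(ov)]
  off <- ifelse(plus[g], p - tss[g], tss[g] - p)
  keep <- off >= lo & off < hi
  data.frame(gene_idx = g[keep], offset = off[keep])
}

# NA-flag columns whose genome footprint leaves the chromosome; a is the
# vector of column left edges in oriented offset space, w the column width
.tss_na_mask <- function(genes, genome_sizes, a, w) {
  tss <- .gene_tss(genes)
  plus <- genes$strand == "+"
  len <- unname(genome_sizes[genes$chrom])
  lo_ok <- ifelse(plus, -tss, tss + 1 - len)       # min valid a
  hi_ok <- ifelse(plus, len - tss - w, tss - w + 1) # max valid a
  outer(lo_ok, a, `>`) | outer(hi_ok, a, `<`)
}

.accumulate_counts <- function(gene_idx, col_idx, n_genes, n_cols) {
  m <- Matrix::sparseMatrix(i = gene_idx, j = col_idx, x = 1,
                            dims = c(n_genes, n_cols))
  as.matrix(m)
}

#' TSS-anchored tag-count profile matrix
#'
#' Builds a genes x windows matrix of read counts over
#' \code{[TSS - span, TSS + span)} in transcription orientation, in
#' \code{window}-bp columns (minus-strand genes are mirrored so negative
#' offsets are biologically upstream). A read contributes to the column
#' containing its 5' position. When \code{genome_sizes} is supplied, columns
#' whose genomic footprint leaves the chromosome are set to \code{NA} and
#' excluded from averages downstream.
#'
#' @param reads read table.
#' @param genes gene-model data.frame.
#' @param window window width in bp (default 50).
#' @param span half-width of the profiled region in bp (default 20000); must
#'   be a multiple of \code{window}.
#' @param genome_sizes optional named chromosome lengths for edge flagging.
#' @return a \code{profile_matrix} whose \code{offsets} are the oriented left
#'   edges of the columns.
#' @export
tss_profile_matrix <- function(reads, genes, window = 50L, span = 20000L,
                               genome_sizes = NULL) {
  .assert_reads(reads); .assert_genes(genes)
  window <- as.integer(window); span <- as.integer(span)
  if (span %% window != 0L) .stopf("span must be a multiple of window")
  k <- 2L * span %/% window
  hits <- .oriented_tss_hits(reads, genes, -span, span)
  col <- (hits$offset + span) %/% window + 1L
  counts <- .accumulate_counts(hits$gene_idx, col, nrow(genes), k)
  offsets <- seq(-span, span - window, by = window)
  if (!is.null(genome_sizes))
    counts[.tss_na_mask(genes, genome_sizes, offsets, window)] <- NA_real_
  .new_profile_matrix(counts, genes$gene_id, offsets, rep(window, k),
                      geometry = "tss", window = window, span = span)
}

#' Promoter-window tag densities
#'
#' Like [tss_profile_matrix()] but covering only the upstream promoter region
#' \code{[TSS - span, TSS)} in \code{window}-bp columns (defaults: ten 500 bp
#' windows over the upstream 5 kb). Counts divided by the column width (via
#' [aggregate_density()] or \code{profile_densities()}) give tags per bp.
#'
#' @inheritParams tss_profile_matrix
#' @param window window width in bp (default 500).
#' @param span upstream extent in bp (default 5000).
#' @return a \code{profile_matrix}.
#' @export
promoter_window_densities <- function(reads, genes, window = 500L,
                                      span = 5000L, genome_sizes = NULL) {
  .assert_reads(reads); .assert_genes(genes)
  window <- as.integer(window); span <- as.integer(span)
  if (span %% window != 0L) .stopf("span must be a multiple of window")
  k <- span %/% window
  hits <- .oriented_tss_hits(reads, genes, -span, 0L)
  col <- (hits$offset + span) %/% window + 1L
  counts <- .accumulate_counts(hits$gene_idx, col, nrow(genes), k)
  offsets <- seq(-span, -window, by = window)
  if (!is.null(genome_sizes))
    counts[.tss_na_mask(genes, genome_sizes, offsets, window)] <- NA_real_
  .new_profile_matrix(counts, genes$gene_id, offsets, rep(window, k),
                      geometry = "promoter", window = window, span = span)
}

#' Metagene tag-count profile
#'
#' Sums read counts into a fixed metagene geometry per gene: \code{flank_kb}
#' upstream 1 kb bins, \code{body_bins} gene-body bins of one
#' \code{body_bins}-th of the gene length each (so 5\% bins by default), and
#' \code{flank_kb} downstream 1 kb bins, all in transcription orientation.
#' Dividing by the per-bin base-pair count (which the object carries as a
#' genes x bins matrix) yields densities free of the bin-size effect. Genes
#' shorter than \code{body_bins} bp are excluded with a warning.
#'
#' @inheritParams tss_profile_matrix
#' @param body_bins number of gene-body bins (default 20).
#' @param flank_kb flank extent in kb on each side (default 20).
#' @return a \code{profile_matrix} with \code{2*flank_kb + body_bins} columns;
#'   \code{offsets} are bin indices (negative = upstream flank bins,
#'   1..body_bins = body, above that = downstream flank bins).
#' @export
metagene_profile <- function(reads, genes, body_bins = 20L, flank_kb = 20L,
                             genome_sizes = NULL) {
  .assert_reads(reads); .assert_genes(genes)
  body_bins <- as.integer(body_bins); flank_kb <- as.integer(flank_kb)
  flank <- flank_kb * 1000L
  L <- genes$end - genes$start
  short <- L < body_bins
  if (any(short)) {
    .warnf("%d gene(s) shorter than body_bins excluded from metagene", sum(short))
    genes <- genes[!short, , drop = FALSE]
    L <- L[!short]
  }
  n <- nrow(genes)
  k <- 2L * flank_kb + body_bins
  plus <- genes$strand == "+"
  spans <- .gr0(genes$chrom, pmax(genes$start - flank, 0), genes$end + flank,
                gene_idx = seq_len(n))
  pts <- .read_points(reads)
  ov <- GenomicRanges::findOverlaps(pts, spans, ignore.strand = TRUE)
  g <- S4Vectors::mcols(spans)$gene_idx[S4Vectors::subjectHits(ov)]
  p <- reads$pos5[S4Vectors::queryHits(ov)]
  u <- ifelse(plus[g], p - genes$start[g], (genes$end[g] - 1) - p)
  keep <- u >= -flank & u < L[g] + flank
  g <- g[keep]; u <- u[keep]
  bin <- integer(length(u))
  up <- u < 0
  body <- u >= 0 & u < L[g]
  dn <- u >= L[g]
  bin[up] <- (u[up] + flank) %/% 1000L + 1L
  bin[body] <- flank_kb + 1L +
    pmin(floor(as.numeric(u[body]) * body_bins / L[g[body]]), body_bins - 1L)
  bin[dn] <- flank_kb + body_bins + 1L + (u[dn] - L[g[dn]]) %/% 1000L
  counts <- .accumulate_counts(g, bin, n, k)

  # per-gene bin widths: 1 kb flanks; body bin j holds
  # ceil((j+1)L/B) - ceil(jL/B) integer positions
  bp <- matrix(1000, nrow = n, ncol = k)
  for (j in seq_len(body_bins)) {
    bp[, flank_kb + j] <- ceiling(j * L / body_bins) -
      ceiling((j - 1) * L / body_bins)
  }
  if (!is.null(genome_sizes)) {
    len <- unname(genome_sizes[genes$chrom])
    a_up <- seq(-flank, -1000L, by = 1000L)          # upstream bin left edges
    na_up <- .metagene_flank_na(genes, len, a_up, plus, upstream = TRUE)
    a_dn <- seq(0L, flank - 1000L, by = 1000L)       # downstream, offset past TES
    na_dn <- .metagene_flank_na(genes, len, a_dn, plus, upstream = FALSE)
    counts[, seq_len(flank_kb)][na_up] <- NA_real_
    counts[, flank_kb + body_bins + seq_len(flank_kb)][na_dn] <- NA_real_
  }
  offsets <- c(seq(-flank_kb, -1L), seq_len(body_bins),
               body_bins + seq_len(flank_kb))
  .new_profile_matrix(counts, genes$gene_id, offsets, bp,
                      geometry = "metagene")
}

# flank bins whose 1 kb genome footprint leaves the chromosome; the same
# anchor formula serves both flanks: genome start = anchor + a on plus,
# anchor - a - w on minus (a = oriented bin left edge relative to the anchor)
.metagene_flank_na <- function(genes, len, a, plus, upstream) {
  w <- 1000L
  anchor <- if (upstream) ifelse(plus, genes$start, genes$end)
            else ifelse(plus, genes$end, genes$start)
  s_plus <- outer(anchor, a, `+`)
  s_minus <- outer(anchor, -(a + w), `+`)
  s <- s_plus
  if (any(!plus)) s[!plus, ] <- s_minus[!plus, ]
  s < 0 | (s + w) > matrix(len, nrow = nrow(genes), ncol = length(a))
}

#' Mean tag density per window over a gene set
#'
#' Column means of count / bp over the (non-missing) rows of a profile
#' matrix, optionally restricted to a gene set and optionally scaled to
#' reads-per-million library size for between-sample comparisons.
#'
#' @param matrix a \code{profile_matrix}.
#' @param gene_set optional character vector of gene ids (must all be rows).
#' @param per_million optional library size; densities are multiplied by
#'   \code{1e6 / per_million} when given.
#' @return named numeric vector of mean densities (tags per bp), one per
#'   window, named by oriented offset.
#' @export
aggregate_density <- function(matrix, gene_set = NULL, per_million = NULL) {
  if (!inherits(matrix, "profile_matrix")) .stopf("not a profile_matrix")
  counts <- matrix$counts
  if (!is.null(gene_set)) {
    if (length(gene_set) == 0L) .stopf("empty gene_set")
    missing <- setdiff(gene_set, matrix$gene_ids)
    if (length(missing))
      .stopf("gene_set not in profile rows: %s",
             paste(head(missing, 3), collapse = ", "))
    counts <- counts[match(gene_set, matrix$gene_ids), , drop = FALSE]
  }
  if (nrow(counts) == 0L) .stopf("empty gene_set")
  bp <- matrix$bp_per_window
  dens <- if (is.matrix(bp)) {
    bpr <- if (!is.null(gene_set)) bp[match(gene_set, matrix$gene_ids), , drop = FALSE] else bp
    counts / bpr
  } else {
    sweep(counts, 2L, bp, `/`)
  }
  if (!is.null(per_million)) dens <- dens * 1e6 / per_million
  setNames(colMeans(dens, na.rm = TRUE), as.character(matrix$offsets))
}
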