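# Five-class genome partition: up20K / exon / intron / down20K / intergenic.

# Per-gene label ranges in 0-based half-open coordinates, clipped to the
# chromosome when genome_sizes is supplied. Returns a GRanges with mcols
# label and gene_idx.
.gene_label_ranges <- function(genes, flank, genome_sizes = NULL) {
  .assert_genes(genes)
  flank <- as.integer(flank)
  if (flank <= 0L) .stopf("flank must be > 0")
  plus <- genes$strand == "+"
  n <- nrow(genes)

  up_s <- ifelse(plus, genes$start - flank, genes$end)
  up_e <- ifelse(plus, genes$start, genes$end + flank)
  dn_s <- ifelse(plus, genes$end, genes$start - flank)
  dn_e <- ifelse(plus, genes$end + flank, genes$start)

  ex_n <- lengths(genes$exon_starts)
  ex_s <- unlist(genes$exon_starts, use.names = FALSE)
  ex_e <- unlist(genes$exon_ends, use.names = FALSE)
  ex_g <- rep.int(seq_len(n), ex_n)

  # introns: gaps between consecutive exons of the same gene
  in_s <- unlist(lapply(genes$exon_ends, function(e) e[-length(e)]), use.names = FALSE)
  in_e <- unlist(lapply(genes$exon_starts, function(s) s[-1L]), use.names = FALSE)
  in_g <- rep.int(seq_len(n), pmax(ex_n - 1L, 0L))

  lab <- c(rep("up20K", n), rep("exon", length(ex_s)),
           rep("intron", length(in_s)), rep("down20K", n))
  gidx <- c(seq_len(n), ex_g, in_g, seq_len(n))
  chrom <- genes$chrom[gidx]
  s0 <- c(up_s, ex_s, in_s, dn_s)
  e0 <- c(up_e, ex_e, in_e, dn_e)

  if (!is.null(genome_sizes)) {
    missing_chr <- setdiff(unique(genes$chrom), names(genome_sizes))
    if (length(missing_chr))
      .stopf("gene chromosome(s) absent from genome_sizes: %s",
             paste(missing_chr, collapse = ", "))
    len <- unname(genome_sizes[chrom])
    clipped <- s0 < 0 | e0 > len
    if (any(clipped & (e0 > pmax(s0, 0L))))
      .warnf("%d label interval(s) clipped at chromosome bounds",
             sum(clipped & (e0 > pmax(s0, 0L))))
    s0 <- pmax(s0, 0L)
    e0 <- pmin(e0, len)
  }
  keep <- e0 > s0
  .gr0(chrom, s0, e0, genome_sizes = genome_sizes,
       label = lab[keep], gene_idx = gidx[keep])
}

#' Partition a genome into five region classes
#'
#' Labels the genome with \code{up20K} (a \code{flank}-bp window upstream of
#' each TSS in transcription orientation), \code{exon}, \code{intron},
#' \code{down20K} (the flank after the TES) and \code{intergenic} (everything
#' else). Flanks are clipped at chromosome edges. Two modes are supported:
#' \describe{
#'   \item{multilabel}{a base pair may carry several labels (e.g. one gene's
#'     flank inside another's intron); per-class fractions can sum to more
#'     than 1. This is the default because observed region percentages of
#'     genomes annotated this way typically total more than 100\%.}
#'   \item{exclusive}{labels are made disjoint with precedence
#'     exon > intron > up20K > down20K; together with intergenic they tile the
#'     genome exactly once.}
#' }
#'
#' @param genes gene-model data.frame (see [read_gene_table()]).
#' @param genome_sizes named numeric vector, chromosome -> length in bp.
#' @param flank flank size in bp (default 20000).
#' @param mode \code{"multilabel"} (default) or \code{"exclusive"}.
#' @return an object of class \code{region_partition}: a list with the
#'   per-label \code{GRanges} (reduced), \code{genome_sizes}, \code{mode} and
#'   \code{flank}.
#' @export
build_region_partition <- function(genes, genome_sizes, flank = 20000L,
                                   mode = c("multilabel", "exclusive")) {
  mode <- match.arg(mode)
  gs <- setNames(as.numeric(genome_sizes), names(genome_sizes))
  gr <- .gene_label_ranges(genes, flank, genome_sizes = gs)
  labs <- lapply(REGION_LABELS, function(L)
    GenomicRanges::reduce(gr[S4Vectors::mcols(gr)$label == L]))
  names(labs) <- REGION_LABELS
  genome_gr <- .gr0(names(gs), rep(0, length(gs)), unname(gs), genome_sizes = gs)
  if (mode == "exclusive") {
    higher <- GenomicRanges::GRanges(seqlengths = GenomeInfoDb::seqlengths(genome_gr))
    for (L in c("exon", "intron", "up20K", "down20K")) {
      labs[[L]] <- GenomicRanges::setdiff(labs[[L]], higher)
      higher <- GenomicRanges::reduce(c(higher, labs[[L]]))
    }
    labs$intergenic <- GenomicRanges::setdiff(genome_gr, higher)
  } else {
    all_lab <- GenomicRanges::reduce(do.call(c, unname(labs)))
    labs$intergenic <- GenomicRanges::setdiff(genome_gr, all_lab)
  }
  structure(list(labels = labs, genome_sizes = gs, mode = mode,
                 flank = as.integer(flank)),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region partition (%s mode, flank %d bp) over %.3g bp genome\n",
              x$mode, x$flank, sum(x$genome_sizes)))
  fr <- region_genome_fractions(x)
  for (L in names(fr)) cat(sprintf("  %-10s %6.2f%%\n", L, 100 * fr[L]))
  invisible(x)
}

#' Genome fraction covered by each region class
#'
#' In exclusive mode the fractions (including intergenic) sum to exactly 1;
#' in multilabel mode they may sum to more than 1 because labels overlap.
#'
#' @param index a \code{region_partition}.
#' @return named numeric vector of fractions for
#'   \code{up20K, exon, intron, down20K, intergenic}.
#' @export
region_genome_fractions <- function(index) {
  if (!inherits(index, "region_partition"))
    .stopf("index must be a region_partition")
  total <- sum(index$genome_sizes)
  vapply(index$labels,
         function(gr) sum(as.numeric(GenomicRanges::width(gr))) / total,
         numeric(1))
}
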