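# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.assert_reads <- function(reads) {
  need <- c("chrom", "pos5", "strand")
  if (!is.data.frame(reads) || !all(need %in% names(reads)))
    .stopf("reads must be a data.frame with columns %s", paste(need, collapse = ", "))
  if (any(reads$pos5 < 0)) .stopf("read pos5 must be >= 0")
  invisible(reads)
}

.assert_genes <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "start", "end", "exon_starts", "exon_ends")
  if (!is.data.frame(genes) || !all(need %in% names(genes)))
    .stopf("genes must be a gene-model data.frame (see read_gene_table); missing columns")
  if (anyDuplicated(genes$gene_id)) .stopf("duplicated gene_id in gene table")
  invisible(genes)
}

# tss/tes by strand rule in 0-based half-open coordinates
.gene_tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end - 1L)
.gene_tes <- function(genes) ifelse(genes$strand == "+", genes$end - 1L, genes$start)

# GRanges from 0-based half-open triples
.gr0 <- function(chrom, start0, end0, genome_sizes = NULL, ...) {
  keep <- end0 > start0
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[keep],
    ranges = IRanges::IRanges(start = start0[keep] + 1L, end = end0[keep]),
    ...
  )
  if (!is.null(genome_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(genome_sizes)
    GenomeInfoDb::seqlengths(gr) <- unname(genome_sizes)
  }
  gr
}

# point GRanges at read 5' positions (width 1)
.read_points <- function(reads, genome_sizes = NULL) {
  .gr0(reads$chrom, reads$pos5, reads$pos5 + 1L, genome_sizes = genome_sizes)
}

.set_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max,
           kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

.md5_file <- function(path) unname(tools::md5sum(path))
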