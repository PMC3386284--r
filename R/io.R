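#' Read aligned ChIP reads from a BED file
#'
#' Reads BED3/BED6 into a read table. Each record becomes a point event at its
#' 5' end: \code{pos5 = start} on the plus strand, \code{end - 1} on the minus
#' strand (0-based). BED3 records (no strand column) default to the plus
#' strand with a single warning. Records with \code{start >= end} are rejected;
#' the number rejected is attached as attribute \code{n_rejected}.
#'
#' @param path path to a BED file (tab-separated, no header; \code{track},
#'   \code{browser} and \code{#} lines are skipped).
#' @param read_length if non-NULL, overrides the per-record length
#'   (\code{end - start}) recorded as metadata. Lengths never affect counting,
#'   which is always at the 5' point.
#' @return data.frame with columns \code{chrom}, \code{pos5}, \code{strand},
#'   \code{length}, one row per retained record.
#' @seealso [write_bed_reads()], [write_graph_track()]
#' @export
read_bed_reads <- function(path, read_length = NULL) {
  lines <- readLines(path)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(lines)
  idx <- which(!skip)
  if (length(idx) == 0L) {
    out <- data.frame(chrom = character(), pos5 = integer(),
                      strand = character(), length = integer())
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    .stopf("malformed BED line %d: fewer than 3 fields", idx[which(nf < 3L)[1L]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    .stopf("malformed BED line %d: non-numeric coordinates", idx[which(bad)[1L]])
  strand <- rep(NA_character_, length(idx))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  unknown <- is.na(strand) | !(strand %in% c("+", "-"))
  if (any(unknown)) {
    .warnf("%d record(s) without usable strand; defaulting to '+'", sum(unknown))
    strand[unknown] <- "+"
  }
  reject <- start >= end
  if (any(reject))
    .warnf("%d BED record(s) with start >= end rejected", sum(reject))
  keep <- !reject
  len <- end[keep] - start[keep]
  if (!is.null(read_length)) len <- rep(as.integer(read_length), sum(keep))
  out <- data.frame(
    chrom = chrom[keep],
    pos5 = ifelse(strand[keep] == "+", start[keep], end[keep] - 1L),
    strand = strand[keep],
    length = len
  )
  attr(out, "n_rejected") <- sum(reject)
  out
}

#' Write reads back to BED6
#'
#' Inverse of [read_bed_reads()]: the 5' point and length reconstruct the
#' original interval (\code{[pos5, pos5+length)} on plus,
#' \code{[pos5-length+1, pos5+1)} on minus).
#'
#' @param reads read table as returned by [read_bed_reads()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed_reads <- function(reads, path) {
  .assert_reads(reads)
  len <- reads$length %||% 49L
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$pos5, reads$pos5 - len + 1L)
  end <- start + len
  df <- data.frame(reads$chrom, start, end, ".", 0L, reads$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genePred-style gene table
#'
#' Expects a tab-separated file with header columns \code{gene_id}, \code{chrom},
#' \code{strand}, \code{txStart}, \code{txEnd}, \code{exonStarts},
#' \code{exonEnds}; coordinates 0-based half-open, exon lists comma-separated
#' (a trailing comma is tolerated). The TSS is \code{txStart} on the plus
#' strand and \code{txEnd - 1} on the minus strand; the TES is the opposite end.
#'
#' @param path path to the gene table.
#' @return data.frame with columns \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end}, list columns \code{exon_starts}/\code{exon_ends},
#'   and derived \code{tss}/\code{tes}.
#' @export
read_gene_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", colClasses = "character")
  need <- c("gene_id", "chrom", "strand", "txStart", "txEnd",
            "exonStarts", "exonEnds")
  if (!all(need %in% names(tab)))
    .stopf("gene table missing column(s): %s",
           paste(setdiff(need, names(tab)), collapse = ", "))
  parse_list <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                   function(v) as.integer(v[nzchar(v)]))
  es <- parse_list(tab$exonStarts)
  ee <- parse_list(tab$exonEnds)
  start <- as.integer(tab$txStart)
  end <- as.integer(tab$txEnd)
  for (i in seq_len(nrow(tab))) {
    if (length(es[[i]]) != length(ee[[i]]))
      .stopf("gene table row %d (%s): exonStarts/exonEnds arity mismatch",
             i, tab$gene_id[i])
    if (length(es[[i]]) < 1L)
      .stopf("gene table row %d (%s): no exons", i, tab$gene_id[i])
    if (!tab$strand[i] %in% c("+", "-"))
      .stopf("gene table row %d (%s): strand must be + or -", i, tab$gene_id[i])
    if (is.na(start[i]) || is.na(end[i]) || start[i] >= end[i])
      .stopf("gene table row %d (%s): invalid span", i, tab$gene_id[i])
    s <- es[[i]]; e <- ee[[i]]
    if (any(e <= s) || is.unsorted(s, strictly = TRUE) ||
        (length(s) > 1L && any(s[-1L] < e[-length(e)])))
      .stopf("gene table row %d (%s): exons must be sorted and non-overlapping",
             i, tab$gene_id[i])
    if (s[1L] < start[i] || e[length(e)] > end[i])
      .stopf("gene table row %d (%s): exon outside gene span", i, tab$gene_id[i])
  }
  genes <- data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                      strand = tab$strand, start = start, end = end)
  genes$exon_starts <- es
  genes$exon_ends <- ee
  genes$tss <- .gene_tss(genes)
  genes$tes <- .gene_tes(genes)
  genes
}

#' Write a gene table in the genePred-style dialect read by [read_gene_table()]
#' @param genes gene-model data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  .assert_genes(genes)
  df <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    txStart = genes$start, txEnd = genes$end,
    exonStarts = vapply(genes$exon_starts, paste, "", collapse = ","),
    exonEnds = vapply(genes$exon_ends, paste, "", collapse = ",")
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MACS 1.4 peak table (.xls dialect)
#'
#' Parses the tab-separated peak table MACS 1.4 writes (header lines starting
#' with \code{#}, then a column-name row: chr, start, end, length, summit,
#' tags, -10*log10(pvalue), fold_enrichment and optionally FDR(\%)). MACS
#' coordinates are 1-based inclusive and are converted to the package's
#' 0-based half-open convention (\code{start0 = start - 1}, \code{end0 = end});
#' the summit (a 1-based offset from the peak start) is stored as an absolute
#' 0-based position. Records with non-positive fold enrichment are rejected and
#' tallied in attribute \code{n_rejected}. A header-only file yields an empty
#' table.
#'
#' @param path path to the peak table.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{summit}, \code{neg_log10_pvalue}, \code{fold_enrichment} (and
#'   \code{fdr_pct} when present).
#' @export
read_macs_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), neg_log10_pvalue = numeric(),
                      fold_enrichment = numeric())
  if (length(lines) <= 1L) {
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(rows) != length(header)))
    .stopf("MACS table line %d: field count differs from header",
           which(lengths(rows) != length(header))[1L] + 1L)
  col <- function(name, alt = NULL) {
    j <- which(header %in% c(name, alt))
    if (length(j) == 0L) .stopf("MACS table missing column '%s'", name)
    vapply(rows, `[[`, "", j[1L])
  }
  start1 <- as.integer(col("start"))
  end1 <- as.integer(col("end"))
  len <- as.integer(col("length"))
  summit_off <- as.integer(col("summit"))
  if (any(len != end1 - start1 + 1L, na.rm = TRUE))
    .warnf("%d peak(s) with length column inconsistent with end-start+1",
           sum(len != end1 - start1 + 1L, na.rm = TRUE))
  fe <- as.numeric(col("fold_enrichment"))
  out <- data.frame(
    chrom = col("chr", alt = "chrom"),
    start = start1 - 1L,
    end = end1,
    summit = (start1 - 1L) + summit_off - 1L,
    neg_log10_pvalue = as.numeric(col("-10*log10(pvalue)")) / 10,
    fold_enrichment = fe
  )
  if (any(header == "FDR(%)")) out$fdr_pct <- as.numeric(col("FDR(%)"))
  bad <- !(fe > 0) | out$summit < out$start | out$summit >= out$end
  if (any(bad))
    .warnf("%d peak record(s) violating invariants rejected", sum(bad))
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write peaks in the MACS 1.4 table dialect
#' @param peaks peak data.frame in internal 0-based half-open coordinates.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_macs_peaks <- function(peaks, path) {
  df <- data.frame(
    chr = peaks$chrom,
    start = peaks$start + 1L,
    end = peaks$end,
    length = peaks$end - peaks$start,
    summit = peaks$summit - peaks$start + 1L,
    tags = peaks$tags %||% 0L,
    check.names = FALSE
  )
  df[["-10*log10(pvalue)"]] <- round(10 * peaks$neg_log10_pvalue, 2)
  df$fold_enrichment <- peaks$fold_enrichment
  if (!is.null(peaks$fdr_pct)) df[["FDR(%)"]] <- peaks$fdr_pct
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# synthetic peak table in MACS 1.4 dialect", con)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summarise reads into non-overlapping fixed-width windows
#'
#' Counts read 5' positions into non-overlapping \code{window}-bp windows
#' (genome browser "graph" track). Windows with zero reads are omitted, so the
#' total of \code{count} always equals the number of reads.
#'
#' @param reads read table.
#' @param window window width in bp (>= 1).
#' @param path optional path; when given the table is also written as TSV.
#' @return data.frame with columns \code{chrom}, \code{window_start},
#'   \code{count}, ordered by chromosome and position.
#' @export
write_graph_track <- function(reads, window = 50L, path = NULL) {
  .assert_reads(reads)
  window <- as.integer(window)
  if (window < 1L) .stopf("window must be >= 1")
  if (nrow(reads) == 0L) {
    out <- data.frame(chrom = character(), window_start = integer(),
                      count = integer())
  } else {
    ws <- (reads$pos5 %/% window) * window
    key <- paste(reads$chrom, ws, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(
      chrom = vapply(parts, `[[`, "", 1L),
      window_start = as.integer(vapply(parts, `[[`, "", 2L)),
      count = as.integer(tab)
    )
    out <- out[order(out$chrom, out$window_start), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Read transcript sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} returning a named
#' character vector (names truncated at the first whitespace).
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_transcript_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read / write a per-gene tag-count table
#'
#' TSV with header \code{gene_id}, \code{count} and optionally \code{tpm}.
#' @param path file path.
#' @return data.frame.
#' @export
read_count_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "")
  if (!all(c("gene_id", "count") %in% names(tab)))
    .stopf("count table must have columns gene_id, count")
  tab
}

#' @rdname read_count_table
#' @param counts data.frame with \code{gene_id}, \code{count} (and extras).
#' @export
write_count_table <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR crossing-point (Cp) table
#'
#' TSV with header columns \code{sample_id}, \code{primer_site},
#' \code{template} (\code{chip} or \code{input}), \code{cp} and optionally
#' \code{input_ng} (template mass for standard curves). Cp values must be
#' positive.
#' @param path file path.
#' @return data.frame of Cp records.
#' @export
read_cp_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "")
  need <- c("sample_id", "primer_site", "template", "cp")
  if (!all(need %in% names(tab)))
    .stopf("Cp table missing column(s): %s",
           paste(setdiff(need, names(tab)), collapse = ", "))
  if (!all(tab$template %in% c("chip", "input")))
    .stopf("Cp table template must be 'chip' or 'input'")
  if (any(tab$cp <= 0)) .stopf("Cp values must be positive")
  tab
}
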