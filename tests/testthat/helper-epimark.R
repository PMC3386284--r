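# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive per-element algorithms, independent of the package's interval /
# sparse-matrix code paths.

mk_genes <- function(gene_id, chrom, strand, start, end,
                     exon_starts = NULL, exon_ends = NULL) {
  g <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                  start = as.integer(start), end = as.integer(end))
  g$exon_starts <- if (is.null(exon_starts)) as.list(g$start) else exon_starts
  g$exon_ends <- if (is.null(exon_ends)) as.list(g$end) else exon_ends
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g$tes <- ifelse(g$strand == "+", g$end - 1L, g$start)
  g
}

mk_reads <- function(chrom, pos5, strand = "+", length = 49L) {
  data.frame(chrom = chrom, pos5 = as.integer(pos5),
             strand = rep(strand, length.out = length(chrom)),
             length = rep(as.integer(length), length.out = length(chrom)))
}

# random toy genome with possibly overlapping gene neighbourhoods
random_toy <- function(seed, n_genes = 10, chrom_len = 100000L, flank = 5000L) {
  set.seed(seed)
  len <- sample(2000:8000, n_genes, replace = TRUE)
  # keep flanks inside the chromosome; clipping has its own dedicated test
  start <- sample(seq(flank + 1L, chrom_len - max(len) - flank - 1L), n_genes)
  end <- start + len
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  ex <- lapply(seq_len(n_genes), function(i) {
    ne <- sample(1:3, 1)
    if (ne == 1) return(list(s = start[i], e = end[i]))
    cuts <- sort(sample(seq(start[i] + 1L, end[i] - 1L), 2L * (ne - 1L)))
    list(s = c(start[i], cuts[seq(2, length(cuts), 2)]),
         e = c(cuts[seq(1, length(cuts), 2)], end[i]))
  })
  genes <- mk_genes(sprintf("t%03d", seq_len(n_genes)), "chr1", strand,
                    start, end,
                    exon_starts = lapply(ex, `[[`, "s"),
                    exon_ends = lapply(ex, `[[`, "e"))
  list(genes = genes, genome_sizes = c(chr1 = chrom_len), flank = flank)
}

# per-bp brute-force labeler; returns list of logical vectors (1-based index
# = bp 0-based position + 1) for the four genic labels
brute_bp_labels <- function(genes, genome_sizes, flank) {
  stopifnot(length(genome_sizes) == 1L)
  len <- as.integer(genome_sizes[[1L]])
  lab <- list(up20K = logical(len), exon = logical(len),
              intron = logical(len), down20K = logical(len))
  mark <- function(v, s, e) {      # 0-based half-open
    s <- max(s, 0L); e <- min(e, len)
    if (e > s) v[(s + 1L):e] <- TRUE
    v
  }
  for (i in seq_len(nrow(genes))) {
    s <- genes$start[i]; e <- genes$end[i]
    if (genes$strand[i] == "+") {
      lab$up20K <- mark(lab$up20K, s - flank, s)
      lab$down20K <- mark(lab$down20K, e, e + flank)
    } else {
      lab$up20K <- mark(lab$up20K, e, e + flank)
      lab$down20K <- mark(lab$down20K, s - flank, s)
    }
    exv <- logical(len)
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    for (k in seq_along(es)) exv <- mark(exv, es[k], ee[k])
    body <- logical(len)
    body <- mark(body, s, e)
    lab$exon <- lab$exon | exv
    lab$intron <- lab$intron | (body & !exv)
  }
  lab
}

# exclusive per-bp labels with precedence exon > intron > up20K > down20K
brute_bp_exclusive <- function(genes, genome_sizes, flank) {
  lab <- brute_bp_labels(genes, genome_sizes, flank)
  len <- length(lab$exon)
  out <- rep("intergenic", len)
  out[lab$down20K] <- "down20K"
  out[lab$up20K] <- "up20K"
  out[lab$intron] <- "intron"
  out[lab$exon] <- "exon"
  out
}

# per-bp vector for one partition label from the package object
partition_label_bp <- function(index, label, chrom = "chr1") {
  len <- as.integer(index$genome_sizes[[chrom]])
  v <- logical(len)
  gr <- index$labels[[label]]
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  for (k in seq_along(gr)) {
    s <- GenomicRanges::start(gr)[k]; e <- GenomicRanges::end(gr)[k]
    v[s:e] <- TRUE
  }
  v
}

# brute-force oriented TSS binning over [-span, span) (or [-span, 0))
brute_tss_bins <- function(reads, genes, window, span, lo = -span, hi = span) {
  k <- (hi - lo) %/% window
  m <- matrix(0, nrow(genes), k)
  for (i in seq_len(nrow(genes))) {
    tss <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i] - 1L
    for (j in seq_len(nrow(reads))) {
      if (reads$chrom[j] != genes$chrom[i]) next
      o <- if (genes$strand[i] == "+") reads$pos5[j] - tss else tss - reads$pos5[j]
      if (o >= lo && o < hi) {
        cc <- (o - lo) %/% window + 1L
        m[i, cc] <- m[i, cc] + 1
      }
    }
  }
  m
}

# brute-force metagene binning (flank 1 kb bins + body fraction bins)
brute_metagene_bins <- function(reads, genes, body_bins = 20L, flank_kb = 20L) {
  flank <- flank_kb * 1000L
  k <- 2L * flank_kb + body_bins
  m <- matrix(0, nrow(genes), k)
  for (i in seq_len(nrow(genes))) {
    L <- genes$end[i] - genes$start[i]
    for (j in seq_len(nrow(reads))) {
      if (reads$chrom[j] != genes$chrom[i]) next
      u <- if (genes$strand[i] == "+") reads$pos5[j] - genes$start[i]
           else (genes$end[i] - 1L) - reads$pos5[j]
      if (u < -flank || u >= L + flank) next
      b <- if (u < 0) (u + flank) %/% 1000L + 1L
           else if (u < L) flank_kb + 1L + min(floor(u * body_bins / L), body_bins - 1L)
           else flank_kb + body_bins + 1L + (u - L) %/% 1000L
      m[i, b] <- m[i, b] + 1
    }
  }
  m
}

# brute-force all-pairs peak-gene association by the >= 1 bp rule
brute_associate <- function(peaks, genes, flank) {
  res <- list()
  overlap <- function(s1, e1, s2, e2) min(e1, e2) - max(s1, s2) >= 1
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    regions <- list()
    if (g$strand == "+") {
      regions$up20K <- c(g$start - flank, g$start)
      regions$down20K <- c(g$end, g$end + flank)
    } else {
      regions$up20K <- c(g$end, g$end + flank)
      regions$down20K <- c(g$start - flank, g$start)
    }
    labs <- character(0); pks <- integer(0)
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != g$chrom) next
      for (L in names(regions)) {
        if (overlap(peaks$start[j], peaks$end[j],
                    regions[[L]][1], regions[[L]][2])) {
          labs <- c(labs, L); pks <- c(pks, j)
        }
      }
      es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
      for (k in seq_along(es))
        if (overlap(peaks$start[j], peaks$end[j], es[k], ee[k])) {
          labs <- c(labs, "exon"); pks <- c(pks, j)
        }
      if (length(es) > 1)
        for (k in seq_len(length(es) - 1))
          if (overlap(peaks$start[j], peaks$end[j], ee[k], es[k + 1])) {
            labs <- c(labs, "intron"); pks <- c(pks, j)
          }
    }
    if (length(labs))
      res[[g$gene_id]] <- list(labels = intersect(c("up20K", "exon", "intron",
                                                    "down20K"), unique(labs)),
                               peak_idx = sort(unique(pks)))
  }
  res
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force tag mapping at tiers 0 then 1, unambiguous only
brute_map_tags <- function(observed, reference) {
  genes <- unique(reference$gene_id)
  counts <- setNames(integer(length(genes)), genes)
  ambiguous <- 0L; unmapped <- 0L
  for (tg in observed) {
    if (nchar(tg) != 21L || grepl("[^ACGT]", tg)) { unmapped <- unmapped + 1L; next }
    d <- vapply(reference$tag, hamming, integer(1), b = tg)
    hit <- unique(reference$gene_id[d == 0])
    if (!length(hit)) hit <- unique(reference$gene_id[d == 1])
    if (length(hit) == 1L) counts[hit] <- counts[hit] + 1L
    else if (length(hit) > 1L) ambiguous <- ambiguous + 1L
    else unmapped <- unmapped + 1L
  }
  list(counts = counts, ambiguous = ambiguous, unmapped = unmapped)
}

# brute-force two-library exact p: conditional pmf over the observed total,
# enumerated directly from the count-probability formula
brute_two_library_p <- function(x, y, nA, nB) {
  t <- x + y
  if (t == 0) return(1)
  r <- nB / nA
  lp <- lchoose(t, 0:t) + (0:t) * log(r) - t * log(1 + r)
  v <- exp(lp)
  min(1, sum(v[lp <= lp[y + 1] + 1e-9]))
}

# from-scratch Spearman-centroid agglomeration (recomputes centroids of the
# row-rank-transformed data from member lists each step); returns heights
naive_cluster_heights <- function(mat) {
  labels <- rownames(mat)
  mat <- t(apply(mat, 1, rank))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    bd <- Inf; bkey <- NULL; bi <- 0L; bj <- 0L
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq((i + 1L), length(clusters))) {
        ci <- colMeans(mat[clusters[[i]], , drop = FALSE])
        cj <- colMeans(mat[clusters[[j]], , drop = FALSE])
        d <- 1 - cor(ci, cj, method = "spearman")
        l1 <- min(labels[clusters[[i]]]); l2 <- min(labels[clusters[[j]]])
        key <- paste(min(l1, l2), max(l1, l2), sep = "\r")
        if (d < bd - 1e-12 || (abs(d - bd) <= 1e-12 && key < bkey)) {
          bd <- d; bkey <- key; bi <- i; bj <- j
        }
      }
    }
    heights <- c(heights, bd)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# brute-force scan for CATG tags, 3'-most first
brute_extract_tags <- function(tx) {
  hits <- character(0)
  for (p in seq_len(max(nchar(tx) - 20L, 0L))) {
    if (substr(tx, p, p + 3L) == "CATG")
      hits <- c(hits, substr(tx, p, p + 20L))
  }
  rev(hits)   # rank 1 = 3'-most
}
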