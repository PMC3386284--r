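# Seeded synthetic-data generators: gene models, expression, ChIP reads with
# an expression-coupled promoter enrichment geometry, and two-group designs.

#' Simulation configuration
#'
#' Bundles every generator parameter with its default study conditions.
#' The ChIP intensity model for a gene g with repression coupling r(g) is
#' \deqn{\lambda(x) = s [1 + B r(g) + A r(g) e^{-(o - c)^2 / 2\sigma_b^2}]
#'   [1 - d e^{-o^2 / 2\sigma_d^2}]}
#' over the gene neighbourhood (o = oriented offset from the TSS; the broad
#' term B spans [TSS - flank, TES + flank]) and \eqn{\lambda = s} elsewhere;
#' s is set so the expected read total equals \code{depth}. The coupling
#' r(g) is rank-based on expression with all zero-TPM genes sharing the
#' maximum r = 1, so silent genes carry the strongest promoter mark.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_genes,n_chroms genome layout; genes are packed so that their
#'   \code{flank}-bp neighbourhoods never overlap.
#' @param gene_length_range min/max gene length in bp.
#' @param chrom_length per-chromosome length in bp; \code{NULL} (default)
#'   sizes chromosomes automatically to fit the genes.
#' @param flank neighbourhood flank in bp (default 20000).
#' @param fraction_silent fraction of genes with zero expression
#'   (default 0.3).
#' @param mu_log,sigma_log log-normal parameters (natural log scale) for
#'   the expressed genes' TPM weights (defaults 4 and 1.5).
#' @param depth expected number of ChIP reads per sample (default 2e6).
#' @param tag_depth DGE tags per sample (default 1e6).
#' @param read_length nominal ChIP read length in bp (default 49; metadata).
#' @param bump_amp,bump_center,bump_sigma promoter bump: amplitude A
#'   (default 20), oriented centre in bp (default -2000) and width in bp
#'   (default 800).
#' @param broad_amp amplitude B of the broad neighbourhood enrichment
#'   (default 6); models the domain-like elevation of a repressive mark over
#'   the whole silenced locus.
#' @param dip_depth,dip_sigma TSS dip depth d in [0,1) (default 0.8) and
#'   width in bp (default 150).
#' @param n_samples samples per condition for single-group generators
#'   (default 1).
#' @param n_affected,expr_log2fc,mark_fold two-group design: number of
#'   affected genes (default 40), their expression knock-down in log2 units
#'   (default 2) and the mark amplification over \code{boost_window}
#'   (default 2).
#' @param boost_window oriented offset interval (bp, left-closed) carrying
#'   the mark amplification (default c(-2000, -1000)).
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_genes = 2000L, n_chroms = 2L,
                       gene_length_range = c(2000L, 10000L),
                       chrom_length = NULL, flank = 20000L,
                       fraction_silent = 0.3, mu_log = 4, sigma_log = 1.5,
                       depth = 2e6, tag_depth = 1e6, read_length = 49L,
                       bump_amp = 20, bump_center = -2000L, bump_sigma = 800,
                       broad_amp = 6, dip_depth = 0.8, dip_sigma = 150,
                       n_samples = 1L, n_affected = 40L, expr_log2fc = 2,
                       mark_fold = 2, boost_window = c(-2000L, -1000L)) {
  cfg <- as.list(environment())
  if (cfg$fraction_silent < 0 || cfg$fraction_silent >= 1)
    .stopf("fraction_silent must lie in [0, 1)")
  if (cfg$dip_depth < 0 || cfg$dip_depth >= 1)
    .stopf("dip_depth must lie in [0, 1)")
  if (any(c(cfg$depth, cfg$tag_depth, cfg$bump_amp, cfg$broad_amp,
            cfg$bump_sigma, cfg$dip_sigma) < 0))
    .stopf("rates and amplitudes must be >= 0")
  if (cfg$gene_length_range[1L] < 100L)
    .stopf("genes shorter than 100 bp are not supported")
  structure(cfg, class = "sim_config")
}

.as_sim_config <- function(config) {
  if (inherits(config, "sim_config")) return(config)
  do.call(sim_config, config)
}

#' Simulate gene models on an artificial genome
#'
#' Places \code{n_genes} genes across \code{n_chroms} chromosomes with
#' alternating strands, uniform lengths in \code{gene_length_range} and 1-5
#' exons each (first exon starts at the gene start, last ends at the gene
#' end). Genes are laid out in fixed slots with seeded jitter so that the
#' \code{flank}-bp neighbourhoods of adjacent genes never overlap and every
#' neighbourhood lies fully inside its chromosome. Fully deterministic for a
#' given config.
#'
#' @param config a \code{sim_config} (or plain list of its fields).
#' @return list with \code{genes} (gene-model data.frame) and
#'   \code{genome_sizes} (named vector).
#' @export
simulate_gene_models <- function(config = sim_config()) {
  cfg <- .as_sim_config(config)
  .set_seed(cfg$seed + 11L)
  spacing <- 2000L
  slot <- cfg$gene_length_range[2L] + 2L * cfg$flank + spacing
  per_chrom <- rep(cfg$n_genes %/% cfg$n_chroms, cfg$n_chroms)
  extra <- cfg$n_genes - sum(per_chrom)
  if (extra > 0L) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  need <- max(per_chrom) * slot + cfg$flank + spacing
  if (is.null(cfg$chrom_length)) {
    chrom_length <- need
  } else {
    chrom_length <- cfg$chrom_length
    if (chrom_length < need)
      .stopf("chrom_length %d too small: packing %d genes needs >= %d bp",
             chrom_length, max(per_chrom), need)
  }
  genome_sizes <- setNames(rep(as.numeric(chrom_length), cfg$n_chroms),
                           paste0("chr", seq_len(cfg$n_chroms)))
  rows <- list()
  gid <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    nc <- per_chrom[ci]
    if (nc == 0L) next
    len <- sample.int(diff(cfg$gene_length_range) + 1L, nc, replace = TRUE) +
      cfg$gene_length_range[1L] - 1L
    jitter <- sample.int(spacing, nc, replace = TRUE) - 1L
    start <- cfg$flank + spacing + (seq_len(nc) - 1L) * slot + jitter
    end <- start + len
    strand <- rep(c("+", "-"), length.out = nc)
    ex <- lapply(seq_len(nc), function(i) {
      ne <- sample.int(5L, 1L)
      if (ne == 1L) return(list(s = start[i], e = end[i]))
      cuts <- sort(sample(seq(start[i] + 1L, end[i] - 1L), 2L * (ne - 1L)))
      list(s = c(start[i], cuts[seq(2L, length(cuts), by = 2L)]),
           e = c(cuts[seq(1L, length(cuts), by = 2L)], end[i]))
    })
    ids <- sprintf("g%05d", gid + seq_len(nc))
    gid <- gid + nc
    df <- data.frame(gene_id = ids, chrom = names(genome_sizes)[ci],
                     strand = strand, start = start, end = end)
    df$exon_starts <- lapply(ex, `[[`, "s")
    df$exon_ends <- lapply(ex, `[[`, "e")
    rows[[ci]] <- df
  }
  genes <- do.call(rbind, rows)
  genes$tss <- .gene_tss(genes)
  genes$tes <- .gene_tes(genes)
  rownames(genes) <- NULL
  list(genes = genes, genome_sizes = genome_sizes)
}

#' Simulate per-gene expression and DGE tag counts
#'
#' Draws the truth TPM profile (a seeded fraction of silent genes; expressed
#' genes' TPM proportional to log-normal weights, normalised to one million)
#' and, per sample, multinomial tag counts at \code{tag_depth}.
#'
#' @param genes gene-model data.frame.
#' @param config a \code{sim_config}.
#' @param n_samples number of samples (defaults to \code{config$n_samples}).
#' @param seed base seed (defaults to \code{config$seed}).
#' @return list with \code{tpm} (named truth vector summing to 1e6),
#'   \code{counts} (genes x samples integer matrix) and \code{tag_depth}.
#' @export
simulate_expression <- function(genes, config = sim_config(),
                                n_samples = NULL, seed = NULL) {
  cfg <- .as_sim_config(config)
  n_samples <- n_samples %||% cfg$n_samples
  seed <- seed %||% cfg$seed
  n <- nrow(genes)
  .set_seed(seed + 23L)
  n_silent <- round(cfg$fraction_silent * n)
  silent <- sample.int(n, n_silent)
  tpm <- setNames(numeric(n), genes$gene_id)
  expressed <- setdiff(seq_len(n), silent)
  w <- rlnorm(length(expressed), cfg$mu_log, cfg$sigma_log)
  tpm[expressed] <- w / sum(w) * 1e6
  counts <- matrix(0L, n, n_samples)
  rownames(counts) <- genes$gene_id
  if (n_samples > 0L) colnames(counts) <- paste0("s", seq_len(n_samples))
  for (s in seq_len(n_samples)) {
    .set_seed(seed + 100L + s)
    counts[, s] <- rmultinom(1L, cfg$tag_depth, tpm / 1e6)[, 1L]
  }
  list(tpm = tpm, counts = counts, tag_depth = cfg$tag_depth)
}

# rank-based repression coupling: all zero-TPM genes share r = 1, the most
# expressed gene gets r ~ 0
.repression_coupling <- function(tpm) {
  n <- length(tpm)
  r <- 1 - (rank(tpm, ties.method = "min") - 1) / (n - 1)
  setNames(r, names(tpm))
}

#' Simulate ChIP reads with expression-coupled promoter enrichment
#'
#' Draws approximately \code{depth} reads (Poisson) from the intensity model
#' described in [sim_config()]: uniform genomic background, a broad
#' neighbourhood elevation and a Gaussian promoter bump (both scaled by the
#' repression coupling r(g) derived from \code{truth_tpm}), and a Gaussian
#' occupancy dip at each TSS applied by thinning. An optional \code{boost}
#' multiplies the intensity over the oriented \code{boost_window} of selected
#' genes (used by the two-group design to plant a localized differential
#' mark).
#'
#' @param genes gene-model data.frame.
#' @param truth_tpm named truth TPM vector (defines the coupling).
#' @param config a \code{sim_config}.
#' @param seed seed (defaults to \code{config$seed}).
#' @param boost optional data.frame with columns \code{gene_id},
#'   \code{fold}.
#' @return list with \code{reads} (read table sorted by position),
#'   \code{truth} (per-gene coupling and relative component masses) and
#'   \code{genome_sizes}.
#' @export
simulate_chip_reads <- function(genes, truth_tpm, config = sim_config(),
                                seed = NULL, boost = NULL) {
  cfg <- .as_sim_config(config)
  seed <- seed %||% cfg$seed
  gm_sizes <- attr(genes, "genome_sizes")
  chroms <- unique(genes$chrom)
  # chromosome sizes: from attribute when present, else auto from extents
  if (is.null(gm_sizes)) {
    gm_sizes <- vapply(chroms, function(cc)
      max(genes$end[genes$chrom == cc]) + cfg$flank + 2000, numeric(1))
  }
  r <- .repression_coupling(truth_tpm[genes$gene_id])
  plus <- genes$strand == "+"
  tss <- .gene_tss(genes)
  len_chr <- gm_sizes[genes$chrom]
  ws <- pmax(genes$start - cfg$flank, 0)
  we <- pmin(genes$end + cfg$flank, len_chr)
  n <- nrow(genes)

  bump_center_genome <- ifelse(plus, tss + cfg$bump_center,
                               tss - cfg$bump_center)
  mass_bg <- unname(gm_sizes[chroms])
  mass_broad <- cfg$broad_amp * r * (we - ws)
  mass_bump <- cfg$bump_amp * r * cfg$bump_sigma * sqrt(2 * pi)

  boost_idx <- integer(0)
  boost_fold <- numeric(0)
  boost_grid <- list()
  mass_boost <- numeric(0)
  if (!is.null(boost) && nrow(boost)) {
    boost_idx <- match(boost$gene_id, genes$gene_id)
    if (anyNA(boost_idx)) .stopf("boost gene(s) not in gene table")
    boost_fold <- boost$fold
    w0 <- cfg$boost_window[1L]; w1 <- cfg$boost_window[2L]
    boost_grid <- lapply(seq_along(boost_idx), function(k) {
      g <- boost_idx[k]
      o <- seq(w0, w1 - 1L)                      # oriented offsets
      x <- if (plus[g]) tss[g] + o else tss[g] - o
      lam <- 1 + cfg$broad_amp * r[g] +
        cfg$bump_amp * r[g] *
        exp(-(o - cfg$bump_center)^2 / (2 * cfg$bump_sigma^2))
      list(x = x, lam = lam)
    })
    mass_boost <- vapply(seq_along(boost_idx), function(k)
      (boost_fold[k] - 1) * sum(boost_grid[[k]]$lam), numeric(1))
  }

  masses <- c(mass_bg, mass_broad, mass_bump, mass_boost)
  total <- sum(masses)
  .set_seed(seed + 37L)
  N <- rpois(1L, cfg$depth)
  comp <- sample.int(length(masses), N, replace = TRUE, prob = masses)
  counts <- tabulate(comp, nbins = length(masses))
  nchr <- length(chroms)

  pos <- numeric(0); chr <- character(0)
  # background, uniform per chromosome
  for (ci in seq_len(nchr)) {
    k <- counts[ci]
    if (k == 0L) next
    pos <- c(pos, floor(runif(k) * gm_sizes[chroms[ci]]))
    chr <- c(chr, rep(chroms[ci], k))
  }
  # broad neighbourhood component, uniform over [ws, we)
  cb <- counts[nchr + seq_len(n)]
  if (sum(cb)) {
    g <- rep.int(seq_len(n), cb)
    pos <- c(pos, floor(runif(sum(cb)) * (we[g] - ws[g])) + ws[g])
    chr <- c(chr, genes$chrom[g])
  }
  # promoter bump, Gaussian around the oriented centre
  cp <- counts[nchr + n + seq_len(n)]
  if (sum(cp)) {
    g <- rep.int(seq_len(n), cp)
    p <- round(rnorm(sum(cp), bump_center_genome[g], cfg$bump_sigma))
    p <- pmin(pmax(p, 0), len_chr[g] - 1)
    pos <- c(pos, p)
    chr <- c(chr, genes$chrom[g])
  }
  # localized boost
  if (length(boost_idx)) {
    cboost <- counts[nchr + 2L * n + seq_along(boost_idx)]
    for (k in seq_along(boost_idx)) {
      if (cboost[k] == 0L) next
      gr <- boost_grid[[k]]
      pos <- c(pos, sample(gr$x, cboost[k], replace = TRUE, prob = gr$lam))
      chr <- c(chr, rep(genes$chrom[boost_idx[k]], cboost[k]))
    }
  }

  # TSS occupancy dip by thinning
  keep <- rep(TRUE, length(pos))
  horizon <- 5 * cfg$dip_sigma
  if (cfg$dip_depth > 0) {
    for (cc in chroms) {
      sel <- which(chr == cc)
      if (!length(sel)) next
      tss_c <- sort(tss[genes$chrom == cc])
      idx <- findInterval(pos[sel], tss_c)
      d_lo <- ifelse(idx >= 1L, pos[sel] - tss_c[pmax(idx, 1L)], Inf)
      d_hi <- ifelse(idx < length(tss_c),
                     tss_c[pmin(idx + 1L, length(tss_c))] - pos[sel], Inf)
      dist <- pmin(abs(d_lo), abs(d_hi))
      pdip <- ifelse(dist < horizon,
                     cfg$dip_depth * exp(-dist^2 / (2 * cfg$dip_sigma^2)), 0)
      keep[sel] <- runif(length(sel)) >= pdip
    }
  }
  strand <- sample(c("+", "-"), length(pos), replace = TRUE)
  reads <- data.frame(chrom = chr, pos5 = as.integer(pos), strand = strand,
                      length = cfg$read_length)[keep, , drop = FALSE]
  reads <- reads[order(reads$chrom, reads$pos5, method = "radix"), ,
                 drop = FALSE]
  rownames(reads) <- NULL
  truth <- data.frame(gene_id = genes$gene_id, r = as.numeric(r),
                      broad_mass = as.numeric(mass_broad),
                      bump_mass = as.numeric(mass_bump))
  list(reads = reads, truth = truth, genome_sizes = gm_sizes)
}

#' Simulate a two-group (parity-style) study
#'
#' Generates one genome, a baseline expression profile, and per group
#' (\code{A} = reference, \code{B} = affected) two DGE tag libraries and two
#' ChIP read samples. In group B, \code{n_affected} expressed genes have
#' their TPM divided by \code{2^expr_log2fc} (then renormalised) and their
#' ChIP intensity multiplied by \code{mark_fold} over the oriented
#' \code{boost_window} only. Both groups share the baseline repression
#' coupling (from the reference expression), so the planted differential
#' mark is confined to the boost window.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{genes}, \code{genome_sizes}, per-group \code{tpm},
#'   \code{counts} (matrices genes x 2), \code{reads} (lists of 2 read
#'   tables), \code{affected} gene ids, and the \code{config}.
#' @export
simulate_two_group_study <- function(config = sim_config()) {
  cfg <- .as_sim_config(config)
  gm <- simulate_gene_models(cfg)
  genes <- gm$genes
  attr(genes, "genome_sizes") <- gm$genome_sizes
  expr <- simulate_expression(genes, cfg, n_samples = 0L)
  tpm_a <- expr$tpm
  expressed <- names(tpm_a)[tpm_a > 0]
  if (cfg$n_affected > length(expressed))
    .stopf("n_affected (%d) exceeds expressed genes (%d)",
           cfg$n_affected, length(expressed))
  .set_seed(cfg$seed + 7L)
  affected <- sort(sample(expressed, cfg$n_affected))
  tpm_b <- tpm_a
  tpm_b[affected] <- tpm_b[affected] * 2^(-cfg$expr_log2fc)
  tpm_b <- tpm_b / sum(tpm_b) * 1e6

  draw_counts <- function(tpm, gseed) {
    m <- matrix(0L, nrow(genes), 2L,
                dimnames = list(genes$gene_id, paste0("s", 1:2)))
    for (s in 1:2) {
      .set_seed(gseed + s)
      m[, s] <- rmultinom(1L, cfg$tag_depth, tpm / 1e6)[, 1L]
    }
    m
  }
  counts_a <- draw_counts(tpm_a, cfg$seed + 110L)
  counts_b <- draw_counts(tpm_b, cfg$seed + 120L)

  boost <- if (cfg$mark_fold != 1)
    data.frame(gene_id = affected, fold = cfg$mark_fold) else NULL
  reads_a <- lapply(1:2, function(s)
    simulate_chip_reads(genes, tpm_a, cfg, seed = cfg$seed + 510L + s)$reads)
  reads_b <- lapply(1:2, function(s)
    simulate_chip_reads(genes, tpm_a, cfg, seed = cfg$seed + 520L + s,
                        boost = boost)$reads)
  list(genes = genes, genome_sizes = gm$genome_sizes,
       tpm = list(A = tpm_a, B = tpm_b),
       counts = list(A = counts_a, B = counts_b),
       tag_depth = cfg$tag_depth,
       reads = list(A = reads_a, B = reads_b),
       affected = affected, config = cfg)
}

#' Synthetic MACS-style peak table from simulation truth
#'
#' Plumbing for exercising the peak ingestion and association stages on
#' simulated data: emits one synthetic peak per selected gene, a 3 kb
#' interval centred on the planted promoter bump, with summary fields
#' derived deterministically from the coupling. Not a peak caller.
#'
#' @param genes gene-model data.frame.
#' @param truth per-gene truth (from [simulate_chip_reads()]).
#' @param config a \code{sim_config}.
#' @param top_n number of most-coupled genes to emit peaks for (default 50).
#' @return peak data.frame in internal coordinates, writable with
#'   [write_macs_peaks()].
#' @export
simulate_peak_table <- function(genes, truth, config = sim_config(),
                                top_n = 50L) {
  cfg <- .as_sim_config(config)
  ord <- order(-truth$r, truth$gene_id, method = "radix")
  pick <- head(ord, top_n)
  plus <- genes$strand == "+"
  tss <- .gene_tss(genes)
  center <- ifelse(plus, tss + cfg$bump_center, tss - cfg$bump_center)
  half <- 1500L
  out <- data.frame(
    chrom = genes$chrom[pick],
    start = pmax(center[pick] - half, 0),
    end = center[pick] + half,
    summit = center[pick],
    neg_log10_pvalue = 5 + 50 * truth$r[pick],
    fold_enrichment = 1 + cfg$bump_amp * truth$r[pick],
    gene_id = genes$gene_id[pick]
  )
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
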