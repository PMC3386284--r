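# Per-window promoter differential modification testing between two groups.

#' Pooled per-gene promoter window densities for one group
#'
#' For each sample, builds the promoter window matrix (see
#' [promoter_window_densities()]), converts counts to densities (tags per bp),
#' optionally scales each sample to reads-per-million library size, and
#' averages across the group's samples, yielding one genes x windows density
#' matrix per group.
#'
#' @param reads_list list of read tables (one per sample in the group).
#' @param genes gene-model data.frame.
#' @param gene_set character vector of gene ids to keep (rows).
#' @param window,span window geometry in bp (defaults 500 / 5000).
#' @param per_million scale each sample to reads per million (default TRUE;
#'   groups sequenced at different depths stay comparable).
#' @param genome_sizes optional chromosome lengths for edge flagging.
#' @return numeric matrix genes x windows (column names = oriented window
#'   start offsets).
#' @export
pooled_promoter_densities <- function(reads_list, genes, gene_set,
                                      window = 500L, span = 5000L,
                                      per_million = TRUE, genome_sizes = NULL) {
  if (!length(reads_list)) .stopf("empty reads_list")
  keep <- genes$gene_id %in% gene_set
  if (!any(keep)) .stopf("gene_set not present in genes")
  genes <- genes[keep, , drop = FALSE]
  mats <- lapply(reads_list, function(rd) {
    pm <- promoter_window_densities(rd, genes, window = window, span = span,
                                    genome_sizes = genome_sizes)
    dens <- sweep(pm$counts, 2L, pm$bp_per_window, `/`)
    if (per_million) dens <- dens * 1e6 / nrow(rd)
    dens
  })
  out <- Reduce(`+`, mats) / length(mats)
  colnames(out) <- as.character(seq(-span, -window, by = window))
  out
}

#' Compare promoter windows between two groups of samples
#'
#' For each promoter window, a Welch two-sample t-test between the two
#' groups' per-gene density values (the unit of replication is the gene).
#' Raw two-sided p-values are reported by default (BH adjustment available);
#' a window is flagged when its (adjusted) p-value is below \code{alpha}.
#' Windows with zero variance in both groups are reported with t = 0, p = 1
#' and marked degenerate.
#'
#' @param densitiesA,densitiesB numeric matrices genes x windows with the
#'   same dimensions and window columns (see
#'   [pooled_promoter_densities()]); at least 3 genes each.
#' @param alpha flagging threshold (default 0.05).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame with one row per window: \code{window_start},
#'   \code{window_end}, group means, \code{t_statistic}, \code{p_value}
#'   (and \code{fdr} when adjusted), \code{flagged}, \code{degenerate}.
#' @export
compare_promoter_windows <- function(densitiesA, densitiesB, alpha = 0.05,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (ncol(densitiesA) != ncol(densitiesB))
    .stopf("groups must share the window geometry")
  if (nrow(densitiesA) < 3L || nrow(densitiesB) < 3L)
    .stopf("need at least 3 genes per group")
  w <- ncol(densitiesA)
  offs <- suppressWarnings(as.integer(colnames(densitiesA)))
  if (anyNA(offs)) offs <- seq_len(w)
  width <- if (w > 1L) offs[2L] - offs[1L] else NA_integer_
  res <- lapply(seq_len(w), function(j) {
    a <- densitiesA[, j]; b <- densitiesB[, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    degenerate <- (length(unique(a)) <= 1L && length(unique(b)) <= 1L)
    tp <- tryCatch({
      ht <- t.test(a, b)            # Welch by default
      c(ht$statistic, ht$p.value)
    }, error = function(e) c(0, 1))
    if (degenerate) tp <- c(0, 1)
    data.frame(window_start = offs[j], window_end = offs[j] + width,
               mean_a = mean(a), mean_b = mean(b),
               t_statistic = unname(tp[1L]), p_value = unname(tp[2L]),
               degenerate = degenerate)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") {
    out$fdr <- p.adjust(out$p_value, method = "BH")
    out$flagged <- out$fdr < alpha
  } else {
    out$flagged <- out$p_value < alpha
  }
  out
}
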