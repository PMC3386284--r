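# Integration of mark profiles with expression: stratified curves,
# concordance calls, Spearman-centroid hierarchical clustering.

#' Aggregate profile curves per expression stratum
#'
#' Builds one profile matrix over all genes and returns one aggregate density
#' curve per stratum (see [aggregate_density()]). Strata must be disjoint,
#' non-empty gene sets.
#'
#' @param reads read table.
#' @param genes gene-model data.frame.
#' @param strata named list of disjoint gene-id vectors (e.g. from
#'   [stratify_by_expression()]).
#' @param geometry \code{"tss"}, \code{"metagene"} or \code{"promoter"}.
#' @param ... passed to the profiling function for the chosen geometry.
#' @return named list of aggregate density curves (one numeric vector per
#'   stratum), with the shared \code{offsets} attached as an attribute.
#' @export
stratified_profiles <- function(reads, genes, strata,
                                geometry = c("tss", "metagene", "promoter"),
                                ...) {
  geometry <- match.arg(geometry)
  if (length(strata) == 0L || is.null(names(strata)))
    .stopf("strata must be a named list")
  if (any(lengths(strata) == 0L)) .stopf("empty stratum")
  all_ids <- unlist(strata, use.names = FALSE)
  if (anyDuplicated(all_ids)) .stopf("strata must be disjoint")
  pm <- switch(geometry,
    tss = tss_profile_matrix(reads, genes, ...),
    metagene = metagene_profile(reads, genes, ...),
    promoter = promoter_window_densities(reads, genes, ...)
  )
  curves <- lapply(strata, function(s)
    aggregate_density(pm, gene_set = intersect(s, pm$gene_ids)))
  attr(curves, "offsets") <- pm$offsets
  curves
}

#' Classify expression / promoter-mark concordance
#'
#' Calls each gene by crossing an expression class with a promoter-mark class,
#' both defined by quantile cuts (defaults: below the 0.25 quantile = low,
#' at or above the 0.75 quantile = high, in between = uncalled). For a
#' repressive mark the consistent patterns are high expression with low mark
#' (\code{expressed_consistent}) and low expression with high mark
#' (\code{repressed_consistent}); the exceptions are \code{co_expressed}
#' (both high) and \code{co_suppressed} (both low).
#'
#' @param tpm named numeric vector of expression values.
#' @param promoter_density named numeric vector of promoter mark densities
#'   over the same genes.
#' @param expr_quantiles,mark_quantiles length-2 numeric (low, high) quantile
#'   cuts.
#' @return data.frame with \code{gene_id}, \code{expression_class},
#'   \code{mark_class} and \code{call} (\code{NA} for uncalled genes).
#' @export
classify_concordance <- function(tpm, promoter_density,
                                 expr_quantiles = c(0.25, 0.75),
                                 mark_quantiles = c(0.25, 0.75)) {
  if (is.null(names(tpm)) || is.null(names(promoter_density)))
    .stopf("inputs must be named by gene id")
  if (!setequal(names(tpm), names(promoter_density)))
    .stopf("tpm and promoter_density must cover the same gene universe")
  promoter_density <- promoter_density[names(tpm)]
  classify <- function(x, qs, what) {
    cuts <- quantile(x, qs, names = FALSE)
    if (cuts[1] == cuts[2]) {
      .warnf("degenerate %s distribution: all genes uncalled", what)
      return(rep(NA_character_, length(x)))
    }
    ifelse(x >= cuts[2], "high", ifelse(x < cuts[1], "low", NA_character_))
  }
  ec <- classify(tpm, expr_quantiles, "expression")
  mc <- classify(promoter_density, mark_quantiles, "mark")
  call <- rep(NA_character_, length(tpm))
  call[ec == "high" & mc == "high"] <- "co_expressed"
  call[ec == "low" & mc == "low"] <- "co_suppressed"
  call[ec == "high" & mc == "low"] <- "expressed_consistent"
  call[ec == "low" & mc == "high"] <- "repressed_consistent"
  data.frame(gene_id = names(tpm), expression_class = ec,
             mark_class = mc, call = call, row.names = NULL)
}

# 1 - Spearman rank correlation between the rows of two matrices' centroids
.spearman_dist <- function(a, b) 1 - cor(a, b, method = "spearman")

#' Hierarchical clustering with Spearman distance and centroid linkage
#'
#' Agglomerative clustering of matrix rows with distance
#' \code{1 - Spearman(i, j)} (range 0..2). Linkage follows the centroid
#' convention of classic expression-clustering tools, pinned as follows: rows
#' are rank-transformed once up front (so the whole procedure, like the leaf
#' distances, is invariant to monotone transformations of any single row), a
#' cluster is represented by the column-wise mean of its members'
#' rank-vectors, and inter-cluster distance is \code{1 - Spearman} of the two
#' centroids. Ties in the minimum distance are
#' broken deterministically by the lexicographically smallest leaf labels of
#' the candidate pair. Rows with zero variance (undefined correlation) are
#' dropped with a warning.
#'
#' @param matrix numeric matrix (genes x features), >= 2 rows and columns,
#'   no missing values; rownames are the leaf labels.
#' @return an object of class \code{hclust} (merge, height, order, labels)
#'   with the initial leaf-leaf distance matrix in \code{$leaf_dist}.
#' @export
spearman_centroid_cluster <- function(matrix) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2L || ncol(matrix) < 2L)
    .stopf("need at least 2 rows and 2 features")
  if (anyNA(matrix)) .stopf("missing values not allowed")
  if (is.null(rownames(matrix)))
    rownames(matrix) <- paste0("r", seq_len(nrow(matrix)))
  constant <- apply(matrix, 1L, function(r) sd(r) == 0)
  if (any(constant)) {
    .warnf("%d constant row(s) dropped (undefined rank correlation)",
           sum(constant))
    matrix <- matrix[!constant, , drop = FALSE]
  }
  n <- nrow(matrix)
  if (n < 2L) .stopf("fewer than 2 usable rows")
  labels <- rownames(matrix)
  leaf_dist <- 1 - cor(t(matrix), method = "spearman")
  ranks <- t(apply(matrix, 1L, rank))   # centroids live in rank space

  # active clusters: running member index sets, centroid sums, hclust ids
  members <- as.list(seq_len(n))
  csum <- lapply(seq_len(n), function(i) ranks[i, ])
  ids <- -seq_len(n)                 # hclust convention: negatives = leaves
  first_label <- labels              # tie-break key per active cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    cent <- do.call(cbind, lapply(seq_len(k), function(i)
      csum[[i]] / length(members[[i]])))
    d <- .spearman_dist(cent, cent)
    diag(d) <- Inf
    dmin <- min(d)
    cand <- which(d <= dmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(first_label[cand[, 1]], first_label[cand[, 2]]),
                 pmax(first_label[cand[, 1]], first_label[cand[, 2]]),
                 sep = "\r")
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    merge[step, ] <- sort(c(ids[[i]], ids[[j]]))
    height[step] <- d[i, j]
    members[[i]] <- c(members[[i]], members[[j]])
    csum[[i]] <- csum[[i]] + csum[[j]]
    ids[[i]] <- step
    first_label[i] <- min(first_label[i], first_label[j])
    members[[j]] <- NULL; csum[[j]] <- NULL
    ids <- ids[-j]; first_label <- first_label[-j]
  }
  order <- .merge_leaf_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "spearman-centroid",
                 leaf_dist = leaf_dist,
                 call = match.call(), dist.method = "1 - spearman"),
            class = "hclust")
}

# leaf order by left-to-right traversal of the merge tree
.merge_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}
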