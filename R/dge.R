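# Digital gene expression: CATG-anchored tag extraction, <=1-mismatch
# unambiguous mapping, TPM, expression strata, exact two-library DE.

TAG_LENGTH <- 21L

#' Extract CATG-anchored 21 bp DGE tags from a transcript
#'
#' Emulates the NlaIII/MmeI tag chemistry: a tag is the CATG site plus the 17
#' following bases (21 bp total). In \code{three_prime_most} mode (the
#' library's canonical tag) only the CATG site closest to the 3' end with at
#' least 17 bp downstream is emitted; in \code{all} mode every qualifying site
#' is emitted with its ordinal rank from the 3' end (rank 1 = 3'-most).
#'
#' @param transcript a single DNA sequence (character, A/C/G/T).
#' @param gene_id source gene identifier recorded on the tags.
#' @param mode \code{"three_prime_most"} (default) or \code{"all"}.
#' @return data.frame with columns \code{sequence}, \code{source_gene},
#'   \code{site_rank}; zero rows when no site qualifies.
#' @export
extract_tags <- function(transcript, gene_id = NA_character_,
                         mode = c("three_prime_most", "all")) {
  mode <- match.arg(mode)
  stopifnot(is.character(transcript), length(transcript) == 1L)
  transcript <- toupper(transcript)
  empty <- data.frame(sequence = character(), source_gene = character(),
                      site_rank = integer())
  if (nchar(transcript) < TAG_LENGTH) return(empty)
  pos <- gregexpr("CATG", transcript, fixed = TRUE)[[1L]]
  if (pos[1L] == -1L) return(empty)
  ok <- pos + TAG_LENGTH - 1L <= nchar(transcript)
  pos <- pos[ok]
  if (length(pos) == 0L) return(empty)
  pos <- sort(pos, decreasing = TRUE)       # rank 1 = 3'-most qualifying site
  if (mode == "three_prime_most") pos <- pos[1L]
  data.frame(
    sequence = substring(transcript, pos, pos + TAG_LENGTH - 1L),
    source_gene = gene_id,
    site_rank = seq_along(pos)
  )
}

#' Build a gene -> tag reference from transcript sequences
#'
#' @param transcripts named character vector (or \code{DNAStringSet}) of
#'   transcript sequences; names are gene ids.
#' @param mode passed to [extract_tags()]; the default keeps only each
#'   gene's canonical 3'-most tag.
#' @return data.frame with columns \code{tag}, \code{gene_id},
#'   \code{site_rank}.
#' @export
build_tag_reference <- function(transcripts, mode = "three_prime_most") {
  if (methods::is(transcripts, "DNAStringSet"))
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  if (is.null(names(transcripts))) .stopf("transcripts must be named")
  out <- lapply(names(transcripts), function(g) {
    tg <- extract_tags(transcripts[[g]], gene_id = g, mode = mode)
    if (nrow(tg)) data.frame(tag = tg$sequence, gene_id = g,
                             site_rank = tg$site_rank)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(tag = character(), gene_id = character(),
                               site_rank = integer())
  else out
}

# all 3 * 21 single-mismatch neighbours of a 21-mer
.one_mismatch_neighbours <- function(tag) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(tag, "", fixed = TRUE)[[1L]]
  out <- character(3L * TAG_LENGTH)
  k <- 0L
  for (i in seq_len(TAG_LENGTH)) {
    for (b in bases[bases != chars[i]]) {
      k <- k + 1L
      v <- chars; v[i] <- b
      out[k] <- paste(v, collapse = "")
    }
  }
  out[seq_len(k)]
}

#' Map observed DGE tags to genes with at most one mismatch
#'
#' Each observed tag is matched at the best tier: exact first, then single
#' mismatch. It is counted for a gene only when it maps to exactly one gene at
#' that tier ("unambiguous"); tags hitting several genes are tallied
#' ambiguous, tags hitting none (or containing non-ACGT characters) unmapped.
#'
#' @param observed_tags character vector of 21 bp tag sequences (one element
#'   per sequenced tag; repeats count repeatedly).
#' @param reference tag reference: data.frame with columns \code{tag} and
#'   \code{gene_id} (see [build_tag_reference()]), or a named character
#'   vector gene_id -> tag.
#' @param max_mismatch 0 or 1 (default 1).
#' @return list with \code{counts} (named integer vector over all reference
#'   genes), \code{ambiguous}, \code{unmapped} and \code{n_tags}; the three
#'   tallies and the count total always sum to \code{n_tags}.
#' @export
map_tags_to_genes <- function(observed_tags, reference, max_mismatch = 1L) {
  if (is.character(reference) && !is.null(names(reference)))
    reference <- data.frame(tag = unname(reference), gene_id = names(reference))
  if (!all(c("tag", "gene_id") %in% names(reference)))
    .stopf("reference must have columns tag and gene_id")
  if (!max_mismatch %in% c(0L, 1L)) .stopf("max_mismatch must be 0 or 1")
  all_genes <- unique(reference$gene_id)
  ref_map <- split(reference$gene_id, reference$tag)   # tag -> genes
  counts <- setNames(integer(length(all_genes)), all_genes)
  ambiguous <- 0L; unmapped <- 0L

  valid <- nchar(observed_tags) == TAG_LENGTH &
    !grepl("[^ACGT]", observed_tags)
  unmapped <- unmapped + sum(!valid)
  obs <- observed_tags[valid]
  if (length(obs)) {
    tab <- table(obs)
    uniq <- names(tab)
    for (i in seq_along(uniq)) {
      tg <- uniq[i]; m <- as.integer(tab[[i]])
      genes <- unique(ref_map[[tg]])
      if (is.null(genes) && max_mismatch >= 1L) {
        nb <- .one_mismatch_neighbours(tg)
        hits <- ref_map[nb]
        genes <- unique(unlist(hits, use.names = FALSE))
      }
      ng <- length(genes)
      if (ng == 1L) counts[genes] <- counts[genes] + m
      else if (ng > 1L) ambiguous <- ambiguous + m
      else unmapped <- unmapped + m
    }
  }
  list(counts = counts, ambiguous = ambiguous, unmapped = unmapped,
       n_tags = length(observed_tags))
}

#' Normalize tag counts to tags per million clean tags (TPM)
#'
#' \code{TPM(g) = count(g) / total_clean_tags * 1e6}. When the total equals
#' the sum of counts, TPM sums to exactly one million.
#'
#' @param counts named numeric vector of per-gene unambiguous tag counts.
#' @param total_clean_tags library total of clean tags (>= sum of counts).
#' @return named numeric vector of TPM values.
#' @export
tpm_normalize <- function(counts, total_clean_tags) {
  if (total_clean_tags <= 0) .stopf("total_clean_tags must be > 0")
  if (sum(counts) > total_clean_tags)
    .stopf("total_clean_tags smaller than the sum of counts")
  if (any(counts < 0)) .stopf("negative counts")
  counts / total_clean_tags * 1e6
}

#' Rank genes by expression into equal-size sets
#'
#' Sorts genes by decreasing TPM (ties broken by gene id, stable) and splits
#' them into \code{n_sets} equal-size sets; any remainder goes to the last
#' (lowest-expressed) set. Set 1 holds the most expressed genes. When
#' \code{pick} is supplied, returns only the named strata mapped through
#' \code{pick_indices} (defaults: high -> set 1, medium -> set 4,
#' low -> set 7, silent -> set 10).
#'
#' @param tpm named numeric vector of per-gene TPM.
#' @param n_sets number of sets (default 10, >= 2).
#' @param pick optional character vector of stratum names to return.
#' @param pick_indices named integer vector mapping stratum names to set
#'   indices.
#' @param silent_definition \code{"lowest_set"} (default) takes the silent
#'   stratum as the last set; \code{"zero_tpm"} restricts it to TPM == 0
#'   genes within that set.
#' @return named list of character vectors of gene ids.
#' @export
stratify_by_expression <- function(tpm, n_sets = 10L, pick = NULL,
                                   pick_indices = c(high = 1L, medium = 4L,
                                                    low = 7L, silent = 10L),
                                   silent_definition = c("lowest_set", "zero_tpm")) {
  silent_definition <- match.arg(silent_definition)
  n_sets <- as.integer(n_sets)
  if (n_sets < 2L) .stopf("n_sets must be >= 2")
  if (is.null(names(tpm))) .stopf("tpm must be named by gene id")
  n <- length(tpm)
  if (n < n_sets) .stopf("need at least n_sets genes")
  ord <- order(-tpm, names(tpm), method = "radix")
  ids <- names(tpm)[ord]
  base <- n %/% n_sets
  sizes <- rep(base, n_sets)
  sizes[n_sets] <- sizes[n_sets] + n - base * n_sets
  sets <- split(ids, rep(seq_len(n_sets), sizes))
  names(sets) <- paste0("set", seq_len(n_sets))
  if (is.null(pick)) return(sets)
  bad <- setdiff(pick, names(pick_indices))
  if (length(bad)) .stopf("unknown stratum name(s): %s", paste(bad, collapse = ", "))
  out <- lapply(pick, function(p) {
    idx <- pick_indices[[p]]
    if (idx > n_sets) .stopf("pick index %d exceeds n_sets", idx)
    s <- sets[[idx]]
    if (p == "silent" && silent_definition == "zero_tpm") s <- s[tpm[s] == 0]
    s
  })
  setNames(out, pick)
}

# exact two-library count test: conditional on t = x + y, y ~ Binomial(t, q)
# with q = nB / (nA + nB); two-sided by minimum-likelihood summation in log
# space (this is the classic equal-proportion exact test for tag counts)
.two_library_p <- function(x, y, nA, nB) {
  t <- x + y
  if (t == 0L) return(1)
  q <- nB / (nA + nB)
  lp <- dbinom(0:t, t, q, log = TRUE)
  min(1, sum(exp(lp[lp <= lp[y + 1L] + 1e-7])))
}

#' Exact two-library differential expression
#'
#' Per gene, tests the equal-proportion null for two tag libraries with the
#' exact count test: conditional on the gene's total count, the second
#' library's count is Binomial with success probability
#' \code{totalB / (totalA + totalB)}; the two-sided p-value sums all outcomes
#' no more likely than the observed one (in log space). P-values are BH
#' adjusted across genes, and a gene is flagged significant when
#' \code{fdr <= fdr_cutoff} and \code{|log2Ratio| >= lfc_cutoff}
#' (defaults 0.01 and 1). The log2 ratio of A over B uses a 0.5 pseudocount
#' so on/off genes stay finite; significance still requires the count-based
#' p-value.
#'
#' @param countsA,countsB named numeric vectors of per-gene tag counts (gene
#'   universes are united; absent genes count 0).
#' @param totalA,totalB library totals of clean tags.
#' @param fdr_cutoff,lfc_cutoff significance thresholds.
#' @return data.frame with \code{gene_id}, \code{count_a}, \code{count_b},
#'   \code{log2_ratio}, \code{p_value}, \code{fdr}, \code{significant}.
#' @export
differential_expression <- function(countsA, totalA, countsB, totalB,
                                    fdr_cutoff = 0.01, lfc_cutoff = 1) {
  if (totalA <= 0 || totalB <= 0) .stopf("library totals must be > 0")
  if (any(countsA < 0) || any(countsB < 0)) .stopf("negative counts")
  genes <- union(names(countsA), names(countsB))
  if (is.null(genes)) .stopf("counts must be named by gene id")
  x <- setNames(numeric(length(genes)), genes)
  y <- x
  x[names(countsA)] <- countsA
  y[names(countsB)] <- countsB
  p <- vapply(seq_along(genes), function(i)
    .two_library_p(x[i], y[i], totalA, totalB), numeric(1))
  lr <- log2(((x + 0.5) / totalA) / ((y + 0.5) / totalB))
  fdr <- p.adjust(p, method = "BH")
  data.frame(
    gene_id = genes,
    count_a = as.numeric(x), count_b = as.numeric(y),
    log2_ratio = as.numeric(lr),
    p_value = p, fdr = fdr,
    significant = fdr <= fdr_cutoff & abs(lr) >= lfc_cutoff,
    row.names = NULL
  )
}
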