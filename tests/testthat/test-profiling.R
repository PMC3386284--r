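test_that("TSS offset arithmetic and strand mirroring place reads correctly", {
  genes <- mk_genes(c("gp", "gm"), "chr1", c("+", "-"),
                    c(10000L, 50000L), c(20000L, 60001L))
  # gm TSS = 60000; read at 62010 is upstream 2010 on the minus strand
  rd <- mk_reads("chr1", c(7990L, 62010L))
  pm <- tss_profile_matrix(rd, genes, window = 50, span = 20000)
  col <- which(pm$offsets == -2050)
  expect_equal(unname(pm$counts["gp", col]), 1)
  expect_equal(unname(pm$counts["gm", col]), 1)
  expect_equal(sum(pm$counts), 2)
})

test_that("profile matrices equal brute-force offset binning and conserve reads", {
  toy <- random_toy(51, n_genes = 3, chrom_len = 60000L)
  set.seed(52)
  rd <- mk_reads("chr1", sample.int(60000L, 400) - 1L)
  pm <- tss_profile_matrix(rd, toy$genes, window = 50, span = 5000)
  oracle <- brute_tss_bins(rd, toy$genes, 50, 5000)
  expect_equal(unname(pm$counts), oracle)

  mg <- metagene_profile(rd, toy$genes, body_bins = 20, flank_kb = 5)
  expect_equal(unname(mg$counts),
               brute_metagene_bins(rd, toy$genes, 20, 5))

  pw <- promoter_window_densities(rd, toy$genes, window = 500, span = 5000)
  expect_equal(unname(pw$counts),
               brute_tss_bins(rd, toy$genes, 500, 5000, lo = -5000, hi = 0))
})

test_that("promoter matrix equals the re-binned TSS matrix on the overlap", {
  toy <- random_toy(53, n_genes = 8)
  set.seed(54)
  rd <- mk_reads("chr1", sample.int(toy$genome_sizes[[1]], 3000, TRUE) - 1L)
  tp <- tss_profile_matrix(rd, toy$genes, window = 50, span = 20000)
  pw <- promoter_window_densities(rd, toy$genes, window = 500, span = 5000)
  sub <- tp$counts[, tp$offsets >= -5000 & tp$offsets < 0]
  rebin <- t(apply(sub, 1, function(x) tapply(x, rep(1:10, each = 10), sum)))
  expect_equal(unname(rebin), unname(pw$counts), ignore_attr = TRUE)
})

test_that("metagene densities are flat for uniform reads", {
  # 40 genes of 4 kb with short flanks; uniform rate 0.1 reads/bp
  genes <- mk_genes(sprintf("g%02d", 1:40), "chr1", rep(c("+", "-"), 20),
                    seq(10000L, by = 12000L, length.out = 40),
                    seq(14000L, by = 12000L, length.out = 40))
  len <- max(genes$end) + 10000L
  set.seed(61)
  rd <- mk_reads("chr1", sample.int(len, round(0.1 * len), TRUE) - 1L)
  mg <- metagene_profile(rd, genes, body_bins = 20, flank_kb = 3)
  dens <- aggregate_density(mg)
  expect_lt(sd(dens) / mean(dens), 0.05)
})

test_that("gene-body binning uses gene-length fractions", {
  genes <- mk_genes("g1", "chr1", "+", 10000L, 12000L)  # 2 kb body
  rd <- mk_reads("chr1", 10000L + 860L)                 # 43% into the body
  mg <- metagene_profile(rd, genes, body_bins = 20, flank_kb = 1)
  body <- mg$counts[1, 2:21]
  expect_equal(unname(which(body == 1)), 9L)            # 0-indexed bin 8
})

test_that("profiles are invariant under genome mirroring", {
  toy <- random_toy(71, n_genes = 6)
  L <- toy$genome_sizes[[1]]
  set.seed(72)
  rd <- mk_reads("chr1", sample.int(L, 800) - 1L)
  mirror_genes <- toy$genes
  mirror_genes$start <- L - toy$genes$end
  mirror_genes$end <- L - toy$genes$start
  mirror_genes$strand <- ifelse(toy$genes$strand == "+", "-", "+")
  mirror_genes$exon_starts <- lapply(seq_len(nrow(toy$genes)), function(i)
    rev(L - toy$genes$exon_ends[[i]]))
  mirror_genes$exon_ends <- lapply(seq_len(nrow(toy$genes)), function(i)
    rev(L - toy$genes$exon_starts[[i]]))
  mirror_genes$tss <- ifelse(mirror_genes$strand == "+",
                             mirror_genes$start, mirror_genes$end - 1L)
  mirror_genes$tes <- ifelse(mirror_genes$strand == "+",
                             mirror_genes$end - 1L, mirror_genes$start)
  mirror_rd <- mk_reads("chr1", L - 1L - rd$pos5)
  p1 <- tss_profile_matrix(rd, toy$genes, window = 50, span = 5000)
  p2 <- tss_profile_matrix(mirror_rd, mirror_genes, window = 50, span = 5000)
  expect_equal(p1$counts, p2$counts)
  m1 <- metagene_profile(rd, toy$genes, flank_kb = 4)
  m2 <- metagene_profile(mirror_rd, mirror_genes, flank_kb = 4)
  expect_equal(m1$counts, m2$counts)
})

test_that("aggregate density averages count/bp over the gene set", {
  genes <- mk_genes(c("a", "b"), "chr1", "+", c(10000L, 30000L),
                    c(12000L, 32000L))
  rd <- mk_reads("chr1", c(rep(9990L, 4), rep(29990L, 6)))
  pm <- tss_profile_matrix(rd, genes, window = 50, span = 1000)
  col <- which(pm$offsets == -50)
  d <- aggregate_density(pm)
  expect_equal(unname(d[col]), (4 + 6) / (2 * 50))
  d1 <- aggregate_density(pm, gene_set = "a")
  expect_equal(unname(d1[col]), 4 / 50)
  expect_error(aggregate_density(pm, gene_set = character(0)), "empty")
  expect_error(aggregate_density(pm, gene_set = "zz"), "not in profile")
})

test_that("columns leaving the chromosome are flagged missing", {
  genes <- mk_genes("g1", "chr1", "+", 3000L, 9000L)
  rd <- mk_reads("chr1", c(10L, 3100L))
  pm <- tss_profile_matrix(rd, genes, window = 50, span = 5000,
                           genome_sizes = c(chr1 = 100000))
  expect_true(all(is.na(pm$counts[1, pm$offsets < -3000])))
  expect_false(anyNA(pm$counts[1, pm$offsets >= -3000]))
  d <- aggregate_density(pm)
  expect_true(all(is.nan(d[as.character(pm$offsets[pm$offsets < -3000])])))
})

test_that("genes shorter than the body bin count are excluded with a warning", {
  genes <- mk_genes(c("g1", "tiny"), "chr1", "+", c(10000L, 50000L),
                    c(14000L, 50010L))
  rd <- mk_reads("chr1", 11000L)
  expect_warning(mg <- metagene_profile(rd, genes, body_bins = 20), "excluded")
  expect_equal(mg$gene_ids, "g1")
})
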