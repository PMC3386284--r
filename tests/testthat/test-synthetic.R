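small_cfg <- function(seed = 131, ...) {
  sim_config(seed = seed, n_genes = 120L, depth = 1e5, tag_depth = 1e5, ...)
}

test_that("generators are fully deterministic under a fixed seed", {
  cfg <- small_cfg()
  g1 <- simulate_gene_models(cfg); g2 <- simulate_gene_models(cfg)
  expect_identical(g1, g2)
  e1 <- simulate_expression(g1$genes, cfg); e2 <- simulate_expression(g2$genes, cfg)
  expect_identical(e1, e2)
  r1 <- simulate_chip_reads(g1$genes, e1$tpm, cfg)
  r2 <- simulate_chip_reads(g1$genes, e1$tpm, cfg)
  expect_identical(r1, r2)
})

test_that("gene layout honours flank separation, strand balance and exons", {
  cfg <- small_cfg(132)
  gm <- simulate_gene_models(cfg)
  g <- gm$genes
  for (cc in unique(g$chrom)) {
    gc <- g[g$chrom == cc, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1)
      expect_true(all(gc$start[-1] - gc$end[-nrow(gc)] >= 2 * cfg$flank))
    expect_true(all(gc$start - cfg$flank >= 0))
    expect_true(all(gc$end + cfg$flank <= gm$genome_sizes[[cc]]))
  }
  expect_lte(abs(sum(g$strand == "+") - sum(g$strand == "-")), 1L)
  for (i in seq_len(nrow(g))) {
    es <- g$exon_starts[[i]]; ee <- g$exon_ends[[i]]
    expect_gte(length(es), 1L); expect_lte(length(es), 5L)
    expect_equal(es[1], g$start[i])
    expect_equal(ee[length(ee)], g$end[i])
    expect_true(all(ee > es))
    if (length(es) > 1) expect_true(all(es[-1] >= ee[-length(ee)]))
  }
  expect_error(simulate_gene_models(small_cfg(chrom_length = 1e5)),
               "too small")
})

test_that("expression truth has the configured silent fraction and TPM scale", {
  cfg <- small_cfg(133)
  gm <- simulate_gene_models(cfg)
  ex <- simulate_expression(gm$genes, cfg, n_samples = 2)
  expect_equal(sum(ex$tpm == 0), round(0.3 * nrow(gm$genes)))
  expect_equal(sum(ex$tpm), 1e6)
  expect_equal(unname(colSums(ex$counts)), rep(1e5, 2))
  expect_true(all(ex$counts[ex$tpm == 0, ] == 0))
})

test_that("TPM estimation error shrinks with tag depth", {
  cfg_lo <- sim_config(seed = 134, n_genes = 400L, tag_depth = 1e4)
  gm <- simulate_gene_models(cfg_lo)
  ex_lo <- simulate_expression(gm$genes, cfg_lo)
  cfg_hi <- sim_config(seed = 134, n_genes = 400L, tag_depth = 1e6)
  ex_hi <- simulate_expression(gm$genes, cfg_hi)
  expect_identical(ex_lo$tpm, ex_hi$tpm)   # same truth, different depth
  expressed <- ex_lo$tpm > 0
  err <- function(ex, depth) {
    est <- tpm_normalize(ex$counts[, 1], depth)
    mean(abs(est[expressed] - ex$tpm[expressed]) / ex$tpm[expressed])
  }
  expect_lt(err(ex_hi, 1e6), err(ex_lo, 1e4))
})

test_that("amplitude ablations remove the planted structure", {
  # no enrichment at all: every region class at genome-average density
  cfg0 <- small_cfg(135, bump_amp = 0, broad_amp = 0, dip_depth = 0)
  gm <- simulate_gene_models(cfg0)
  ex <- simulate_expression(gm$genes, cfg0)
  cr <- simulate_chip_reads(gm$genes, ex$tpm, cfg0)
  p <- build_region_partition(gm$genes, gm$genome_sizes, mode = "exclusive")
  s <- region_read_summary(cr$reads, p)
  expect_true(all(abs(s$abundance - 1) < 0.1))

  # dip ablation: TSS column no longer depressed for silent genes
  cfg_dip <- small_cfg(136, dip_depth = 0)
  ex2 <- simulate_expression(gm$genes, cfg_dip)
  cr_dip <- simulate_chip_reads(gm$genes, ex2$tpm, cfg_dip)
  pm <- tss_profile_matrix(cr_dip$reads, gm$genes, window = 50, span = 2000,
                           genome_sizes = gm$genome_sizes)
  d <- aggregate_density(pm)
  win <- pm$offsets >= -500 & pm$offsets < 500
  tss_cols <- pm$offsets %in% c(-50L, 0L)
  expect_gt(mean(d[tss_cols & win]), 0.6 * median(d[win]))
})

test_that("simulated outputs round-trip through the io readers cleanly", {
  cfg <- small_cfg(137)
  gm <- simulate_gene_models(cfg)
  ex <- simulate_expression(gm$genes, cfg)
  cr <- simulate_chip_reads(gm$genes, ex$tpm, cfg)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed_reads(cr$reads, bed)
  expect_no_warning(back <- read_bed_reads(bed))
  expect_equal(back$pos5, cr$reads$pos5)
  gtab <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(gm$genes, gtab)
  expect_no_warning(gback <- read_gene_table(gtab))
  expect_equal(gback$tss, gm$genes$tss)
  pk <- simulate_peak_table(gm$genes, cr$truth, cfg, top_n = 20)
  xls <- withr::local_tempfile(fileext = ".xls")
  write_macs_peaks(pk, xls)
  expect_no_warning(pback <- read_macs_peaks(xls))
  expect_equal(nrow(pback), 20L)
  expect_equal(pback$start, pk$start)
})

test_that("two-group ablations separate the expression and mark effects", {
  base <- list(seed = 138, n_genes = 300L, depth = 3e5, tag_depth = 3e5,
               n_affected = 30L)
  run <- function(expr_log2fc, mark_fold) {
    cfg <- do.call(sim_config, c(base, list(expr_log2fc = expr_log2fc,
                                            mark_fold = mark_fold)))
    study <- simulate_two_group_study(cfg)
    de <- differential_expression(rowSums(study$counts$A), 2 * cfg$tag_depth,
                                  rowSums(study$counts$B), 2 * cfg$tag_depth)
    da <- pooled_promoter_densities(study$reads$A, study$genes,
                                    study$affected,
                                    genome_sizes = study$genome_sizes)
    db <- pooled_promoter_densities(study$reads$B, study$genes,
                                    study$affected,
                                    genome_sizes = study$genome_sizes)
    cmp <- compare_promoter_windows(da, db)
    list(de = de, cmp = cmp, study = study)
  }
  # expression knock-down only: DE recovered, windows at the null rate
  r1 <- run(expr_log2fc = 2, mark_fold = 1)
  sens <- mean(r1$study$affected %in% r1$de$gene_id[r1$de$significant])
  expect_gt(sens, 0.8)
  expect_lte(sum(r1$cmp$flagged), 2L)
  expect_gt(min(r1$cmp$p_value[c(7, 8)]), 1e-4)

  # mark boost only: the boost windows light up, DE stays at the null rate
  r2 <- run(expr_log2fc = 0, mark_fold = 2)
  expect_true(all(r2$cmp$flagged[c(7, 8)]))
  expect_equal(sort(order(r2$cmp$p_value)[1:2]), c(7L, 8L))
  expect_lte(sum(r2$de$significant), 2L)
})
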