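test_that("tag extraction follows the CATG + 17 bp rule", {
  tg <- extract_tags("AACATGTTTTTTTTTTTTTTTTTAA")
  expect_equal(tg$sequence, "CATGTTTTTTTTTTTTTTTTT")
  expect_equal(nchar(tg$sequence), 21L)

  # the 3'-most CATG lacks 17 bp downstream; the earlier site is used
  tx <- paste0("GGCATG", strrep("A", 17), "CATG", strrep("T", 10))
  tg <- extract_tags(tx)
  expect_equal(tg$sequence, paste0("CATG", strrep("A", 17)))

  expect_equal(nrow(extract_tags("AAAATTTTGGGGCCCCAAAATTTT")), 0L)
  expect_equal(nrow(extract_tags(paste0("CATG", strrep("A", 5)))), 0L)
})

test_that("mode all emits every qualifying site ranked from the 3' end", {
  tx <- paste0("AA", "CATG", strrep("A", 17), "CATG", strrep("C", 17),
               "CATG", strrep("G", 17))
  tg <- extract_tags(tx, mode = "all")
  expect_equal(nrow(tg), 3L)
  expect_equal(tg$site_rank, 1:3)
  expect_equal(tg$sequence[1], paste0("CATG", strrep("G", 17)))
  expect_equal(tg$sequence[3], paste0("CATG", strrep("A", 17)))
})

test_that("tag extraction matches a brute-force scan on random transcripts", {
  set.seed(91)
  for (i in 1:50) {
    tx <- random_dna(sample(21:200, 1))
    oracle <- brute_extract_tags(tx)
    all_tags <- extract_tags(tx, mode = "all")
    expect_equal(all_tags$sequence, oracle)
    canon <- extract_tags(tx)
    expect_equal(canon$sequence,
                 if (length(oracle)) oracle[1] else character(0))
  }
})

test_that("tag mapping counts unambiguous best-tier hits only", {
  ref <- data.frame(tag = c("CATGAAAAAAAAAAAAAAAAA",
                            "CATGCCCCCCCCCCCCCCCCC",
                            "CATGCCCCCCCCCCCCCCCCC",
                            "CATGGGGGGGGGGGGGGGGGG"),
                    gene_id = c("g1", "g2", "g3", "g4"))
  # exact unique
  m <- map_tags_to_genes("CATGAAAAAAAAAAAAAAAAA", ref)
  expect_equal(m$counts[["g1"]], 1L)
  # exact hit shared by two genes -> ambiguous
  m <- map_tags_to_genes("CATGCCCCCCCCCCCCCCCCC", ref)
  expect_equal(m$ambiguous, 1L)
  expect_equal(sum(m$counts), 0L)
  # 1-mismatch to two different genes -> ambiguous
  m <- map_tags_to_genes("CATGAAAAAAAAAAAAAAAAG", ref["g1" == ref$gene_id |
                                                       ref$gene_id == "g4", ])
  expect_equal(m$counts[["g1"]], 1L)   # only g1 within 1 mismatch
  m <- map_tags_to_genes("CCTGAAAAAAAAAAAAAAAAA",
                         data.frame(tag = c("CATGAAAAAAAAAAAAAAAAA",
                                            "CCTGAAAAAAAAAAAAAAAAC"),
                                    gene_id = c("g1", "g2")))
  expect_equal(m$ambiguous, 1L)
  # non-ACGT -> unmapped
  m <- map_tags_to_genes("CATGNNNNNNNNNNNNNNNNN", ref)
  expect_equal(m$unmapped, 1L)
})

test_that("mapping matches brute-force Hamming search and conserves tags", {
  set.seed(92)
  txs <- setNames(vapply(1:30, function(i)
    paste0(random_dna(20), "CATG", random_dna(25)), ""),
    sprintf("g%02d", 1:30))
  ref <- build_tag_reference(txs)
  mutate1 <- function(tg) {
    p <- sample.int(21L, 1)
    substr(tg, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                       substr(tg, p, p)), 1)
    tg
  }
  observed <- c(sample(ref$tag, 60, TRUE),
                vapply(sample(ref$tag, 30, TRUE), mutate1, ""),
                vapply(sample(ref$tag, 15, TRUE),
                       function(t) mutate1(mutate1(t)), ""),
                replicate(10, paste0("CATG", random_dna(17))),
                "CATGNNNNNNNNNNNNNNNNN")
  m <- map_tags_to_genes(observed, ref)
  oracle <- brute_map_tags(observed, ref)
  expect_equal(m$counts[names(oracle$counts)], oracle$counts)
  expect_equal(m$ambiguous, oracle$ambiguous)
  expect_equal(m$unmapped, oracle$unmapped)
  expect_equal(sum(m$counts) + m$ambiguous + m$unmapped, length(observed))
  # permutation invariance
  m2 <- map_tags_to_genes(sample(observed), ref)
  expect_equal(m2$counts, m$counts)
})

test_that("TPM normalization scales counts to tags per million", {
  expect_equal(unname(tpm_normalize(c(g = 5), 1e6)), 5)
  tp <- tpm_normalize(c(a = 10, b = 30, c = 60), 100)
  expect_equal(unname(tp), c(1e5, 3e5, 6e5))
  expect_equal(sum(tp), 1e6)
  set.seed(93)
  cts <- setNames(rpois(100, 50), paste0("g", 1:100))
  expect_equal(sum(tpm_normalize(cts, sum(cts))), 1e6)
  expect_error(tpm_normalize(c(a = 1), 0), "total")
  expect_error(tpm_normalize(c(a = 5), 4), "smaller")
})

test_that("expression stratification is rank-based with deterministic ties", {
  tpm <- setNames(c(20:1), sprintf("g%02d", 1:20))
  s <- stratify_by_expression(tpm, n_sets = 4)
  expect_equal(lengths(s), setNames(rep(5L, 4), paste0("set", 1:4)))
  expect_equal(s$set1, sprintf("g%02d", 1:5))
  # all-equal TPM: sets determined by gene id order
  tpm2 <- setNames(rep(7, 20), sprintf("g%02d", 20:1))
  s2 <- stratify_by_expression(tpm2, n_sets = 4)
  expect_equal(s2$set1, sprintf("g%02d", 1:5))
  expect_error(stratify_by_expression(tpm, n_sets = 1), "n_sets")

  picked <- stratify_by_expression(tpm, n_sets = 4,
                                   pick = c("high", "silent"),
                                   pick_indices = c(high = 1, silent = 4))
  expect_equal(picked$high, s$set1)
  expect_equal(picked$silent, s$set4)
})

test_that("7000 genes stratify into 10 sets of 700", {
  set.seed(94)
  tpm <- setNames(c(rlnorm(4900, 4, 1.5), rep(0, 2100)),
                  sprintf("g%04d", 1:7000))
  s <- stratify_by_expression(tpm)
  expect_equal(unname(lengths(s)), rep(700L, 10))
  expect_true(all(tpm[s$set1] >= max(tpm[s$set2])))
})

test_that("two-library exact test matches the enumeration oracle", {
  # null identities
  de <- differential_expression(c(g = 0), 1000, c(g = 0), 1000)
  expect_equal(de$p_value, 1)
  expect_false(de$significant)
  de <- differential_expression(c(g = 100), 5e4, c(g = 100), 5e4)
  expect_equal(de$log2_ratio, 0)
  expect_equal(de$p_value, 1, tolerance = 1e-10)
  # hand-enumerable case: x = 0, y = 5 at equal totals
  de <- differential_expression(c(g = 0), 1000, c(g = 5), 1000)
  expect_equal(de$p_value, brute_two_library_p(0, 5, 1000, 1000))
  expect_equal(de$p_value, 0.0625)
  # random cases, including unequal totals
  set.seed(95)
  for (i in 1:25) {
    x <- rpois(1, 20); y <- rpois(1, 20)
    nA <- sample(c(1e5, 2e5, 5e5), 1); nB <- sample(c(1e5, 3e5), 1)
    de <- differential_expression(setNames(x, "g"), nA, setNames(y, "g"), nB)
    expect_equal(de$p_value, brute_two_library_p(x, y, nA, nB),
                 tolerance = 1e-12)
    # independent check against the exact binomial test
    bt <- binom.test(y, x + y, nB / (nA + nB))$p.value
    if (x + y > 0) expect_equal(de$p_value, bt, tolerance = 1e-9)
  }
})

test_that("swapping libraries negates the ratio and preserves the p-value", {
  set.seed(96)
  for (i in 1:20) {
    x <- rpois(1, 30); y <- rpois(1, 10)
    nA <- 2e5; nB <- 7e5
    d1 <- differential_expression(setNames(x, "g"), nA, setNames(y, "g"), nB)
    d2 <- differential_expression(setNames(y, "g"), nB, setNames(x, "g"), nA)
    expect_equal(d1$log2_ratio, -d2$log2_ratio, tolerance = 1e-12)
    expect_equal(d1$p_value, d2$p_value, tolerance = 1e-10)
  }
  expect_error(differential_expression(c(g = -1), 10, c(g = 1), 10),
               "negative")
})

test_that("significance requires both the FDR and the fold-change rule", {
  # strong p-value but |log2Ratio| < 1 must not be flagged
  de <- differential_expression(c(g = 1000, h = 50), 1e6,
                                c(g = 1500, h = 50), 1e6)
  g <- de[de$gene_id == "g", ]
  expect_lt(g$fdr, 0.01)
  expect_lt(abs(g$log2_ratio), 1)
  expect_false(g$significant)
})
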