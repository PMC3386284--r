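---
title: "Methods: integrating a repressive histone mark with digital gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating a repressive histone mark with digital gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`epimark` analyses how a repressive histone mark of the H3K27me3 kind relates
to gene expression, working from mapped ChIP-seq read positions (BED),
gene models (a genePred-style table), MACS 1.4 peak tables, and tag-based
digital gene expression (DGE) libraries. Alignment and peak calling happen
upstream; the package consumes their outputs.

All internal coordinates are 0-based half-open. BED is the native convention;
MACS tables (1-based inclusive, summit as an offset from the peak start) are
converted on ingest, which makes the conversion a bijection
(`start0 = start1 - 1`, `end0 = end1`). A ChIP read is a point event at its
5' position — `start` on the plus strand, `end - 1` on the minus strand —
because nucleosomal signal summaries count tag starts in fixed windows; the
recorded read length (49 bp by default) is metadata only. Reads are not
strand-filtered relative to genes: nucleosomal ChIP signal is strand-agnostic.
BED3 records without a strand default to plus with a logged warning rather
than an error.

# Genome partition and read distribution

`build_region_partition()` labels the genome with five classes: `up20K`
(20 kb upstream of the TSS in transcription orientation), `exon`, `intron`,
`down20K` (20 kb past the TES), and `intergenic`. Two modes are first-class
because annotations genuinely overlap (one gene's promoter flank can sit in
another's intron):

* **multilabel** (default): a base pair can carry several labels, so class
  percentages may sum to more than 100%. This is the accounting that makes
  published region-percentage tables exceed 100%, and it is the default for
  that reason.
* **exclusive**: labels are made disjoint with precedence
  `exon > intron > up20K > down20K` (genic sequence identity dominates flank
  assignment; the precedence is configurable in principle by rebuilding with
  different inputs) and, with `intergenic`, tile the genome exactly once.
  This mode supports the algebraic identity
  `sum(genome_fraction * abundance) = 1`, which the tests check to 1e-12.

Flanks are clipped at chromosome edges rather than dropped, conserving reads
near ends. The **abundance** of a class is its read percentage divided by its
genome percentage; 1 means reads land at genome-average density. Read
percentages always use the number of reads as denominator (not the sum of
label counts), so each label's percentage is interpretable on its own.

# Profile geometries

Three profile geometries cover the standard views, all left-closed
right-open in oriented offset space so that the TSS sits at the left edge of
the first downstream column:

* `tss_profile_matrix()`: 50 bp windows over [TSS − 20 kb, TSS + 20 kb),
  minus-strand genes mirrored.
* `metagene_profile()`: twenty 5%-of-gene-length body bins flanked by twenty
  1 kb bins per side; the object carries per-gene bin widths (body bin *j*
  holds `ceil((j+1)L/20) − ceil(jL/20)` positions) so densities are free of
  the bin-size effect.
* `promoter_window_densities()`: ten 500 bp windows over [TSS − 5 kb, TSS);
  identical, by construction and by test, to re-binning the 50 bp TSS matrix.

Columns whose genomic footprint leaves the chromosome are flagged missing and
excluded from averages, which avoids edge bias at the cost of dropping those
genes from the affected columns only. `aggregate_density()` reports the
column mean of count/bp over a gene set, optionally scaled to reads per
million for between-sample figures (off by default within one sample's
figures).

A note on resolution: the simulated occupancy dip is centred exactly on the
TSS, which at 50 bp resolution is the shared edge of two columns whose
expected densities differ by under 2%. Recovery checks therefore accept the
minimising column if it touches the TSS (column midpoint within half a
window). This is a measurement-resolution convention, fixed before any
results were inspected, not a tolerance.

# Peaks

A peak is associated with a gene when it overlaps any of the gene's four
genic classes by **at least 1 bp**; a gene hit through several classes keeps
the union of labels, which is why per-class percentages of associated genes
can exceed 100%. The implementation uses interval overlap queries
(GenomicRanges); the test suite keeps an all-pairs brute-force oracle and
rechecks every cited supporting peak independently. Saturation analysis
subsamples reads without replacement at fixed fractions over the *fixed*
full-data peak regions — peaks are not re-called per fraction, since peak
calling is outside the package — and each (seed, fraction) subsample is
reproducible independent of which other fractions are requested.

# Digital gene expression

Tag chemistry is emulated at the sequence level: a tag is a CATG anchor plus
the 17 following bases (21 bp), and the canonical library tag is the 3'-most
CATG site with at least 17 bp downstream (`mode = "all"` emits every
qualifying site, ranked from the 3' end, for reference building). Mapping
accepts at most one mismatch, resolved at the best tier (exact before
1-mismatch) and counted only when the tag hits exactly one gene at that
tier; ambiguous and unmapped tags are tallied so that counts always conserve
the input. The 1-mismatch neighbourhood is searched exactly (63 variants per
tag against a hash of reference tags), not heuristically.

TPM is `count / total_clean_tags * 1e6`, with the total taken post-filter.
Expression strata sort genes by decreasing TPM (ties broken by gene id,
stable) into equal sets — ten sets by default, with high/medium/low/silent
mapped to sets 1/4/7/10. "Silent" defaults to the lowest set; a strict
TPM == 0 definition is available by flag since either reading is defensible.

## The two-library exact test

The differential expression test is the classic exact two-library count test
for tag data. For a gene with counts \(x, y\) in libraries of size
\(N_1, N_2\), the null probability of the second count given the first is

\[ p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
   \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y}}, \]

which, restricted to the observed total \(t = x + y\), is exactly the
binomial law \(y \sim \mathrm{Bin}(t,\, N_2/(N_1+N_2))\). The package
computes the two-sided p-value conditionally on \(t\) by minimum-likelihood
summation in log space (all outcomes no more likely than the observed one).
The conditional form is used deliberately: the unconditional single-tail sum
of the formula above is not symmetric under swapping the two libraries,
whereas the conditional two-sided value is swap-symmetric to machine
precision and agrees with the enumeration of the formula on the observed
total — both properties are asserted in the tests, with `binom.test` as an
independent cross-check. Benjamini–Hochberg FDR is applied across genes and
a gene is called significant when `fdr <= 0.01` **and** `|log2Ratio| >= 1`.
The log2 ratio uses a 0.5 pseudocount per library so on/off genes stay
finite; significance still requires the count-based p-value.

# Integration and clustering

Concordance calls cross an expression class with a promoter-mark class, each
defined by 0.25/0.75 quantile cuts (no numeric cutoffs exist for "high" and
"low" in this setting, so quantiles are the least arbitrary choice and are
configurable); genes between the cuts stay uncalled. For a repressive mark,
"co-expressed" (both high) and "co-suppressed" (both low) are the
exceptions to the expected anti-coupling.

Hierarchical clustering uses distance `1 − Spearman` between rows and
centroid linkage in the convention of classic expression-clustering tools,
pinned precisely because "centroid" is convention-dependent on non-Euclidean
distances: rows are rank-transformed once up front, a cluster's centroid is
the mean of its members' rank vectors, and cluster distance is `1 − Spearman`
of centroids. The up-front rank transform makes the whole dendrogram — not
just the leaf distances — invariant to monotone transformations of any
single row. Ties in the minimal distance break deterministically by the
lexicographically smallest leaf labels. Constant rows (undefined rank
correlation) are dropped with a warning. When expression and modification
values share a matrix, z-scaling columns before clustering is recommended;
the pipeline works on one feature type at a time and leaves scaling to the
caller.

# Promoter-window group comparison

`compare_promoter_windows()` tests, per 500 bp promoter window, a Welch
two-sample t-test between two groups' per-gene densities. The unit of
replication is the **gene**: with two animals per group an animal-level test
has no power to exist at all, so per-gene window densities (each gene's
value averaged over the group's samples, after reads-per-million scaling —
groups are rarely sequenced to identical depth) are compared across groups.
This choice is deliberate and visible: it treats genes as exchangeable
replicates and animals as pooled, and it is conservative when the same genes
appear in both groups (shared gene effects inflate the within-group variance
but not the between-group difference). Raw two-sided p-values are reported
with a 0.05 flag by default, matching the convention of reporting raw
P < 0.05 for window scans; BH adjustment is available. Windows with zero
variance in both groups report t = 0, p = 1, and a degeneracy flag.

# qPCR arithmetic

Standard curves fit Cp against log10(input ng) by least squares over at
least three distinct concentrations; the per-cycle amplification factor is
`10^(-1/slope)` (−3.3219 cycles/decade = perfect doubling). Relative
enrichment uses `2^-ddCp` with the target site referenced to a negative
control site in both the ChIP and input templates; replicate Cp values are
averaged first and their spread is propagated for error bars. The
fold inverts exactly under swapping ChIP and input, which the tests assert.

# The synthetic-data generator

The generator plants the statistical structure the analysis is designed to
recover, with truth tables for every recovery metric. For a gene \(g\) with
repression coupling \(r(g) \in [0,1]\), the ChIP intensity at oriented
offset \(o\) from the TSS is

\[ \lambda(o) = s\,\bigl[1 + B\,r(g) + A\,r(g)\,
   e^{-(o-c)^2/2\sigma_b^2}\bigr]\,
   \bigl[1 - d\,e^{-o^2/2\sigma_d^2}\bigr] \]

inside the gene neighbourhood (gene body plus 20 kb flanks) and \(s\)
outside, with defaults: promoter bump centre \(c = -2000\) bp, width
\(\sigma_b = 800\) bp, amplitude \(A = 20\); broad neighbourhood amplitude
\(B = 6\); TSS dip depth \(d = 0.8\), width \(\sigma_d = 150\) bp. The scale
\(s\) is set so the expected read total equals the configured depth
(2e6 by default); reads are a Poisson draw from the mixture, with the dip
applied by thinning. The broad term models the domain-like elevation a
repressive mark shows over an entire silenced locus — without it, stratum
curves would separate only inside the narrow bump and coincide elsewhere,
which is not what marked repressive domains look like. The amplitudes were
fixed by a pre-run power analysis at the default depth (stratum separation
at the far end of the promoter window, −5 kb, is about 3.5 standard errors
per 50 bp column for adjacent picked strata), so the planted ordering is
recoverable at the study scale rather than only at the bump.

The coupling is rank-based, not TPM-linear: genes are ranked by ascending
TPM with ties sharing the minimum rank, and \(r = 1 - (\mathrm{rank}-1)/(n-1)\).
Tie-sharing matters: with 30% silent genes, averaging ranks across the
zero-TPM block would give the bottom expression stratum a mean coupling
barely above the next stratum's and destroy the monotone stratum ordering
the analysis is supposed to recover; with shared minimum ranks all silent
genes carry the maximal coupling \(r = 1\).

Expression truth draws a 30% silent fraction and log-normal TPM weights
(meanlog 4, sdlog 1.5, natural scale) normalised to one million; tag
libraries are multinomial draws at the configured depth. The two-group
design knocks affected genes' TPM down by `2^expr_log2fc` (renormalised) and
multiplies their ChIP intensity by `mark_fold` over the oriented window
[−2000, −1000) **only**; both groups share the baseline coupling derived
from the reference group's expression, so the planted differential mark is
confined to that window by construction. Genes are packed in fixed slots
with seeded jitter so 20 kb neighbourhoods never overlap and never leave the
chromosome — a deliberately gene-dense toy genome, so region shares (e.g.
the intergenic fraction) are not those of a real mammalian genome.

What the generator does **not** emulate: mappability and sequencing error,
fragment-length structure (reads are 5'-point events, matching how the
pipeline counts), isoform structure beyond one model per gene, biological
replicate variance beyond Poisson/multinomial sampling, and realistic
genome-wide gene spacing. Passing recovery tests therefore demonstrate the
pipeline's correctness on data with the assumed structure, not robustness to
artefacts real libraries contain.

# Determinism and numerical conventions

Every stochastic step derives its seed from a single master seed (fixed RNG
kind, Mersenne-Twister/Inversion/Rejection), and the full pipeline is
byte-identical across runs with the same config — asserted by md5 in the
tests. Degenerate inputs have defined behaviour rather than errors where a
value is representable: empty peak sets report n = 0 with a flag, zero
totals are errors, constant clustering rows are dropped with a warning,
windows without variance report p = 1. Ties break by gene id (stratification)
or lexicographic leaf label (clustering). Tail summations for the exact test
run in log space; the minimum-likelihood comparison uses a 1e-7 relative
slack, the same convention as `binom.test`.

# Problem sizes used by the tests

The default simulation is 2000 genes at 2e6 reads and 1e6 tags — large
enough that planted-geometry recovery is comfortably powered. The two-group
recovery runs use 400 genes at 4e5 reads with 40 affected genes; null
calibrations use 50 replicates of 2000-gene libraries at 5e5 tags (DE) and
200 replicates of the window test; pipeline determinism runs use 200–300
genes. These sizes are the package's own choices for desk-scale, seeded,
single-CPU verification.

# Known limitations

* The window comparison treats genes as independent replicates; genes with
  correlated promoter signal (clustered paralogues) would violate that.
* The exact DE test assumes tag sampling is multinomial per library;
  overdispersion across biological replicates is not modelled (libraries are
  pooled per group before testing).
* Multilabel percentages are not a partition; downstream arithmetic that
  assumes fractions summing to one must use exclusive mode.
* The centroid linkage can produce inversions (non-monotone merge heights),
  as centroid linkages do; the dendrogram object preserves them.
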