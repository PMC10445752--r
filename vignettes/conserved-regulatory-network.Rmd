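---
title: "Methods: conserved regulatory network inference from single-nucleus chromatin accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved regulatory network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## The problem

Invasive trophoblast cells (extravillous trophoblast in human) remodel the
uterine vasculature during placentation. Single-nucleus ATAC-seq over the
uterine-placental interface yields a peak × nucleus fragment-count matrix
with cell-type labels transferred from matched expression data. The goal is
a bipartite network of transcription-factor families and target genes
supported by four independent lines of evidence: cell-type-specific
accessibility at two gestational stages, cross-species conservation of the
element, an enriched binding motif of an expressed factor, and
invasive-population-specific expression of the target.

## Differential accessibility model

Cell-type-specific peaks are called one-vs-rest per stage with a
likelihood-ratio test between two logistic regressions of population
membership:

- full: `logit P(y=1) = b0 + b1*a + b2*log(depth)`
- null: `logit P(y=1) = b0 + b2*log(depth)`

with `a = log(1 + 1e4 * count / depth)` the log-normalized accessibility
and `depth` the nucleus's total fragments in peaks. Putting `log(depth)` in
both models absorbs the dominant technical covariate of snATAC data, so
the single-df chi-square on the deviance difference tests accessibility
beyond depth. Assumptions: nuclei are independent given their labels, and
depth enters membership log-odds linearly on the log scale.

The effect size is reported as `log2((m1 + 1)/(m0 + 1))` with `m` the group
means of the linear normalized accessibility `1e4 * count / depth`; the
pseudocount of 1 on this scale keeps fold changes of near-empty peaks
bounded and makes the `log2(1.5)` specificity threshold meaningful.
P-values are Benjamini-Hochberg adjusted within a comparison; a peak is
*specific* at adjusted p ≤ 0.05 and log2FC ≥ log2 1.5. The identical model
with stage membership as the outcome gives the between-stage test.

Numerical choices: the null model is fitted once per comparison (it does
not depend on the peak). Fits use IRLS to a deviance tolerance of 1e-10. A
constant predictor (for example an all-zero peak) short-circuits to
statistic 0 and p = 1. Complete separation — common when an effect is
strong — drives the full-model deviance to its numerical floor; such fits
are accepted (the statistic is then the null deviance, a finite,
conservative value) rather than flagged as failures. Genuine
non-convergence is reported as p = 1 with `converged = FALSE`, never
silently.

## Normalization and gene activity

`tfidf_normalize` implements the log-TF × log-IDF variant,
`log1p(1e4 * count/depth) * log1p(n_nuclei / n_with_peak)`, the form suited
to very sparse matrices with heavy count outliers; zero counts map exactly
to zero. `gene_activity` sums fragments in the half-open window
`[tss - 2000, tss + 2000)` around each strand-aware TSS and averages the
depth-normalized value (`× 1e4`) per cell type — the window form rather
than a gene-body variant, because the TSS window is what the dot-plot and
expression-coupling summaries use.

## Peak-gene association

Peaks are linked to the nearest same-chromosome TSS. Distance is the gap
between the TSS and the peak's half-open interval boundary (a TSS at
`end + d` or `start - d` is at distance `d`; a TSS inside the peak is at
distance 0); magnitudes drive all thresholds, while the stored sign is
strand-aware (upstream negative). Ties are broken toward the
lexicographically smaller gene id and flagged. The reference-species
variant caps the association at 1 Mb and leaves farther peaks unassigned.
Summaries built on the links: the distal fraction (strictly greater than
5 kb), peaks-per-gene counts, a Wilcoxon comparison of expression between
genes with many versus few peaks, marker-list overlap (hypergeometric),
and generic over-representation analysis against a user-supplied GMT with
the enrichment-rate (observed/expected), minimum-observed (≥ 5) and FDR
(< 0.05) filters.

## Peak-set logic and conservation

The common-peak rule keeps a query peak when a partner covers at least 50%
of the query's bases (bedtools `-f 0.5` semantics, boundary inclusive); a
reciprocal mode is available. Cross-species transfer uses a deliberately
simple mapping dialect — equal-length source/target blocks, a peak maps iff
it falls entirely inside one block, minus-strand blocks mirror the offset —
because the pipeline needs the mapping contract, not chain-file parsing.
Conservation is ≥ 1 bp overlap with a reference open-chromatin set;
proportions are compared with the Yates-corrected one-sided two-proportion
test and mark support with a one-sided Fisher test whose universe is an
explicit argument (we use the mapped peak universe in the analysis
scripts; the right universe is genuinely ambiguous and so is never
defaulted).

## Motif scanning and enrichment

PWMs are probability matrices; JASPAR-style counts are converted with a
total pseudocount of 0.8 distributed by the background base frequencies.
Scanning scores log2 odds against the background, discretized at 1e-3.
The hit threshold for a motif is the smallest *achievable* window score
whose exact null tail probability (computed by position-wise convolution of
the discretized score distribution) is at most the cutoff, default 5e-5.
Scanning uses the same discretized scores on both strands, so the
threshold's semantics are exact — the tests verify the dynamic program
against full enumeration for short motifs. `N` bases never match;
sequences shorter than the motif are simply not hit. The achievable-score
canonicalization matters only for reporting: any threshold in the gap
between achievable scores selects the same hit set.

Backgrounds are drawn with replacement from a candidate pool (50,000 draws
by default), weighted so the joint GC-decile × length-decile distribution
(deciles from the foreground) matches the foreground; foreground bins
missing from the pool fall back to the nearest populated bin with a
warning, and the realized maximum bin deviation is reported. Per-motif
enrichment compares hit fractions (fold change) with a hypergeometric tail
on the pooled counts, BH-adjusted across motifs. Motifs are then filtered
on TF expression at both stages (≥ 0.5, inclusive; a dimer survives if any
constituent passes) and grouped into families; the enrichment filter is
applied per motif *before* grouping, the stricter of the two orders. A
family hits a peak when any member motif does (union), its representative
is the member with the highest fold change among motifs of the family's
two most expressed TFs, and pairwise family co-occurrence (shared target
genes; shared peaks) is tested with hypergeometric tails, BH-adjusted
within each matrix.

## Network assembly

An edge (family → gene) requires a conserved common peak carrying the
family's motif whose nearest gene is the target, with the target on the
conserved-marker list; mediating peaks are recorded on the edge, duplicate
(family, gene) pairs collapse, and in-degree (distinct regulating
families) ranks the targets. Export formats: a lossless edge TSV, SIF, and
GraphML via igraph.

## Statistical conventions

All over-representation tails are `P(X ≥ k)` — the upper tail including
the observed value — fixed once in `stats_core`; the lower-tail variant is
exposed as an argument. Wilcoxon tests take the exact path up to a
combined sample size of 20 when untied, otherwise the normal approximation
with tie and continuity correction; fully tied samples return p = 1. The
two-proportion test keeps the Yates correction, matching the convention of
the R function it mirrors; a degenerate pooled proportion (no successes,
or all successes) returns p = 1. Spearman's rho uses average ranks with a
two-sided t-approximation p-value and refuses zero-variance ranks.

## The synthetic-data generator

The generator emulates the study design the pipeline targets: two
"gestational-day" datasets over a shared peak universe, five labeled cell
types with the invasive population first, lognormal sequencing depths, and
Poisson fragment counts whose per-peak rates are multiplied in the planted
cell-type-specific peaks. Defaults (all in `sim_config`): 1000 peaks of
300-500 bp on a 2 × 2 Mb two-chromosome genome; 80 nuclei per type per
stage; depths lognormal(meanlog 8, sdlog 0.35), i.e. roughly 1200-7500
fragments, inside the usual QC range; 50 specific peaks per type per stage
with 80% shared between stages; a threefold rate effect — enough for the
planted peaks to clear both the significance and the fold-change
thresholds at this sample size without being trivial; per-peak GC drawn
from N(0.45, 0.08) clamped to [0.25, 0.65]; each of five high-information
12-bp motifs planted (as its consensus, random strand, non-overlapping
positions) into 30% of the shared invasive-specific peaks; 60% of peaks
covered by the cross-species mapping; and per-type expression
`0.2 + activity/10 + N(0, 1)` truncated at zero. The noise SD of 1 was
calibrated once so that the Spearman correlation between promoter-window
accessibility and expression falls in the 0.4-0.6 band — the moderate
coupling regime reported for real single-cell multi-omic data — and is a
generator property, not a reproduction of any measured value. The implied
ground truth (specific peaks, motif placements, and the family → gene
edges that survive conservation and marker filtering) is emitted as JSON.

A `noiseless_config` raises the effect to tenfold, tightens depths, zeroes
the expression noise and drops the scan cutoff to 1e-7; under it every
planted signal is recoverable and chance motif hits are vanishingly rare,
which is what makes the exact end-to-end network-recovery test meaningful.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: zero inflation and Tn5 insertion bias in
the counts (counts are plain Poisson); fragment-length structure; doublets
and label-transfer errors (labels are exact); genomic sequence composition
(background sequence is iid with the drawn GC); degenerate or overlapping
real motifs (the built-in set is near-orthogonal); peaks-per-gene
expression gradients (expression couples to the promoter window only, so
the many-vs-few-peaks comparison is expectedly null on synthetic data);
and real liftover edge cases (split or partially deleted blocks).

## Problem sizes and determinism

The test and acceptance workloads use the generator's default scale (1000
peaks × 400 nuclei per stage; 2000 peaks × 400 nuclei for null
calibration; 50,000 background draws), sizes at which every stage's
behavior — calibration, sensitivity, enrichment, exact recovery — is
measurable while a full run stays inexpensive. A fixed seed makes a bundle
byte-identical across runs; the acceptance script derives all of its seeds
from its `--seed` argument.

## Known limitations

The LR test treats nuclei as independent and ignores replicate structure
(pregnancies); a pseudo-replicate-aware test is out of scope. The motif
scan calls presence, not affinity, and family aggregation by hit union
cannot distinguish which member bound. Nearest-TSS assignment is a
heuristic — enhancers can skip genes — and the network inherits that
assumption. On default (noisy) settings the network recovers planted edges
with high recall but picks up extra edges from chance motif hits at the
5e-5 cutoff; the stricter noiseless cutoff removes them, which is the
standard specificity/sensitivity trade of motif calling.
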