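---
title: "Methylome-transcriptome integration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome-transcriptome integration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrlink)
```

## The problem

Drought reshapes plant DNA methylomes, most visibly in the asymmetric
CHH context, and part of that reshaping propagates into transcription.
Given WGBS and RNA-seq data for two contrasting phenotype groups (here
called *tolerant* and *sensitive*, six genotypes each) under control
and drought treatments, the pipeline answers three questions:

1. Which regions change methylation under drought, per genotype and
   conserved within a group?
2. Which genes change expression?
3. Which genes show the canonical *negative* coupling — methylation up,
   expression down (or vice versa) — and of those, which sit in
   pathways perturbed at both molecular layers?

## Differential methylation

### Window test

Smoothing-based DMR callers model spatial correlation of methylation
levels; this package deliberately uses a simpler, fully transparent
stand-in so that its behaviour is checkable against ground truth.
Counts are pooled per 200-bp window sliding by 50 bp. For a window with
pooled methylated/total counts $(m_d, t_d)$ under drought and
$(m_c, t_c)$ under control, we test equality of proportions with the
exact conditional (hypergeometric) distribution of $m_d$ given the
margins, doubling the smaller tail and capping at 1. The doubled-tail
form is chosen over summing point probabilities because it vectorises
over tens of thousands of windows; it is never anti-conservative
relative to the summed form.

Windows require at least `min_cytosines = 4` covered in-context
cytosines in **both** conditions; sparser windows are skipped silently
rather than tested on vapour. Significant windows (`p < 0.05`) of the
same sign that overlap or are book-ended are unioned.

A subtlety worth recording: a merged region's effect size is taken from
its strongest constituent window, not recomputed over the union.
Boundary windows straddle the true region's edge, so a union-level
recomputation systematically dilutes |Δ| — with a planted Δ = 0.40 CHH
region the union-level estimate can drop to ~0.20 and fail the CHH
threshold. Peak-window reporting removes this bias; region coordinates
still cover the full merged span.

### Thresholds and conservation

Significant DMRs must strictly exceed per-context |Δ| thresholds of
0.20 (CG), 0.15 (CHG) and 0.25 (CHH), on the fraction scale, with
Δ = level(drought) − level(control) so that positive Δ means
drought-induced hypermethylation. Thresholds are applied to
per-genotype DMRs *before* group merging (filter → merge); the merge
joins regions with a gap of at most 100 bp, inclusive — gap 100 merges,
gap 101 does not — matching common interval-merge semantics. A merged
region's support is the number of distinct contributing genotypes, and
regions with support < 3 are discarded: a change seen in fewer than
half the genotypes of a group is treated as idiosyncratic rather than
group-characteristic. The merged mean Δ averages per-genotype means so
a genotype fragmented into many pieces does not dominate.

## Differential expression

DESeq2-style dispersion modelling is out of scope; the stand-in keeps
the two elements that matter downstream: median-of-ratios size factors
(robust to composition) and an honest p-value. The log2 fold change is
`log2((mean normalised drought + 0.5) / (mean normalised control +
0.5))`; the pseudocount of 0.5 bounds fold changes for low-count genes.
The p-value is a Welch t-test on `log2(normalised + 0.5)`, BH-adjusted.
On null simulations the raw-p false-positive rate at 0.05 stays below
0.075 (tested), and planted log2FC = 2 effects at n = 6 per arm are
estimated within ±0.3 (tested). Precomputed DE tables (gene, log2fc,
pvalue, padj) can be supplied wherever the stand-in's output is
accepted, so DESeq2 results drop in directly.

Genes with total counts below 10 are removed first; DEGs satisfy
`padj < 0.05` and `|log2FC| > 1`, both strict.

## Integration

DMR-gene association uses ≥ 1 bp overlap with the gene body or the
strand-aware 2-kb flanks; placement precedence is gene body >
upstream > downstream, so a DMR spanning the TSS counts as gene body.
When several DMRs link to one gene, the per-gene Δm is the
length-weighted mean per context, then averaged across contexts — a
context with many small regions should not outvote one with a single
large region. A "strongest DMR" mode is available for sensitivity
analysis.

The screen keeps genes with `|Δm| > 0.05` (strict) and opposite signs
of Δm and log2FC. The priority score is

$$\text{Priority} = |log_2FC|\cdot 1 + |\Delta m|\cdot 5 +
  \text{phenotype coverage}\cdot 10 + \text{data completeness}\cdot 5 +
  \ln(\text{DMR count})\cdot 2$$

The weights are fixed; the operational definitions of two terms are
this package's own, documented choices because only the weights are
standard: *phenotype coverage* is the number of groups (1 or 2) in
which the gene passes the screen, and *data completeness* is the
fraction of the relevant groups' samples with at least one covered
cytosine in the gene ± 2 kb **and** a nonzero count for the gene. The
logarithm is natural by default ("log" being otherwise unqualified);
the base is exposed as an argument. Ties in the ranking break by gene
id for reproducibility.

Enrichment is the plain hypergeometric upper tail against a
user-supplied gene→term map, BH-corrected, significant at
`padj < 0.01`. The universe is a consequential and often unstated
choice: here it is the genes surviving the low-count filter, and it is
an explicit argument so users can substitute e.g. all genes with
covered flanks for the methylation side. Terms significant in all four
(group × layer) sets form the core module; candidates inside core
pathways are hub genes.

## The synthetic-data generator

`simulate_study()` emulates the study design: 6 + 6 genotypes × 2
treatments, per-cytosine binomial counts around per-context baselines
taken from a *B. napus* control methylome (CG 92.31 %, CHG 46.76 %,
CHH 32.16 %), Poisson coverage (default mean 30, a typical WGBS
depth), and gamma-Poisson (negative binomial, dispersion 0.05) counts
with relative library sizes in [0.8, 1.2]. Cytosine sites are placed
at 0.25 sites/bp with context mix CG 15 % / CHG 20 % / CHH 65 %,
roughly the density and composition of a plant genome; sparser
placements starve the 4-cytosine window minimum for the rarer contexts.

Two latent layers control calibration. Each site draws a level from a
Beta around its context baseline (concentration 60, site
heterogeneity), and each genotype jitters that level (concentration
200). Crucially, control and drought share the genotype-level latent
level wherever nothing is planted, so within-genotype tests are exactly
null — the basis for the null-calibration tests. Between-genotype
variation exists but does not enter the control-vs-drought contrast.

Planted features: DMRs shift the latent level of the target group's
drought samples by Δ inside placed regions (validation rejects Δ that
leaves [0, 1]); placement favours C-subgenome chromosomes with weight
0.67, reflecting the C-subgenome bias of epigenetic remodelling in
allopolyploid *B. napus*. DEGs multiply count means by $2^{log_2FC}$.
Negative-regulation genes combine an upstream-flank methylation shift —
half the genes hyper-CHH (+0.35, paired with log2FC ~ −U(1.5, 3)), half
hypo-CHG (−0.30, paired with +U(1.5, 3)) — placed 1.2–1.8 kb before the
TSS, strand-aware; the promoter placement mirrors where such regulation
concentrates in real data, and the two-sided planting makes the
candidate (Δm, log2FC) scatter genuinely negatively correlated rather
than a one-sided point cloud. The gene→term map adds a three-term
"stress module" carried by the negative-regulation genes of both
groups, so the four-way pathway intersection has a real core to find.

What the generator does **not** emulate: read-level data (no FASTQ, no
bisulfite-conversion error), spatial methylation structure around genes
(baselines are flat across features, so metagene U-shapes only appear
when constructed), RdDM mechanism, linked genetic variation, and
replicate structure richer than i.i.d. draws (the published design has
3 biological × 2 technical replicates; the generator defaults to 1 per
genotype × treatment and exposes `n_replicates`). Passing recovery
tests therefore demonstrate correctness of the *pipeline logic* under
the stated noise model, not performance on real methylomes.

## Numerical and degenerate-input choices

* Coverage filter for level computation: ≥ 4 reads (standard WGBS
  practice; no published cutoff to follow), configurable. Zero-coverage
  cytosines are retained by the parser but excluded from levels.
* "No data" is `NA`, never 0 — an uncovered region has no level.
* Weighted levels (Σ meth / Σ total) rather than means of per-site
  ratios, the field standard for count data.
* Expression groups: genes at exactly 0 form "none"; the rest split
  into rank-based quintiles with ties broken by gene id, making
  membership invariant under monotone transforms of expression.
* Genes shorter than the bin count are binned by fractional
  coordinates rather than rejected.
* Correlations with n < 3 or a constant variable return `NA`
  ("no data"), not an error; empty enrichment universes and empty core
  sets degrade with warnings, not crashes.
* All internal coordinates are 0-based half-open; 1-based closed only
  at the GFF3/CX boundaries. Subgenome attribution is by chromosome
  name (`A##` / `C##`, scaffolds → "other").

## Problem sizes used in the shipped tests

The test suite and acceptance script run desk-scale studies: 2
chromosomes of 100–150 kb, 40–60 genes, 6 + 6 genotypes at coverage 30
for recovery/calibration batches (8–20 independent seeds), and a
350-kb genome for the law-of-large-numbers check of baseline levels
(> 10^5 CHH sites). These sizes were chosen as the smallest at which
every stage operates in its intended regime — windows meet the
cytosine minimum, BH has hundreds of genes, support filtering has six
genotypes to count — while keeping a full batch in tens of seconds.

## Known limitations

* The window test ignores spatial correlation and biological
  replicate variance within a condition (counts are pooled); DSS-style
  smoothing would be strictly better on real data and its output can be
  ingested via the significant-DMR entry point.
* The DE stand-in does not share dispersion information across genes;
  at n = 6 per arm it is serviceable but less powerful than DESeq2.
* Correlation units: published per-group candidate correlations can be
  reported with n's that exceed the candidate gene count (e.g. when
  computed per gene × DMR pair); this package computes one r per group
  over candidate *genes* and reports that n alongside.
* The "common DMR" tier between groups is defined here as ≥ 1 bp
  overlap of same-context conserved DMRs; other operational definitions
  exist and would change that tier's counts.
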