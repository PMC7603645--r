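---
title: "Charting aging-regulated lncRNAs across tissues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charting aging-regulated lncRNAs across tissues: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncage)
```

## The analysis in one paragraph

`lncage` takes a gene-level read-count matrix from a multi-tissue,
multi-age bulk RNA-seq design (the reference design is 11 mouse tissues
sampled at 8, 26, 60, 78 and 104 weeks with 5 replicates each, 275
libraries in all) and asks three questions. Which genes — and in
particular which long non-coding RNAs (lncRNAs) — are regulated during
aging in each tissue? How tissue- and age-specific are they, and does
tissue specificity predispose a lncRNA to aging regulation? And how does
the co-expression coupling between aging-regulated (AR) lncRNAs and AR
mRNAs grow as tissues age? Because raw sequencing data at this scale is
not a practical test substrate, the package ships a seeded
negative-binomial study generator that plants all three kinds of
structure with known labels, so every stage of the pipeline can be
scored against ground truth.

## Expression quantification

Counts are normalized between samples with the trimmed mean of M-values
(TMM, via edgeR: reference sample chosen by the upper-quartile rule,
30%/5% trims on M/A values, factors rescaled to geometric mean 1) and
converted to FPKM using `count / (length_kb x effective library in
millions)`, where the effective library is the column sum times the TMM
factor. A gene is *detectable* when its FPKM strictly exceeds 0.5 in at
least 20% of samples (sample count rounded up); detectable genes enter
all downstream stages as `log2(FPKM + 1)`. The pseudocount of 1 is the
conventional choice for count-derived abundance and is configurable.
Detectability is assessed per tissue by default — the natural unit for
per-tissue calling — with a global option (`detect_scope = "global"`)
for a single filter across all samples; the reference protocol does not
state which scope was used, so both are provided rather than guessed.

## Aging-regulated genes

Two callers are provided. The *aging-correlation* caller computes the
Pearson correlation between `log2(FPKM + 1)` and log2(age in weeks) over
all samples of a tissue and calls genes with `|r| > 0.9` and `P < 0.05`
(t-transform with n − 2 degrees of freedom; both signs reported).
Correlation is computed over replicate samples, not per-age means, with
a per-age-mean mode available. The *differential-expression* caller runs
a per-gene Welch t-test on log2 expression for each older age against
the youngest (8 weeks), with Benjamini–Hochberg adjustment within each
tissue-by-contrast family. A gene is *aging-regulated* (AR) when
`|log2FC| > 0.75` and `FDR < 0.1` — both strict — in the 78-week or the
104-week contrast. Its reported `log2FC(old/young)` is the signed fold
change of larger magnitude among those two contrasts, so down-regulated
genes keep their sign. Genes qualifying in both contrasts with opposite
signs are kept and flagged `"discordant"` rather than silently resolved.
The Welch test is a deliberate, simple stand-in for moderated linear
models: with five replicates per group and the fold-change gate doing
most of the work, empirical-Bayes shrinkage changes little, and the
threshold semantics stay exactly as stated.

## Specificity scores

For a gene *i* and category *j* (tissues at a fixed age, or ages within
a fixed tissue), the fractional expression is the category mean of
linear FPKM divided by the sum of category means; the specificity score
is the maximum fraction (1 = exclusive, 1/k = uniform across k
categories). Fractions are computed on linear FPKM because log-scale
"fractions" can be negative and are no longer proportions. Tissue
fractions are computed at each age point separately; lncRNAs are ranked
by score per age point, with the top 20% taken as tissue-specific and
the bottom 20% as universally expressed controls (sizes
`floor(0.2 x n)`, ties broken deterministically by gene id). The
regulation-shift analysis then compares the two groups' `log2FC(old/
young)` distributions (ECDFs over signed and absolute fold change,
two-sided Mann–Whitney) and their AR rates.

## Tissue similarity

Two tissues' AR sets are compared with a weighted combination of the
Jaccard index and the overlap coefficient:
`0.8 x |A∩B|/|A∪B| + 0.2 x |A∩B|/min(|A|,|B|)`. A literal reading of
"0.8 times the union plus 0.2 times the intersection" as raw
cardinalities is not dimensionless and is unbounded; the enrichment-map
style combination above is the standard bounded, symmetric coefficient
built from exactly those two ingredients, and the raw-cardinality
reading remains available (`mode = "raw"`) for audit. lncRNA and mRNA
matrices are built separately so the two triangles can be compared, and
an abundance-matched comparison (quantile-binned mean expression, equal
draws per bin from each biotype) guards against the ~4-fold lower
abundance of lncRNAs driving the difference.

## Stage-binned co-expression networks

Samples of a tissue are pooled into four stages of adjacent ages
(8&26, 26&60, 60&78, 78&104 weeks). Within each stage, every AR-lncRNA
is correlated with every AR-mRNA (per-gene z-scoring within the stage is
applied; it is cosmetic for Pearson r), and an edge is significant when
`r > 0.9` — signed, as stated; an absolute-value mode is configurable —
and BH-adjusted `FDR < 0.05` over all pairs of that tissue-by-stage
scan. The *consensus network* is the union of edges significant in the
youngest or the oldest stage, each edge carrying its correlation in all
four stages. Union rather than intersection is the default because the
growth analysis is about edges that *emerge* late, which an intersection
would discard; intersection is available via
`pipeline_config(consensus_mode = "intersection")`. Modules are
communities found by walktrap (10-step random walks on the unweighted
graph; optional stage-4-weighted walks) and retained when they have more
than 30 genes. Growth is summarised per stage as the mean |r| over all
AR-lncRNA~AR-mRNA pairs, the count of super-threshold pairs, and
per-module mean |r|, with a strict-increase flag. For guilt-by-
association annotation, each AR-lncRNA's partner list is every
detectable mRNA with `r > 0.8` and adjusted `P < 0.05` over all the
tissue's samples.

## Enrichment

Gene-set enrichment is a local hypergeometric test over a GMT
collection: terms restricted to the background (the tissue's detectable
genes — the defensible default when the original web-service background
cannot be recovered), kept when their in-background size is between 10
and 400, reported when the overlap is at least 5, and called significant
at BH `FDR < 0.1`. The upper-tail probability is the plain
hypergeometric `P(X >= k)`; the EASE variant (overlap deflated by one)
is available behind `ease = TRUE`. Recurrence across tissues is a simple
tally of tissues in which a term is significant.

## The synthetic study generator

`generate_study()` draws counts `NB(mu, size = 1/dispersion)` with a
log-normal baseline (log2 mean 1, sd 2; lncRNA baselines shifted −2,
i.e. ~4× lower), per-gene-per-tissue identity effects (log2 sd 0.5),
per-sample sequencing depth (2 million ± 0.25 log2), and three kinds of
planted structure:

* **Aging genes** follow a log-linear trend in log2(weeks) reaching the
  configured log2 fold change (default 2) between 8 and 104 weeks, up
  and down in equal numbers per tissue.
* **Tissue-specific genes** are boosted 8× in one tissue and carry 3×
  the aging effect there, anchored at the youngest age so the boost
  equals the planted enrichment at baseline; this builds in the
  "tissue-specific lncRNAs are preferentially aging-regulated" signal
  that the regulation-shift analysis is designed to detect.
* **Modules** share a latent per-sample factor whose variance follows a
  4-stage coupling schedule. A schedule value c sets the factor variance
  to `2c/(1−c)` times the residual log2 noise variance — a within-module
  correlation of `2c/(1+c)`, about 0.95 at full coupling 0.9 — so a
  fully coupled module clears the `r > 0.9` edge rule rather than
  straddling it. Stage values are converted to per-age variances by
  telescoping the stage averages, and the factor is standardized within
  each age group so the planted coupling is realized exactly instead of
  up to the sampling noise of five replicates. Module genes additionally
  carry a late-onset aging trend (default log2 fold change 4, one
  direction per module) following the shape of the coupling schedule,
  which makes them AR — a prerequisite for appearing in the
  AR-lncRNA~AR-mRNA networks at all.

Genes with planted effects are drawn above a baseline floor (one log2
below the baseline mean): detectability censoring is a property of the
filter, not of the callers, and recovery metrics should measure the
callers. All randomness flows from a single integer seed; identical
configurations reproduce identical studies bit for bit.

What the generator does **not** emulate: batch effects, isoform-level
variation, read-level artefacts, GC/length bias beyond the FPKM length
term, tissue-correlated noise, or realistic effect-size distributions —
the defaults are calibration choices, not estimates of real aging
effects. Passing recovery tests therefore demonstrates that the
pipeline's machinery is correct and calibrated on data satisfying its
own assumptions, not that real tissues behave this way.

## Numerical choices and degenerate inputs

Strict inequalities are used at every stated threshold (detectability,
correlation, fold change, FDR, specificity thresholds, module size).
Zero-variance genes are excluded from correlation and edge scans and
flagged, never errors; zero-total genes are excluded from fractional
profiles and recorded. Quantile groups and abundance matching break ties
by gene id so results are reproducible. Empty consensus networks return
a warning, not an error, and yield zero modules. All-zero samples and
missing gene lengths abort with the offending ids named.

## Problem sizes used by the test suite

The packaged checks run a scaled-down study — 3 tissues × 5 ages × 5
replicates × 2,000 genes, seed-replicated three times — with 100
aging-up and 100 aging-down genes per tissue (log2 effect 2, dispersion
0.1), 300 tissue-specific genes (boost 8×), and one 40-gene module with
coupling schedule (0.1, 0.3, 0.6, 0.9). These sizes keep each replicate
under a few seconds while leaving every recovery quantity (sensitivity,
false-discovery proportion, top-decile specificity occupancy, module
Jaccard, stage-wise correlation growth) estimable with comfortable
margins. Calibration checks use 5,000 null genes for the correlation
tail, 10 × 2,500 null pairs for edge FDR, and 100,000-shuffle
permutation oracles for the Mann–Whitney and correlation p-values.

## Known limitations

* The Welch t replaces moderated models (limma/edgeR); with few
  replicates and no fold-change gate it would be anti-conservative for
  low-variance genes.
* The consensus rule, signed-edge rule and the exact U/I semantics of
  the similarity score are pinned interpretations of under-specified
  protocol text; each has a config escape, and none is asserted to be
  the original authors' computation.
* Specificity scores are maximum fractions, which saturate for genes
  expressed in a single category; entropy- or tau-style indices are out
  of scope.
* The hypergeometric test treats genes as exchangeable; no GO-DAG
  propagation or term-term redundancy collapsing is performed.
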