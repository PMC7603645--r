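# lncage

Multi-tissue aging-transcriptome analysis of lncRNAs and mRNAs in R.

## The problem

Aging reshapes the transcriptome of every organ, but it does so
organ-specifically, and the long non-coding RNAs (lncRNAs) — more
tissue-restricted than mRNAs — are a sensitive readout of that
specificity. Given a gene-level read-count matrix from a multi-tissue,
multi-age bulk RNA-seq design (the reference design: 11 mouse tissues ×
5 ages (8, 26, 60, 78, 104 weeks) × 5 replicates = 275 libraries),
`lncage` identifies **aging-regulated (AR)** genes per tissue, measures
their tissue- and age-specificity, compares tissues by the similarity of
their AR sets, and tracks the growth of AR-lncRNA~AR-mRNA co-expression
networks across life stages. It is aimed at computational biologists who
want the full analysis as tested, reusable functions rather than a
one-off script collection.

## The method at its core

* **Quantification** — TMM-normalized FPKM; a gene is detectable iff
  FPKM > 0.5 in ≥ 20% of samples; analysis on log2(FPKM + 1).
* **Aging-correlated genes** — Pearson *r* between log2 expression and
  log2(weeks); called at |r| > 0.9, P < 0.05.
* **AR genes** — Welch t per gene, old (78w or 104w) vs young (8w);
  called at |log2FC| > 0.75 and BH FDR < 0.1; the reported
  log2FC(old/young) is the larger-magnitude signed fold change of the
  two old contrasts.
* **Specificity** — fractional expression T<sub>ij</sub> = mean FPKM of
  gene *i* in tissue *j* / Σ<sub>j</sub> mean FPKM; score = max
  fraction; top/bottom 20% define tissue-specific vs control genes.
* **Tissue similarity** — 0.8 × Jaccard + 0.2 × overlap coefficient
  between two tissues' AR sets.
* **Networks** — samples pooled into 4 stages of adjacent ages; edges
  with r > 0.9, FDR < 0.05 per stage; consensus = union of stage-1 and
  stage-4 edges; walktrap modules (10 steps) with > 30 genes; per-stage
  mean |r| as the growth metric; partner lists (r > 0.8, adj. P < 0.05)
  for guilt-by-association annotation.
* **Enrichment** — local hypergeometric test over a GMT collection,
  term size 10–400 in the detectable background, overlap ≥ 5,
  FDR < 0.1.

A seeded negative-binomial generator (`generate_study()`) plants aging
trends, tissue-specific boosts and latent-factor co-expression modules
with known labels, so the whole pipeline can be scored against ground
truth (`recovery_report()`). See the vignette
(`vignettes/aging-lncRNA-landscape.Rmd`) for the model and every design
decision.

## Worked example

```r
library(lncage)

cfg   <- study_config(n_tissues = 3, seed = 1)   # scaled-down study
study <- generate_study(cfg)
study
#> Synthetic aging study: 2000 genes x 75 samples (3 tissues x 5 ages x 5 reps)
#>   planted aging labels: 940; tissue-specific: 300; modules: 1

fit <- aging_landscape(study$counts, study$samples, study$genes,
                       truth = study$truth)
fit
#> aging_landscape: 3 tissue(s), 75 samples, 2000 genes
#>         tissue detectable aging_correlated ar_lncRNA ar_mRNA network_edges
#> 1        brain       1971              109        99     261          1164
#> 2 hypothalamus       1975              115       104     209           943
#> 3         lung       1978              111        78     230           850
#>   modules
#> 1       3
#> 2       2
#> 3       2
```

Per tissue, roughly 2,000 genes pass the detectability filter, ~110 are
aging-correlated, and a few hundred are called AR (the planted 940
aging labels span the three tissues; the rest of each AR column is the
planted module and tissue-specific genes plus a small false-discovery
margin). The consensus networks carry hundreds of edges and 2–3
walktrap modules each. Because truth labels were supplied, the fit
carries a recovery report:

```r
rec <- fit$recovery
sprintf("AR sensitivity %.3f, FDP %.3f", rec$ar$sensitivity, rec$ar$fdp)
#> "AR sensitivity 0.980, FDP 0.061"
rec$modules$M01$stage_mean_abs_r
#> stage1 stage2 stage3 stage4
#>   0.53   0.72   0.82   0.92
```

The planted module's within-module correlation climbs from 0.53 in the
youngest stage to 0.92 in the oldest — the network-growth signature the
pipeline is built to detect — and the detected module matches the
planted one at Jaccard 0.87. `run_pipeline()` writes all per-tissue and
cross-tissue tables (TSV with threshold headers, GraphML networks, a
YAML run manifest) to an output directory; `inst/cli/lncage.R` wraps
`simulate` and `run` for shell use.

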