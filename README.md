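# paralogdose

Quantitative analysis of **paralog dose** for duplicated transcription
factors, modeled on STAT5A/STAT5B in mouse CD4⁺ T cells. When two
paralogs drive a largely shared transcriptional program, the useful
question is how much of that program each paralog carries. `paralogdose`
answers it from knockout expression profiling across an allele-dosage
series (WT, A-deficient, B-deficient), with optional ChIP-seq and
flow-cytometry layers.

## The statistics at the core

For every gene regulated in either knockout (absolute fold change > 1.5,
p < 0.05, on offset-normalized RPKM), each KO-vs-WT contrast yields a
**paralog score**

> score = |FC| × max(RPKM_WT, RPKM_KO)

and the gene's **paralog preference** is

> preference = log2(score_B / score_A),

positive when loss of paralog B hits the gene harder. Preferences are
reported as a 12-bin histogram (bin 1: below −5; bins 2–11: [−5,−4) …
[4,5); bin 12: 5 and above) with its median. On top of this sit:

* a **specificity classifier** (pan / A-specific / B-specific /
  excluded-opposite / unclassified) using the 1.5-fold regulation rule,
  a 1.2-fold "unchanged in the other knockout" ceiling, and a direct
  KO-vs-KO contrast;
* **relative abundance** estimates: `pct_B = 100·B/(A+B)` for mRNA, and
  for protein the WT-normalized MFI fold changes compared within
  one-allele and three-allele genotype pairs, ratios averaged, and
  converted to a percentage;
* **ChIP-seq occupancy integration**: peak retention (> 3-fold
  enrichment, p < 5×10⁻⁵), one-to-one cross-genotype peak matching,
  ±10 kb TSS assignment, and the nested occupancy hierarchy (WT-only →
  shared-by-all) related to WT peak height and expression variance;
* a seeded **synthetic-data generator** that plants all of the above as
  recoverable ground truth.

See `vignettes/paralog-dose-analysis.Rmd` for the full model description
and design rationale.

## Worked example

```r
library(paralogdose)
report <- run_pipeline(run_config(seed = 7))
print(report)
```

```
Paralog-dose pipeline report (seed 7)
  offset: 0.2458
  genes: 1000 input -> 1000 after collapse -> 370 after filter -> 291 pooled
  median paralog preference: 1.080 (n = 291)
  paralog-specific fraction: 12.0%
  peak counts: WT 1000, het 520, A-KO 480, B-KO 80 
  protein abundance: A 38.1% / B 61.9%
```

Reading the report: the offset (0.246) is the dataset's median RPKM;
1000 simulated genes shrink to 370 expressed ones and 291 regulated in
at least one knockout. The median preference of 1.08 ≈ log2(2) recovers
the planted 2-fold B-dominance asymmetry; 12% of regulated genes are
called paralog-specific; peak counts fall off steeply as the dominant
paralog is removed; and the allele-dosage MFI series (per-allele units
1:2) yields a 61.9% protein share for B.

Individual stages are plain functions — for example:

```r
mrna_paralog_percentages(25, 75)
#> Relative paralog abundance (mrna): A 25.0% / B 75.0%

bin_preferences(c(-1, 0, 3))   # 12-bin histogram, median 0
```

A thin command-line wrapper with subcommands `simulate`, `de`,
`preference`, `specificity`, `abundance`, `chip` and `run` is installed
under `exec/paralogdose`.

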