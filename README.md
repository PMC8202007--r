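# mirFFL

Analysis pipeline for six-group pooled miRNA sequencing designs used
to study sex disparity in liver tumorigenesis: wild-type normal liver
(W), peri-tumor precancerous tissue (P) and hepatic tumor (T) in males
and females, one pooled library per group (`MW, MP, MT, FW, FP, FT`),
with no replicates.

The package covers, end to end:

* **Normalization and QC** — TPM conversion, trimmed-mean-of-M-values
  (TMM) scaling factors, Pearson-R² / PCA / sequencing-saturation
  summaries.
* **No-replicate differential expression** — a conditional exact test
  on each count pair given its total: binomial at dispersion φ = 0,
  and for φ > 0 the conditional law of two negative binomials
  (variance μ + φμ²) with null means proportional to the TMM-adjusted
  effective library sizes, summed exactly over all splits of the
  total. Two-sided p by doubling the smaller tail;
  Benjamini–Hochberg q per contrast; DEMIR gate q ≤ 0.05 and fold
  change ≥ 2 (both inclusive).
* **Expression-pattern grading** — each miRNA's W/P/T trajectory per
  sex is mapped to a weak order graded 1/2/3 and classified into the
  named subtypes of four categories (HCC-positive `T>P=W, T=W>P,
  T>W>P`; Ras-positive `W<P=T, W<P<T`; HCC-negative `T<P=W, T=W<P`;
  Ras-negative `W>T=P, W>P>T`), with a ≥ 2-significant-contrasts
  recurrence filter and shared/unique calls between sexes.
* **Feed-forward-loop networks** — four regulatory relations
  (miRNA–gene, miRNA–TF, TF–gene, TF–miRNA) assembled from
  target-prediction scores (context score < −0.3 **and** target score
  > 50) and TF binding-scan scores (core score = 1.00, matrix score >
  0.95), an anti-correlation constraint on miRNA edges, enumeration of
  3-node FFLs typed TF-/miRNA-/composite-FFL (mutually exclusive),
  per-type sub-networks, and top-25%-degree hub extraction with ties.
* **Imprinted-region localization** — per-contrast and pooled counts
  and percentages of between-sex DEMIRs whose locus midpoint falls in
  a configured region (default: a placeholder interval for the
  Dlk1-Dio3 cluster on chr12), with up/down splits and a 2×2 exact
  enrichment test.
* **Over-representation** — upper-tail hypergeometric test of
  predicted targets of in-region DEMIRs against GMT gene sets, with
  Count / % / Log10(P) / Log10(q) reporting.
* **qPCR validation helpers** — the ΔΔCt rule
  `2^−(Ct_target − Ct_reference)`.
* **A seeded synthetic-data generator** that emulates every input with
  planted ground truth (true DEMIRs, true patterns, true FFLs, true
  in-region loci), so each stage has a recoverable answer key.

## Worked example

```r
library(mirFFL)
res <- runPipeline(defaultRunConfig(seed = 1))

head(res$records[res$records$significant, ], 3)
#>         mirna contrast log2fc   pvalue   qvalue significant direction
#> 1 miR-sim-001    MT/MP   2.69 3.93e-08 4.07e-07        TRUE        up
#> 2 miR-sim-002    MT/MP   4.01 9.44e-15 5.66e-13        TRUE        up
#> 3 miR-sim-003    MT/MP   2.16 6.32e-06 5.26e-05        TRUE        up
```

Each row is one miRNA in one pairwise contrast (here tumor vs
peri-tumor in males): the effective-size-normalized log2 fold change,
the exact-test p, its BH q, and the DEMIR call. On this simulated data
set (300 miRNAs, six libraries of 10⁷ reads, φ = 0.05, eight-fold
planted effects) the run calls 60 within-sex and 17 between-sex
DEMIRs; the pattern stage keeps 40 shared, 6 male-unique and 10
female-unique categorized miRNAs — the planted disparity structure.

```r
res$fflSummary$ffl
#> $total
#> [1] 16
#> $by_type
#> $by_type$`TF-FFL`       8
#> $by_type$`miRNA-FFL`    4
#> $by_type$`composite-FFL` 4

res$gir$pooled
#>   contrast inside outside unplaced total  pct up_in up_out down_in down_out
#> 1   pooled     10       7        0    17 58.8     4      3       6        4
```

All 16 planted feed-forward loops are recovered and typed correctly;
10 of the 17 between-sex DEMIRs (58.8%) localize to the configured
imprinted region, split into up/down and in/out cells. The
over-representation stage recovers the planted pathway among the
targets of in-region DEMIRs:

```r
res$enrichment[1, c("term", "count", "percent", "log10_p", "log10_q")]
#>              term count percent log10_p log10_q
#> 1 planted_pathway    20     100   -17.1   -16.8
```

`runPipeline(cfg, outDir = "out")` additionally writes every stage
table (`demirs.tsv`, `norm.tsv`, `patterns.tsv`, `ffls.tsv`,
`snw_nodes.tsv`, `gir_summary.tsv`, `enrichment.tsv`) plus
`report.json`. A thin command-line wrapper with `simulate | de |
patterns | ffl | gir | enrich | report` subcommands ships as
`inst/scripts/mirffl.R`; configurations are YAML
(`readRunConfig()`), with a full default block mirroring the
documented thresholds.

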