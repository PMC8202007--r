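---
title: "mirFFL: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirFFL: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirFFL)
```

# The design the package models

`mirFFL` analyses a six-library miRNA sequencing design used to study
sex disparity in oncogene-driven liver cancer: wild-type normal liver
(W), peri-tumor precancerous tissue (P) and hepatic tumor (T), in males
and females (`MW, MP, MT, FW, FP, FT`). Each library is a pooled
composite of several inbred animals, so there is **one library per
group and no biological replicates** — a design choice that shapes the
statistics throughout (see the exact test below).

The pipeline runs, in order: TMM/TPM normalization and QC; pairwise
no-replicate exact tests with Benjamini–Hochberg control and the
DEMIR gate (q ≤ 0.05 and fold change ≥ 2, both inclusive); grading of
each miRNA's W/P/T trajectory into expression-pattern subtypes and
categories; assembly of a miRNA–TF–gene regulatory network from
target-prediction and TF-binding score tables and enumeration of
3-node feed-forward loops (FFLs); localization of between-sex DEMIRs
relative to the Dlk1-Dio3 imprinted miRNA cluster; and hypergeometric
over-representation of predicted targets. A seeded generator
(`simulateAll()`) emulates every input with planted ground truth.

# Normalization

**TPM.** `tpmNormalize()` rescales each library to reads-per-million:
$tpm_{ig} = c_{ig}\,10^6/\sum_j c_{jg}$; every column sums to $10^6$
exactly.

**TMM.** `tmmFactors()` implements the trimmed mean of M-values:
for each library against a reference (the library whose total is
closest to the mean total), per-miRNA log2 count-rate ratios
$M_i$ are doubly trimmed — 30% on $M$ and 5% on the average log
abundance $A$ — and averaged with inverse asymptotic-variance weights;
the factor is $2^{\bar M_w}$, and factors are rescaled to geometric
mean 1. miRNAs with a zero in either library are excluded from the
$M$ computation. The unit test cross-checks the implementation against
edgeR's independent one at $10^{-10}$.

# The no-replicate exact test

With a single library per group the dispersion cannot be estimated, so
it is a configuration value: counts are modelled as negative binomial
with variance $\mu + \phi\mu^2$ and a fixed common $\phi$ (default
0.05, a plausible value for pooled composites of an inbred strain —
the emulated study never states one). For a contrast $a/b$ the test
conditions on the pair total $n = x_a + x_b$:

* $\phi = 0$: $X_a \mid n \sim \mathrm{Binom}(n,\; N'_a/(N'_a+N'_b))$
  with $N'$ the TMM-adjusted effective library sizes — the classic
  conditional binomial test.
* $\phi > 0$: the conditional law of $X_a$ given $n$ for two
  independent NB variables with null means proportional to the
  effective sizes, evaluated by summing the conditional mass over all
  $n+1$ splits of the total (a compiled kernel using the pmf ratio
  recurrence; both tails are accumulated directly to avoid
  cancellation).

The two-sided p doubles the smaller tail — each tail including the
observed point once — and caps at 1; this is the standard exact-test
convention. BH q-values are computed per contrast across all miRNAs.
Fold changes use effective-library-normalized counts with a
pseudo-count of 0.5, so zeros never produce infinite log fold changes.
Whether fold change should instead be computed on plain TPM is exposed
via the TMM factors argument (pass unit factors).

The DEMIR gate is inclusive at both boundaries (q = 0.05 and
|log2FC| = 1 count as significant), and a miRNA is a DEMIR when
significant in at least one pairwise contrast.

# Expression-pattern grading

For one sex, the three within-sex contrasts (T/P, T/W, P/W) each
contribute a relation: significant-up means numerator above
denominator, significant-down below, non-significant equal. A
consistent relation triple corresponds to exactly one of the 13 weak
orders of {W, P, T}; grades start at 1 for the lowest tissue and
increase by one per strict step. Nine weak orders carry the named
subtypes:

| category | subtypes |
|---|---|
| HCC-positive (a) | a1: T>P=W, a2: T=W>P, a3: T>W>P |
| Ras-positive (b) | b1: W<P=T, b2: W<P<T |
| HCC-negative (c) | c1: T<P=W, c2: T=W<P |
| Ras-negative (d) | d1: W>T=P, d2: W>P>T |

The all-equal order is `flat`; the three remaining strict orders
(P>T>W, P>W>T, W>T>P) are `other`. Contradictory triples (e.g. T>W,
W>P, T=P) admit no weak order; rather than forcing a grade they get
their own `inconsistent` label — the emulated study never addresses
them. The mapping is a pure function of the signed significance
triple, tested exhaustively over all 27 triples.

**Recurrence filter.** "Changed at least twice" is read as ≥ 2
significant contrasts among all six within-sex comparisons with both
sexes pooled, since the joint pattern display groups miRNAs across
sexes; a per-sex mode is available (`minSigMode = "per-sex"`).

**Shared/unique.** A miRNA is categorized in a sex when its subtype
belongs to a named category. Shared status requires the same
*category* in both sexes (not the same subtype), because the pattern
display groups miRNAs by direction class; conflicting categories are
`discordant`.

# The FFL network

Edges come from two score tables. miRNA–target pairs must pass
`context_score < −0.3` in one source **and** `target_score > 50` in
the other (pair-level intersection — the source sentence "merged …
present in both databases" is self-contradictory, and intersection
matches "present in both"; a union mode exists behind
`targetsMode = "union"`). TF edges require `core_score = 1.00` exactly
and `matrix_score > 0.95`. All three inequality gates are strict, as
written. miRNA–TF edges are miRNA–gene edges whose target carries the
TF flag of the mRNA status table.

Because miRNAs repress their targets, miRNA edges are kept only when
the miRNA and target changed in opposite directions (miRNA direction
from its pattern category, target direction from the mRNA table);
edges with an unannotated endpoint are dropped and counted, never
silently. TF edges are unconstrained. By default the constraint is
applied before enumeration (`directionFirst = TRUE`); applying it
after is supported, since the original ordering is unstated.

A 3-node FFL is a triple (TF, miRNA, gene) with TF→gene, miRNA⊣gene
and at least one of TF→miRNA / miRNA⊣TF. Types are mutually
exclusive: both cross edges → composite-FFL, TF→miRNA only → TF-FFL,
miRNA⊣TF only → miRNA-FFL. Enumeration joins the TF→gene and
miRNA⊣gene edge lists on the gene and filters on the cross edges; the
suite proves it equal to a brute-force $O(n^3)$ triple scan on random
fixtures. Triples where the TF is its own target gene are dropped
unless `allowSelf = TRUE` (self-regulation handling is unstated in
the source design).

FFLs are grouped into TF-, miRNA- and composite sub-networks. Hubs
are, per node class independently, the top `ceiling(0.25 n)` nodes by
degree **including ties at the cutoff** — arbitrary exclusion among
tied nodes would be order-dependent. Degree is the undirected incident
edge count within the sub-network.

# Imprinted-region localization

Each DEMIR's locus (BED6, converted by `rtracklayer`) is assigned to
the configured region by its **midpoint**, so no miRNA is ever
double-assigned; any-overlap mode is a flag. Fractions are reported as
percentages at one decimal, per between-sex contrast and pooled over
the union of the three contrast DEMIR sets (the union reading of the
pooled denominator; per-contrast rows let a reader form any other
combination). Unplaced miRNAs are counted and listed, never dropped.
The Dlk1-Dio3 interval itself is configuration (default: a documented
placeholder on chr12, `dlk1Dio3Region()`), since no coordinates are
printed in the source design. −3p/−5p products of one precursor count
as distinct miRNAs. Enrichment of DEMIRs in the region uses the
conditional two-sided exact test on the 2×2 table, with a Haldane
(+0.5) odds-ratio correction only when a cell is zero.

# Over-representation

`ora()` is an upper-tail hypergeometric test of the overlap between
the query (targets of in-region DEMIRs, intersected with the
down-regulated gene set) and each GMT term, with BH q-values across
reported terms and `Log10(P)`/`Log10(q)` reporting. The universe is
the down-regulated mRNA table, not the genome — a deliberate, narrower
background than web enrichment services use; term clustering is out of
scope.

# The synthetic-data generator

`simulateAll()` emulates the study inputs with planted truth:

* **Counts** — one NB draw per miRNA per library (no replicates).
  Baseline relative abundances are log-normal (meanlog 6, sdlog 1.5 on
  the TPM scale); six libraries of $10^7$ reads (the depth at which
  the emulated study's detection saturates; per-group mapped depths
  are never stated); $\phi = 0.05$; 300 miRNAs with planted patterns
  in proportions echoing the observed category sizes — a 40-miRNA
  block shared by both sexes plus 5 male-only and 10 female-only
  blocks, whose sex-divergent grades also define the true between-sex
  DEMIRs — and an eight-fold effect per grade step. Planted means are
  *not*
  renormalized within a library, so fold identities are exact by
  construction (subtype a1 at fold 8 gives $E[T] = 8E[P] = 8E[W]$);
  realized totals drift slightly above nominal, which the TMM stage
  absorbs — as it must for real composition shifts.
* **Loci** — exactly `round(fracInRegion × n)` midpoints inside the
  region; the rest on other chromosomes.
* **Score tables** — planted FFLs sit on node-disjoint triples with
  scores on the passing side of every gate; decoys fail at least one
  gate and so never become edges; optional passing noise closes no new
  triangle. Planted FFL recovery is therefore exact, and the suite
  asserts recovery of exactly the planted set. In-region miRNAs with
  sex-divergent patterns additionally get passing target rows onto
  down-regulated, TF-edge-free genes, so the over-representation stage
  has a recoverable query that closes no loop.
* **Ct table** — $Ct = Ct_{ref} - \log_2(\mathrm{TPM}/10^3) +
  \varepsilon$, reference constant at 25, $\varepsilon \sim N(0,
  0.15^2)$; TPM/1000 keeps typical Ct near the reference, the realistic
  qPCR range.

Every sub-generator derives its seed from the one configuration seed,
so runs are bit-reproducible and the pieces can be called
independently.

**What the generator does not emulate:** sequence content and mapping
artefacts, miRNA families with correlated expression, isomiR
structure, genome-realistic locus clustering (in-region members are a
random sample, not a physical cluster), and score distributions of the
real prediction databases. Passing the planted-recovery suite
therefore shows the estimators are correct under the stated model, not
that the model captures every property of real libraries.

# Numerical choices and problem sizes

* Dispersion default 0.05; exact-test tails computed by direct
  summation (no approximation), with overflow-safe rescaling.
* Pseudo-count 0.5 for fold changes; log2(TPM+1) for correlation/PCA
  (the transform is a convention; the source design is silent).
* Saturation curves use *nested* binomial thinning (each shallower
  subsample drawn from the previous), which makes detection monotone
  in depth by construction rather than only in expectation.
* Hub ties included; FFL triples sorted lexicographically for stable
  output; all tables written at 6 significant digits.
* Test problem sizes, chosen to exercise the stated study conditions
  at desk scale: planted-recovery runs use 300 miRNAs × 6 libraries of
  5×10⁶ reads × 20 seeds; the null-calibration check uses 500 miRNAs ×
  10⁶ reads × 20 seeds (null calibration is depth-insensitive);
  network oracles use 20 random 30–50-node graphs.

# Known limitations

* With one library per group, "significance" is conditional on the
  assumed $\phi$; the q-values quantify counting noise plus the
  assumed biological variability, not replicate-estimated variability.
* The union-of-contrasts DEMIR call does not control FDR at the
  miRNA-set level across contrasts (each contrast is controlled
  separately); the planted-recovery suite measures the realized
  call-level false-discovery proportion instead.
* Real headline counts from the emulated study (total DEMIRs, total
  FFLs) depend on its sequencing data and 2018-era databases and are
  not reproducible from synthetic inputs; the package reproduces the
  study's *arithmetic* (worked percentages, accounting identities) and
  its *procedures* under planted truth.
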