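---
title: "Methods: transcriptome-weighted codon usage divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-weighted codon usage divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncocodon)
```

## The model

A transcriptome's effective codon usage is the codon composition of its
expressed mRNA pool. With a genes × 64 codon count matrix $M$ (one row per
gene, counts from the primary-transcript CDS, stop codon included) and a
per-sample expression vector $w$ in TPM, the weighted usage is

$$ u = \frac{w^\top M}{\sum_c (w^\top M)_c} \times 1000, $$

codons per thousand; codon pairs use the genes × 4096 matrix of
overlapping in-frame bigrams and a per-million scale. Two properties matter
in practice and are enforced by tests: $u$ is invariant to positive
rescaling of $w$ (so TPM, median TPM or any proportional weights agree),
and $u$ is a convex combination of the per-gene usage vectors. Because
expression is quantified against a reference annotation, usage reflects
expression re-weighting only, never per-sample sequence variation — that is
a stated limit of the approach, not an implementation gap.

Tissue-level usage is computed on a *median sample*: the per-gene median
TPM across a group's samples (even group sizes use the mean of the central
pair). The median sample is deliberately not renormalized; the weighting
step normalizes regardless. The unweighted baseline (`genomic_usage`) pools
counts over genes, which is identical to weighting every gene equally —
not, note, to weighting genes by their own codon totals, which would square
each gene's contribution.

## Conventions and parameters

**Counting.** Reading frame starts at position 1; all codons count,
including the terminal stop (stop-codon usage is a reported quantity in
this field, so it stays in all 64 positions). Pairs are overlapping
consecutive bigrams: $n$ codons yield $n-1$ pairs, never spanning genes.
Codons are ordered lexicographically (A < C < G < T) everywhere for stable
serialization. The 1-codon CDS yields an all-zero pair vector rather than
an error.

**Primary transcript.** Annotation tag (canonical/MANE-style) when
supplied, else longest CDS, ties broken by smallest transcript id. Both
routes are supported because annotation conventions differ; the default is
documented rather than guessed silently.

**TPM from counts.** $\mathrm{TPM}_g \propto \mathrm{count}_g / L_g$
normalized to $10^6$, with $L_g$ the primary-transcript CDS length. The
normalizing denominator therefore spans coding genes only; a pre-computed
TPM table can be supplied instead when a whole-annotation denominator is
wanted. Genes in the counts but absent from the annotation are dropped with
a tally, not an error.

**RSCU.** $\mathrm{RSCU}_c = u_c \cdot k / \sum_{c' \in \mathrm{fam}(c)}
u_{c'}$ with $k$ the family size under the standard genetic code. The three
stop codons are treated as one 3-member family so that stop-codon
preference is defined; single-codon families (Met, Trp) are exactly 1.
Zero-usage families give `NA` ("undefined preference") rather than 0,
and per-patient ΔRSCU rows for such families are dropped with a tally.

**Percent difference.** The default convention reports each codon's change
relative to the smaller of the two tissues' usage — "X% higher in cancer"
or "X% higher in normal" — because that matches how such differences are
quoted bidirectionally in this literature. A symmetric convention
(difference over the mean) is available behind a flag; published
percent-difference tables are therefore comparable in spirit but not
bit-for-bit, since the convention behind them is typically unstated.

**Statistics.** The ΔRSCU regression "Wald test" is the OLS slope $t$-test
($\hat\beta/\mathrm{SE}$ against $t_{n-2}$, two-sided), which is what the
named test reduces to in simple regression; significance at $\alpha/3 =
0.01/3$ for the three synonymous partners tested against a reference
codon. The per-codon screen is the paired Wilcoxon signed-rank test at
$\alpha/64 = 0.01/64$. Zero differences are dropped by default (Wilcoxon's
original procedure, as implemented by `stats::wilcox.test`, which switches
from the exact null distribution to a continuity-corrected normal
approximation at 50 non-zero pairs); we kept that library behavior rather
than imposing a lower exact-distribution cutoff because the exact
distribution is cheap well past 25 pairs and better calibrated in the far
tail the Bonferroni-64 threshold lives in. Pratt's zero-retaining variant
is available (`zeros = "pratt"`, normal approximation with zero-adjusted
variance). PCA is mean-centered without unit-variance scaling (usage
values share one scale); each component's sign is fixed by making its
largest-magnitude loading positive. Dendrograms default to average linkage
— the linkage behind published tumor/normal usage dendrograms is
unstated, so tree topologies are validated on ultrametric constructions,
not against published figures.

**Survival.** Product-limit estimates with Greenwood variance and log-log
95% intervals (linear Greenwood behind a flag), truncated at a 10-year
horizon; median = earliest time the estimate reaches 0.5. Quartile
comparison takes the top and bottom $\lceil n/4 \rceil$ cases by the chosen
divergence metric (ties broken by case id, deterministically), reports both
medians and per-year CI overlap, and computes no formal test by default —
CI separation is the reported evidence, with a log-rank test available
behind a flag. Where `survfit` returns `NA` limits (zero variance, or an
estimate at 0), the interval is collapsed onto the point estimate.

## What the synthetic generator emulates

The generator produces the four input types the pipeline consumes — CDS
FASTA, per-sample two-column count files, GDC-like metadata, clinical
table — plus a truth record. Its design choices:

- **The planted signal is expression re-weighting, not mutation.** One
  "shifted" gene class is enriched (weight × 8) for the up-target codons
  and depleted for the down-targets; tumors multiply that class's
  expression by a per-case fold-change. This matches the mechanism the
  statistic measures.
- **Calibration.** The class-level multiplier is solved by `uniroot` so the
  *expected* median-sample usage shift of the first target codon equals its
  nominal magnitude (default 20% GGT-up). Per-case heterogeneity then
  multiplies it by a log-normal factor (sdlog 0.5), so patients differ in
  shift size — that spread is what drives the ΔRSCU regressions and the
  MSE-to-survival coupling. The calibration is exact for the median case;
  tests verify it with heterogeneity off and sampling noise on.
- **Expression and counts.** Log-normal baseline expression (meanlog 1,
  sdlog 1 — the standard heavy-tailed RNA-seq marginal), multiplicative
  per-gene log-noise (default sd 0.05), Poisson integer counts around
  expected abundances at a 5 × 10⁵ library size so the TPM-conversion path
  is exercised. `noise_sd = 0` switches to exact expected counts so the
  zero-shift cohort is exactly null.
- **Survival.** Death times are exponential with log-hazard = baseline
  (0.15/yr) + coupling × per-case codon-usage MSE; censoring is an
  independent exponential process whose rate yields the requested
  censoring fraction exactly in expectation. The default coupling (0.125
  per MSE unit) was set analytically from the planted MSE spread so the
  top-vs-bottom quartile hazard ratio lands near 3 — a regime in which CI
  separation is expected to emerge but desk-scale group sizes keep it from
  being trivial.
- **Distractors.** The metadata plants exactly one record violating each
  cohort filter (a metastatic sample, a prior-treated case, an
  under-threshold cancer type), and the truth record stores the tallies so
  bookkeeping is testable exactly.

What it does **not** emulate: real human gene structure, isoform mixtures,
GC-content of a real genome, batch effects, or annotation errors. Passing
tests therefore demonstrate that the estimators recover known planted
structure under idealized noise — they do not validate conclusions about
any real cohort.

## Problem sizes and numerical choices

Test and validation runs use desk-scale cohorts chosen as the smallest
sizes at which each property is statistically identifiable: 100 cases for
planted-shift and ΔRSCU recovery, 300 for survival stratification, 2,000
replicates × 30 pairs for the Wilcoxon null calibration, 1,000 random CDS
for the counting oracle. Usage normalization is checked to 1e-9 relative;
the usage-vs-loop oracle to 1e-12; OLS against normal equations to 1e-10.
Quantile columns in the per-cancer MSE summary use linear-interpolation
quantiles (R type 7), which are of limited meaning below ~8 patients —
the summary still reports them, with `n_patients` alongside.

Published headline values from full-scale cohorts (tens of thousands of
samples) are not reproducible at these sizes and are not targets; what is
reproducible, and tested, are the analytic constants (thresholds, closed
forms) and the recovery of planted structure.

## Known limitations

- Gene-level weighting only; isoform-level expression would change pair
  counts at junctions between alternately used exons.
- No variant-aware counting: per-sample SNVs/indels do not alter the count
  matrices.
- Selenocysteine recoding, frameshifts and partial CDS annotations are
  handled by skip-with-log only.
- The O/E ratio uses first-order independence of adjacent codons as the
  expectation; dicodon-level biology (e.g. ribosome dwell interactions) is
  precisely what its deviations are meant to flag, so it should not be read
  as a model fit.
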