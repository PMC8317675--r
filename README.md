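# oncocodon

Transcriptome-weighted codon and codon-pair usage analysis of tumor and
matched normal tissues.

## The problem

The codon composition a cell's translation machinery actually sees is not
the genome's codon composition: it is the composition of the expressed mRNA
pool, with each gene's codons weighted by how strongly that gene is
transcribed. Tumors remodel their transcriptomes, and with them the
effective codon and codon-pair usage — even when no coding sequence changes
at all. `oncocodon` quantifies that remodeling for cohorts of matched
tumor/normal RNA-seq samples (TCGA-style inputs: per-sample count files,
GDC-like metadata, clinical follow-up), and ships a synthetic cohort
generator so the whole pipeline is testable without any downloads.

It is written for computational biologists who want per-cohort and
per-patient answers to: *which codons shift, how much, is the shift a
coherent change in synonymous codon preference, and does its magnitude
stratify survival?*

## The quantities it computes

For each gene g, count matrices **M** (genes × 64 codons) and **P**
(genes × 4096 ordered, overlapping codon pairs) are built from the
primary-transcript CDS. Given a sample's expression vector **w** (TPM),
the transcriptome-weighted usage is

    u = wᵀM / Σ(wᵀM) × 1000        (codons per thousand)
    p = wᵀP / Σ(wᵀP) × 10⁶         (pairs per million)

Tissue-level usage uses a *median sample* (per-gene median TPM across the
group). On top of these vectors the package computes:

- **Divergence**: MSE between usage vectors (the per-patient and per-cancer
  scalar), signed per-codon percent differences with top-k reports,
  Euclidean distance matrices, dendrograms, PCA.
- **Codon preference**: RSCU per codon (usage over its synonymous-family
  mean; stop codons form one 3-member family), per-patient ΔRSCU
  (tumor − normal), OLS regressions of one codon's ΔRSCU on a synonymous
  partner's with two-sided Wald tests at α = 0.01 Bonferroni-corrected by 3.
- **Screens**: per-codon paired Wilcoxon signed-rank tests across matched
  cases, Bonferroni-corrected by 64.
- **Codon-pair structure**: percentile ranks and observed/expected ratios
  (expected from marginal codon frequencies under independence).
- **Survival**: Kaplan-Meier curves with log-log Greenwood 95% CIs for the
  top vs bottom quartiles of per-patient MSE, medians and per-year CI
  overlap over a 10-year horizon.

## Worked example

Simulate a 30-case cohort with a planted 20% GGT-up (GGG-down) expression
shift, run the full pipeline, and look at the three headline outputs:

```r
library(oncocodon)

spec <- synthetic_spec(n_cases = 30, seed = 11)
cfg  <- simulate_inputs(spec, "cohort30")
res  <- run_all(cfg)

u <- res$aggregate$usage
divergence_report(u["normal breast", ], u["ductal carcinoma - breast", ], k = 4)
#> Codon usage divergence report
#>   MSE (per-thousand scale): 1.052
#>   Top codons higher in cancer: GGT (+20.8%), TGA (+3.9%)
#>   Top codons higher in normal: GGG (+10.3%), ATA (+3.9%)

res$paired$rscu_regressions[, c("y_codon", "slope", "r_squared", "significant")]
#>   y_codon  slope r_squared significant
#> 1     GGA -0.318     0.999        TRUE
#> 2     GGC -0.232     0.998        TRUE
#> 3     GGG -0.450     1.000        TRUE
```

The planted GGT enrichment is recovered at almost exactly its nominal 20%
magnitude in the median-sample comparison, and the per-patient ΔRSCU of
every other glycine codon moves against ΔGGT (negative slopes, R² ≈ 1):
the shift is a coherent change in synonymous preference, carried by
expression re-weighting alone. `res$paired$case_mse` holds the per-patient
MSEs ("case 1" = largest divergence; median here 0.94), and with a larger
cohort (the hazard in the generator is coupled to per-case MSE) the
`res$paired$km` comparison separates the high- and low-divergence
quartiles.

Real data enter the same way: a CDS FASTA (or genome + GTF), a directory of
two-column HTSeq-style count files, a metadata TSV (file/case ids, sample
type, tissue, diagnosis, prior-treatment flag) and an optional clinical
TSV, wired together with `run_config()`. `default_merge_config()` ships
the standard label merges (lung sub-sites, esophageal SCC subtypes) and
tissue exclusions as editable data. A thin CLI wrapper lives at
`inst/cli/oncocodon.R` (`simulate`, `aggregate`, `paired`, `run-all`).

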