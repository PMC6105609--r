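# sweepenrich

Polygenic enrichment of GWAS associations in genomic regions of interest —
canonically, regions that underwent a positive selective sweep in modern
humans after the split from Neanderthals ("human divergent", HD, regions).
The package is for statistical geneticists who have GWAS summary statistics,
a reference genotype panel, and one or more BED tracks of regions, and want
to know whether association signal is concentrated in those regions beyond
what the regions' SNP share predicts.

## What it computes

With per-SNP chi-squares χ²ⱼ = zⱼ² from a GWAS of N individuals, the
stratified LD-score regression

    E[χ²ⱼ] = 1 + N·a + N·Σ_c τ_c ℓ(j, c)

is fit by two-step weighted least squares with a free intercept, where
ℓ(j, c) is the partitioned LD score of SNP j toward category c (bias-adjusted
r² summed over a ±1 Mb window). Per-category heritability h²_c and the
enrichment fold

    fold_c = (h²_c / h²) / (M_c / M)

follow from the fitted τ, with standard errors from a 200-block delete-a-block
jackknife (the fold ratio is jackknifed directly). Around the regression the
package provides:

* LD-weighted region annotation scores (Σ δⱼ·r², r² < 0.2 zeroed, self = 1)
  for exon/intron/UTR/brain-gene tracks;
* intergenic SNP classification and the genomic-control factor λ_GC
  (median z² of LD-pruned intergenic sets over 100 pruning iterations,
  divided by the χ²₁ median), plus correction;
* conditional Q-Q and fold-enrichment curve statistics truncated at
  −log₁₀(p) = 7.3, as data frames ready for plotting;
* MHC exclusion (chr6:25,119,106–33,854,733 plus r² > 0.1 partners);
* Fisher's combined probability test across traits;
* a synthetic-data module (block-LD panel, annotation tracks, summary
  statistics from the partitioned polygenic model) that replaces the
  unavailable real inputs and backs all simulation tests.

Readers/writers cover TSV summary statistics (configurable header dialect),
BED region tracks, and VCF or TSV-dosage reference panels, with strict
row-level validation and reported drop counts.

## Worked example

Simulate a 20,000-SNP world whose sweep regions (5% of SNPs) carry a true
enrichment fold of 2.0, then run the full pipeline:

```r
library(sweepenrich)

cfg <- sim_config(M = 20000, N_gwas = 50000,
                  tau = c(hd = tau_for_fold(2, 0.05, 0.5, 20000)[["extra"]]),
                  seed = 1)
panel  <- generate_panel(cfg)
tracks <- generate_tracks(cfg)
ann <- build_annotations(panel,
  tracks[c("hd", "exon", "intron", "utr3", "utr5", "brain", "hdbrain")],
  weighted = FALSE)
sim <- generate_sumstats(panel, ann, cfg)
ld  <- partitioned_ld_scores(panel, ann)
fit <- fit_stratified(sim$sumstats$z ^ 2, cfg$N_gwas, ld)
enrichment_table(list(synthetic = fit), category = "hd")
#>   phenotype     fold   fold_se p_enrichment p_enrichment_fmt p_coefficient
#> 1 synthetic 1.903244 0.5000502   0.07087056      7.09 × 10−2     0.1104376
```

The estimated fold 1.90 ± 0.50 brackets the true value 2.0; at this desk
scale a single replicate is noisy (the test suite checks 20 seeded
replicates recover the fold within 3 jackknife s.e. in ≥ 18 of 20). The
fold-enrichment curve shows the same signal as an upward deflection:

```r
fold_enrichment(sim$sumstats, ann$binary[, "hd"] == 1, grid = c(0, 1, 2, 3))
#>   x     fold n_stratum n_all reliable
#> 1 0 1.000000      1000 20000     TRUE
#> 2 1 1.172960       629 10725     TRUE
#> 3 2 1.343805       462  6876     TRUE
#> 4 3 1.529770       352  4602     TRUE
```

Combining published per-trait enrichment p-values across trait groups:

```r
fisher_combine(c(2.63e-2, 4.48e-2, 2.45e-2, 2.36e-2), "cognitive")
#> Fisher combination 'cognitive': k = 4, X2(8) = 28.399, p = 4.04 × 10−4
fisher_combine(c(3.12e-1, 7.17e-2), "anthropometric")
#> Fisher combination 'anthropometric': k = 2, X2(4) = 7.600, p = 1.07 × 10−1
```

The four cognitive-trait enrichment p-values combine to p ≈ 4.0 × 10⁻⁴
(jointly significant); the two anthropometric controls do not (p ≈ 0.107).

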