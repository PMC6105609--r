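---
title: "Methods: polygenic enrichment in selective-sweep regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic enrichment in selective-sweep regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

sweepenrich asks whether genome-wide association signal for a phenotype is
concentrated in a set of genomic regions — canonically, regions inferred to
have undergone a positive selective sweep in modern humans after the split
from Neanderthals ("human divergent", HD, regions). The regions are an input
(a BED track); the package quantifies enrichment of association, it does not
infer sweeps.

The statistical core is the partitioned polygenic model. With per-SNP
association chi-squares $\chi^2_j = z_j^2$ from a GWAS of $N$ individuals,
and categories $c$ with per-SNP heritability coefficients $\tau_c$,

$$ E[\chi^2_j] \;=\; 1 + N a + N \sum_c \tau_c\, \ell(j, c), $$

where $\ell(j,c) = \sum_{k \in c} \tilde r^2_{jk}$ is the partitioned LD
score of regression SNP $j$ to reference-panel SNPs in $c$ (window
$\pm 1$ Mb; $\tilde r^2 = r^2 - (1-r^2)/(n-2)$ is the usual small-sample
bias adjustment, so individual values may be slightly negative) and the free
intercept $1 + Na$ absorbs confounding. The category-$c$ heritability is
$h^2_c = \sum_{j \in c} \sum_{c'} \tau_{c'} a_{jc'}$ and the *enrichment
fold* is

$$ \mathrm{fold}_c = \frac{h^2_c / h^2}{M_c / M}, $$

1 meaning "carries its share". The HD coefficient $\tau_{\mathrm{HD}}$,
tested against 0, is the conditional effect of sweep-region affiliation
after controlling for the other annotations (exon, intron, UTRs, brain
genes, and their HD intersection in the shipped default set).

## Estimation choices

**Two-step weighted least squares.** Step 1 weights by
$1/\max(\ell_{\mathrm{tot}}, 1)$ (down-weights LD-redundant SNPs); step 2
re-weights by $1/[\max(\ell_{\mathrm{tot}},1)\cdot\max(1,\hat E[\chi^2_j])^2]$
using step-1 fitted values (heteroscedasticity: the variance of a
chi-square grows with its mean). The intercept is always free.

**Block jackknife.** Standard errors come from a delete-a-block jackknife
over `n_blocks = 200` contiguous equal-count SNP blocks in chromosome
order, which is robust to LD-induced dependence provided each block spans
several LD blocks. The fold standard error jackknifes the ratio directly
rather than delta-method linearizing it — the ratio is nonlinear and the
blockwise ratio replicates are cheap. `p_coefficient` and `p_enrichment`
are two-sided normal tests of $\tau_c$ and $\mathrm{fold}_c - 1$ against
their jackknife standard errors. When the estimated total heritability is
numerically zero (below a level contributing $10^{-8}$ to the mean
chi-square) folds are reported `NA` rather than as 0/0 ratios.

**Degenerate inputs.** Constant LD-score columns are collinear with the
free intercept and are dropped with a warning; a constant chi-square of 1
yields exactly $\hat\tau = 0$, intercept 1, folds undefined.

## Annotation scores and two distinct r² rules

Two LD-weighted quantities look similar but follow different rules, and
the package keeps them separate on purpose:

* **LD-weighted region annotation score** (`ld_weighted_region_score`):
  $\mathrm{score}_i = \sum_j \delta_j r^2_{ij}$ with $r^2 < 0.2$ zeroed
  and $r^2_{ii} = 1$ exactly. This is the "does SNP *i* tag the region
  class" annotation used for exon/intron/UTR/brain columns and the
  intergenic rule.
* **Partitioned LD scores** (`partitioned_ld_scores`): unthresholded,
  bias-adjusted $\tilde r^2$, used as the regression covariates.

Coordinates follow the two standards touched: BED intervals are 0-based
half-open, SNP positions 1-based; membership is $start < pos \le end$.
Summary statistics are harmonized to the panel by chromosome+position,
flipping the z sign on swapped alleles and dropping strand-ambiguous
(A/T, C/G) SNPs. Missing genotypes are mean-imputed (configurable), which
keeps every pairwise correlation defined.

## Genomic control from intergenic SNPs

Intergenic SNPs — zero LD-weighted genic scores *and* no LD ($r^2 \ge
0.2$) partner inside genes$\pm$100 kb, ncRNA, TFBS or miRNA-site intervals
— approximate a null set. $\lambda_{GC}$ is the median $z^2$ of LD-pruned
($r^2 < 0.2$, greedy random order) intergenic subsets, aggregated as the
median over 100 seeded pruning iterations (mean available), divided by the
$\chi^2_1$ median 0.4549364. The aggregation rule across iterations is a
package choice; the source methodology leaves it ambiguous. Correction
divides $z$ by $\sqrt{\lambda_{GC}}$ only when $\lambda_{GC} > 1$.
Whether correction is applied before curve statistics is the caller's
choice; the regression does not need it (free intercept), which is why
`fit_stratified` takes uncorrected chi-squares in the examples.

## Curve statistics

The conditional Q-Q curve plots, per stratum, nominal $-\log_{10} p$
against empirical $-\log_{10}(r/(n+1))$ (ties broken by SNP id), truncated
at $-\log_{10} p < 7.3$ (p $> 5\times10^{-8}$) so the curves describe the
polygenic, sub-significance signal. The fold-enrichment curve is the ratio
of complementary ECDFs, $CDF_s(x)/CDF_{all}(x)$ with $CDF(x)$ the
proportion of SNPs at-or-beyond $x$ — this orientation makes enrichment an
*upward* deflection (fold $>$ 1), matching the Q-Q curve's leftward
deflection, and gives $\mathrm{fold}(0)=1$ identically. Grid points whose
denominator tail holds fewer than 5 SNPs are flagged unreliable; empty
tails give `NA`. The package emits curve data (TSV via `write_curve`);
rendering is left to the user's plotting layer.

## The MHC

The extended MHC (chr6:25,119,106–33,854,733, build 19) has long-range LD
that inflates partitioned regressions; `mhc_exclusion_mask` removes SNPs
in the interval and any SNP with $r^2 > 0.1$ to one of them.

## What the synthetic world emulates — and what it does not

`sim_config`/`generate_panel`/`generate_tracks`/`generate_sumstats`
replace the unavailable real inputs (ten-million-SNP GWAS summary files,
the 1000 Genomes panel, the published sweep index, a 4915-gene brain set)
with a stated desk-scale world:

* **Panel**: 20,000 SNPs in 800 exchangeable-LD blocks of 25 (10 kb
  spacing, 2 chromosomes, so $\pm$1 Mb spans $\pm$100 SNPs), 200 samples,
  MAF uniform on (0.05, 0.5). Haplotypes are thresholded Gaussians; the
  implied genotype correlation is computable (internal oracle
  `genotype_block_cor`) and the generator is tested against it.
* **Tracks**: sweep regions 5% of SNPs and genes 30%, both block-aligned
  (so LD-tagging of the HD stratum is realistic); UTRs at gene-block ends,
  10% of gene interiors exonic, rest intronic; brain genes a quarter of
  gene blocks; small ncRNA/TFBS/miRNA context tracks on 1% of non-genic
  SNPs. Fractions are hit exactly by construction.
* **Summary statistics**: drawn at the z level per block,
  $z = \sqrt N R\beta + \eta$, $\eta \sim \mathrm{MVN}(0,
  \mathrm{inflation}\cdot R)$, with $R$ the *panel's* standardized-genotype
  correlation. Sharing $R$ between "GWAS population" and panel is
  deliberate: it makes the regression's expectation exact, so recovery
  tests probe the estimator, not reference mismatch. (Simulating from the
  population copula correlation instead introduces errors-in-variables
  attenuation at desk-scale panel sizes — observed as an inflated
  intercept and shrunken $\tau$ — which is a *real* phenomenon but not the
  one the recovery criteria test.) Total SNP heritability defaults to 0.5
  on the z scale; `tau_for_fold` converts a target fold and category
  fraction into the per-SNP increment realizing it exactly.

A green simulation test therefore establishes estimator correctness under
matched LD, block-exchangeable correlation and uniform MAF. It does not
establish robustness to panel/GWAS LD mismatch, realistic human MAF/LD
spectra, in-sample overlap between combined traits (the Fisher
combination assumes independence, as the source analysis does), or
annotation measurement error.

## Numerical and design notes

* LD computations walk the panel in 512-SNP chunks against their bp
  window (one dense crossprod per chunk); results are exactly invariant
  to sample permutation and equal dense brute-force double loops on small
  panels to 1e-10 or better (tested).
* LD pruning is greedy in uniformly random order with an
  integer-indexed adjacency list; a fixed seed fixes the kept set.
* The λ recovery experiment uses a weak-LD world (block ρ = 0.25,
  M = 40,000): a sample median over ~15k independent SNPs has s.e. ≈ 0.02,
  making the ±0.05 acceptance band a >2σ margin. With the default strong-LD
  world the pruned intergenic set would be too small for that band.
* Jackknife calibration needs several LD blocks per jackknife block;
  with 25-SNP LD blocks the default 200 jackknife blocks at M = 20,000
  put 4 LD blocks in each. At much smaller M the enrichment p-values
  become heavy-tailed (observed at M = 4,000 with 8 HD blocks), which is a
  small-sample property of the ratio statistic, not a bug; calibration is
  asserted at M = 20,000.
* No shell CLI is shipped: the exported function API plus TSV writers is
  the package's interface, in line with how R analysis packages expose
  pipelines; `meta_combine()` covers the grouped meta-analysis table use
  case.

## Known limitations

Binary annotations only (no continuous-annotation extension); bp windows,
not cM; no liability-scale conversion; Fisher combination without
dependence correction; the synthetic generator draws effects Gaussian per
SNP with block-aligned categories, so boundary SNPs whose window straddles
categories are rarer than in real genomes.
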