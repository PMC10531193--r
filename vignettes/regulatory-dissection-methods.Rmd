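---
title: "Methods: dissecting noncoding GWAS risk loci through regulatory elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting noncoding GWAS risk loci through regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regelex)
```

# Overview

Most GWAS risk variants for immune-mediated disease are noncoding, and the
working model is that they act by perturbing regulatory elements — often in a
stimulation-dependent, cell-type-specific way. `regelex` implements the
computational workflow for dissecting such loci as a set of composable,
tested stages:

1. **Credible sets** (`ld_expand`, `single_causal_posteriors`,
   `build_credible_set`): which variants at a locus are plausibly causal.
2. **Element activity and overlap** (`threshold_active_elements`,
   `intersect_variants_elements`): which candidate regulatory elements the
   credible variants fall in, and in which biosamples those elements are
   active.
3. **Differential accessibility** (`loess_normalize`,
   `test_differential`): which elements respond to a condition contrast
   (T-cell receptor stimulation, patient versus control).
4. **Allele-specific accessibility** (`infer_genotype`,
   `pool_het_counts`, `fit_beta_binomial`, `test_allelic_imbalance`): does
   chromatin accessibility differ between the two alleles of a risk SNP in
   heterozygotes.
5. **Heritability enrichment** (`compute_ld_scores`,
   `regress_partitioned`, `enrichment_estimates`): does an element set
   carry more trait heritability than its SNP share predicts.
6. **Permutation enrichment** (`permutation_overlap_test`,
   `exact_overlap_p`): are risk variants overrepresented inside an element
   set.
7. **Integration** (`pwm_delta_score`, `classify_gene_support`): which
   target genes have convergent eQTL/GWAS/ATAC support, and which motifs do
   risk alleles break.

Every stage is exercised end-to-end on synthetic data from the `simulate_*`
generators, which emulate the statistical structure of the real inputs at
desk scale and serialize their ground truth so that calibration and power
are measurable, not assumed.

# The synthetic-data generators

**Haplotype panel.** LD is simulated with a founder-haplotype block model:
each block has a handful of founder haplotypes, every sampled haplotype
copies one founder and flips sites independently at a small mutation rate.
This is deliberately not a coalescent simulation — the downstream
mathematics (r², LD scores, the fine-mapping likelihood) only needs
controllable correlation structure, and the founder model provides strong
within-block LD, exact independence across blocks, and speed. Blocks sit
1 Mb apart on one synthetic chromosome so a sub-megabase LD window never
spans two blocks. Monomorphic sites are dropped and counted. What this does
*not* emulate: recombination gradients, allele-frequency spectra,
population structure, or sequence content; conclusions about those features
cannot be drawn from these tests.

**GWAS summary statistics.** Z-scores are drawn directly from the model
that stratified LD-score regression assumes: per-SNP true effects
$\beta_j \sim N(0, \sum_C \tau_C a_{jC})$ on the standardized-genotype
scale, then per block $z = \sqrt{N} R \beta + \varepsilon$ with
$\varepsilon \sim N(0, R)$, where $R$ is the block correlation matrix from
the panel. Simulating at the summary level rather than through
individual-level phenotypes matches the regression being tested and is
orders of magnitude cheaper; it is the standard device for validating
summary-statistic methods.

**ATAC counts.** Negative-binomial counts with uniform baseline log2 means
(default range 4–9, i.e. ~16–512 reads per element), log-normal
library-size factors (SD 0.25 on the log2 scale), gamma-style dispersion
0.1, and a configurable fraction of elements whose group-2 mean is shifted
by a spike log2 fold change. Cohort sizes default to 10 versus 11 samples,
matching a realistic patient/control ATAC study. The depth distribution of
real ATAC libraries is not modeled; these defaults are generic, not
estimates of any particular study.

**Allelic read counts.** Each (SNP, individual) pair is heterozygous with
probability `het_rate`; read depth is Poisson; heterozygote reference
counts are beta-binomial with mean $\theta$ and overdispersion $\rho$,
drawn independently per heterozygote. Overdispersion therefore acts at the
read-sampling level within each individual, so pooling reads across
heterozygotes dilutes it — the pooled count over $h$ hets of depth $d$ has
variance factor $1 + (d-1)\rho$, not $1 + (hd-1)\rho$. This mirrors
technical sources of overdispersion (PCR, transposition) that are not
shared across individuals. A SNP-level shared imbalance is modeled through
$\theta \ne 0.5$, which *does* survive pooling. The beta-binomial *fitter*
is additionally validated on draws from its own model (`rbetabinom`) where
recovery of $(\mu, \rho)$ is exact to sampling error.

**Element atlas.** Non-overlapping 200-bp intervals; each
(element, biosample) cell is active with the target probability, active
cells drawing Z above the 1.64 threshold (1.64 + Exp(1)) and inactive cells
a standard normal truncated below it. The construction makes the expected
active fraction exact by design.

# Models and numerical choices

## Fine-mapping

Under a single causal variant per locus with a flat prior over SNPs and a
$N(0, W)$ effect prior, the posterior probability of SNP $j$ is its
Wakefield approximate Bayes factor normalized over the locus:

$$\mathrm{ABF}_j = \sqrt{\frac{s_j^2}{s_j^2 + W}}
  \exp\!\left(\frac{z_j^2 W}{2(s_j^2 + W)}\right), \qquad
  \mathrm{PP}_j = \mathrm{ABF}_j / \sum_k \mathrm{ABF}_k .$$

ABFs are normalized in log space (subtracting the max) so loci with very
strong signals do not overflow. The 95% credible set is the smallest
PP-descending prefix reaching 0.95 cumulative mass, with ties broken by
position and members at PP ≤ 1% dropped afterwards — the retention rule is
strictly greater than 1%. The default prior variance `W = 0.04` (prior SD
0.2 on the log-odds scale) is the standard single-causal choice and is
exposed as configuration; when the generative `W` is matched, simulated
coverage of the true causal variant is ~97% across 500 loci (the tests
require ≥ 93%). The locus window for LD expansion defaults to ±500 kb; the
r² threshold is strictly greater than 0.7. Multi-causal search and
conditional analysis are out of scope.

## Differential accessibility

Normalization fits, per sample, a robust loess curve of
$M = \log_2(\text{count}) - \overline{\log_2(\text{count})}$ against mean
abundance $A$, and subtracts the fitted trend as an offset
(`span = 0.3`, degree 1, symmetric family, pseudocount 0.5). Offsets absorb
both library-size and abundance-dependent biases and are centered to sum to
zero across samples for each element. Two caveats are inherent to MA-trend
normalization and are demonstrated by the tests rather than hidden: the
trend is unidentifiable if all elements share one abundance, and in
abundance regions populated *only* by truly differential elements the trend
absorbs part of the signal (robust fitting protects regions where
differential elements are a minority).

Testing is a per-element negative-binomial likelihood-ratio test of the
group effect with offsets fixed, deliberately simpler than csaw's
quasi-likelihood machinery (the analysis design, not the csaw internals, is
what this package reproduces; results are not csaw-exact). Dispersion is
estimated by Cox–Reid-adjusted profile maximum likelihood: a global value
across elements, then per-element values on a log grid, shrunk toward the
global value with 20 prior degrees of freedom — an empirical-Bayes
moderation in the spirit of edgeR. Measured behavior at the default
conditions (2,000 elements, 10 vs 11 samples, dispersion 0.1): null
type-I error ≈ 0.05–0.06 at nominal 0.05, spike AUROC > 0.99. All-zero
elements are excluded and reported untested; BH correction is applied
within each analysis, and both raw-p and FDR cutoffs are configuration.

## Allele-specific accessibility

Genotypes come from the read counts themselves: individuals with fewer
than 5 reads at a SNP are excluded, otherwise heterozygous iff both alleles
were observed. Reads are summed across heterozygotes per SNP, one global
beta-binomial null $(\mu, \rho)$ is fitted per dataset to the pooled
$(k, n)$ pairs by maximum likelihood (method-of-moments start, BFGS on
logit-transformed parameters, explicit binomial comparison at the
$\rho = 0$ boundary, degenerate boundary fits flagged), and each SNP gets a
minimum-likelihood two-sided exact p-value: the total probability of all
outcomes no more likely than the observed one, with a $1 + 10^{-7}$ slack
factor against floating-point ties. The fit uses the $(k, n)$ pairs, not
the fractions, because that is the likelihood-correct reading of fitting a
beta-binomial to pooled reference fractions. Because genotype inference and
testing reuse the same reads, a selection effect exists at low depth; it is
documented, not corrected, matching common practice. Reference-bias read
filtering is assumed to have happened upstream. The nominal p < 0.05
cutoff is the default for calling hits, with BH q-values available;
cross-dataset `concordance` requires significance in ≥ 2 datasets with the
same skew direction.

## Stratified LD-score regression

LD scores $\ell(j, C) = \sum_k a_{kC}\, \tilde r^2_{jk}$ are computed over
a window (default 100 kb) with the finite-sample correction
$\tilde r^2 = r^2 - (1 - r^2)/(n - 2)$; the self term is exactly 1. The
regression of $\chi^2_j$ on $\{N \ell(j, C)\}_C$ has a free intercept
(configurable but not pinned, matching standard practice), and uses
variance-motivated weights $1/(2(N \bar h^2 \ell_j / M + 1)^2)$ iterated
once from an unweighted first pass. Standard errors come from a
delete-one-block jackknife over 20 contiguous SNP blocks — appropriate at
desk scale where 200 genome-scale blocks would leave too few SNPs per
block. Enrichment is the heritability share over the SNP share; its SE is
propagated by recomputing enrichment on each leave-one-block-out
coefficient vector. This is a pedagogical-scale reimplementation: no
baseline-model annotation files, no MHC exclusion, one synthetic
chromosome; published enrichment analyses are reproduced in structure, not
value. Measured at 5,000 SNPs, N = 10,000, 50 replicates: mean estimated
enrichment ≈ 5.0 at truth 5, jackknife 95% CI coverage ≈ 95%, null
intercept ≈ 1.00.

## Permutation enrichment

The observed statistic is the number of risk SNPs inside elements; each
permutation redraws that many SNPs from the universe without replacement,
within MAF bins when provided. The empirical p uses the add-one
pseudocount, $(1 + \#\{ \ge \text{obs}\})/(1 + n_{\text{perm}})$, so it is
never zero. The exact hypergeometric upper tail is provided as the oracle
for the unmatched scheme and agrees with the permutation estimate within
Monte-Carlo error. SNP sets (not element sets) are permuted; LD-aware
rotation schemes are out of scope.

## Motif and gene integration

PWMs are probability matrices with a 0.001 pseudocount renormalized per
column; scores are log2-odds against the background, with optional
both-strand scanning (max of the two orientations). For an allele
substitution with the alignment held fixed, the full-window score
difference collapses algebraically to the single-column log ratio
$\log_2 P_i(\mathrm{alt})/P_i(\mathrm{ref})$; a negative delta predicts
decreased binding for the alternative allele. Gene support classification
applies the stated cutoffs — GWAS support if any eQTL SNP of the gene has
GWAS p < 10⁻⁶, ATAC support if any eQTL SNP falls inside a differential
element with p < 0.01, differential tiers at FDR 10%/20% — and flags
non-differential genes with both supports as regulatory candidates. The
same GWAS cutoff is used for both the support classification and the
candidate rule; eQTL significance is taken as given from the input table.

# Problem sizes and determinism

The test and acceptance experiments use: 500 loci × 20 SNPs for
fine-mapping coverage; 2,000 SNPs for allelic calibration and 400 for
power (pooled depth ~500, above the ≥150 floor the power claim assumes);
1,000 SNPs at depth 50 for parameter recovery; 5,000 panel SNPs,
N = 10,000, 50 replicates for enrichment recovery; 2,000 elements at 10 vs
11 samples for differential calibration; 10⁵ permutations against the
exact tail. These sizes were chosen so every experiment has enough
replication for its acceptance band while remaining runnable on a laptop
in minutes.

Every simulator requires an explicit seed and restores the caller's RNG
state (`withr::with_seed`); rerunning any pipeline configuration
reproduces identical outputs bit for bit. `run_pipeline` writes all seeds
and parameters into its JSON summary.

# Known limitations

- The founder-block panel has no recombination within blocks and exactly
  zero LD between them; LD-score windows never face the partial-overlap
  regimes of real genomes.
- The NB test is not csaw-exact (no quasi-likelihood F-test); its
  calibration is demonstrated empirically on the generator's conditions.
- The beta-binomial null conflates dataset-level and SNP-level
  overdispersion into one global $(\mu, \rho)$; real data may need
  per-depth or per-region nulls.
- Single-causal fine-mapping is exact only under its own assumption; loci
  with allelic heterogeneity will spread posterior mass incorrectly.
- The pipeline consumes already-quantified counts; alignment, peak
  calling, read-level bias correction, and RNA quantification are upstream
  and out of scope.
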