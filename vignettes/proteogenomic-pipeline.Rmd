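---
title: "Methods: a proteogenomic discovery pipeline for CSF pQTL, PWAS and MR analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a proteogenomic discovery pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and scientific setting

`proteopheno` implements, as tested reusable code, the inference chain used
in sentinel-variant proteogenomics of cerebrospinal-fluid (CSF) aptamer
panels: a risk variant of interest (for example a common Parkinson's-disease
risk allele in a kinase locus) is tested against thousands of aptamer-level
protein measurements (PheWAS), conditionally independent protein-modifying
SNPs are extracted from summary statistics (conditional/joint selection plus
LD pruning), genetically predicted protein levels are tested against disease
GWAS summary statistics (PWAS), causality is probed by two-sample Mendelian
randomization with pleiotropy-aware sensitivity configurations, group
differences in measured protein levels are validated observationally, and
the discovered protein set is placed into brain cell types by a specificity
and enrichment rule.

Real cohort genotypes and SomaScan proteomes are access-controlled, so every
stage is exercised on synthetic data with planted truth. The synthetic-data
module is first-class, tested code: it defines the study conditions, and the
recovery tests and the acceptance script quantify how well each stage
retrieves what was planted.

# Aptamer quality control and normalization

The QC cascade mirrors standard SomaScan practice, in this order:

1. **Scale-factor filter.** An aptamer is removed when its plate scale
   factor diverges from that plate's median scale factor by strictly more
   than 0.5 (default). The rule is applied per plate, removal on *any* plate
   (`scope = "any_plate"`); an aggregate per-aptamer variant is available
   because vendor documentation is ambiguous on this point. When no scale
   factors accompany the data (the 5K-panel situation) the stage is skipped
   with a logged warning.
2. **CV filter.** An aptamer is removed when its *median* cross-plate
   coefficient of variation exceeds 0.15 (strict inequality; a median CV of
   exactly 0.15 is retained).
3. **IQR screen.** Per aptamer, values outside
   \[Q1 − 1.5·IQR, Q3 + 1.5·IQR\] are set to *missing* (not winsorized —
   the exclusion reading matches the companion validation cohort's
   description of outlier removal). Quartiles use linear interpolation
   (type 7), the default convention of most statistics environments;
   the type is configurable because the field is not unanimous. Values
   exactly on a fence are kept. Aptamers with fewer than 4 observed values
   are skipped with a warning.
4. **Call-rate cascade.** Stage 1 removes samples and aptamers with call
   rate below 65% (both computed on the incoming table). Call rates are
   recomputed on the survivors and stage 2 removes at 85%, aptamers before
   samples by default; the order is configurable because it is a genuine
   convention choice, and on realistic missingness patterns it changes
   little.
5. **Normalization.** Per aptamer, `x -> (log10(x) - mean) / sd` over
   observed values, with the *sample* (n−1) standard deviation. Constant
   aptamers are dropped with a warning; nonpositive values are an error
   naming the offending cell. A useful closed form: a column
   (10, 100, 1000) becomes (1, 2, 3) after log10, whose sample sd is
   exactly 1, hence normalizes to (−1, 0, 1).

The `qc_pipeline()` report records every removal with exactly one stage and
reason, and the bookkeeping identity
`aptamers_in = aptamers_out + removals` is enforced by test.

# pQTL scanning and meta-analysis

`pqtl_scan()` fits, per (SNP, aptamer) pair, ordinary least squares of the
normalized protein on alt-allele dosage plus covariates (age, sex, array,
and leading genotype principal components in the full pipeline). Complete
columns are handled by residualizing protein and dosages on the covariate
design once (Frisch–Waugh–Lovell) and computing every slope by matrix
algebra; this is numerically identical to per-pair `lm` fits and is tested
against them to 1e-8. P-values use the t distribution with residual degrees
of freedom. Genotype PCs are computed on an LD-pruned variant subset
(r² < 0.2), the standard practice for ancestry components; without pruning
the leading PCs align with LD blocks and absorb genuine trans signals.

`meta_fixed()` is fixed-effect inverse-variance meta-analysis:
β_meta = Σ(β_i/se_i²)/Σ(1/se_i²), se_meta = (Σ 1/se_i²)^(−1/2),
Cochran's Q = Σ((β_i − β_meta)/se_i)², and I² = max(0, (Q − (k−1))/Q)·100.
Alleles are harmonized to the first contributing cohort (swapped
orientations flip the sign; irreconcilable allele pairs drop that cohort
for that record). `forest_consistency()` summarizes per-cohort sign
concordance and flags I² > 50.

# Conditional/joint selection on summary statistics

The selection machinery works on the standardized scale. For a
covariate-free marginal scan the SNP–protein correlation is recovered
*exactly* from the t statistic, r = t/√(df + t²) with df = n − 2, rather
than through the 2f(1−f) allele-frequency approximation; with an in-sample
LD (correlation) matrix R, the joint solution b = R⁻¹r, residual variance
(n−1)(1 − b'r)/(n − p − 1) and Var(b) = σ²R⁻¹/(n−1) then reproduce
individual-level multiple regression to numerical accuracy. This is what
makes the package's summary-level stepwise selection testable against an
explicit individual-level oracle (agreement to 1e-6 is a test, not a hope).

`stepwise_select()` is greedy forward selection by smallest conditional p
below the entry threshold (default 5e-8, the convention of the original
conditional-joint method; configurable), with a backward check dropping any
selected SNP whose joint p rises above the threshold, a collinearity guard
(candidate r² with the selected set below 0.9), and deterministic
tie-breaking (smaller p, then lexicographic variant ID). `ld_prune()` keeps
variants in order of ascending p and drops any with r² strictly greater
than 0.85 to a kept variant; a pair at exactly the threshold is retained,
and the comparison carries a 1e-12 epsilon so values that round-trip
through floating point to the threshold behave as the strict rule intends.

`discovery_loop()` chains the stages: PheWAS of the sentinel (BH-FDR at 5%
across aptamers, per-variant scope by default), stepwise selection per
significant aptamer, union and pruning of the selected SNPs, then PheWAS of
the newly found SNPs to extend the aptamer set; it runs a fixed number of
rounds (default 2, one extension past the sentinel).

# PWAS: weight training and association

`train_weights()` fits two learners on covariate-residualized protein
levels over a cis+trans SNP set (the cis window is ±1 Mb around the
aptamer's gene; trans SNPs come from the conditional selection): `top1`
(single best marginal SNP, weight = its marginal beta, cross-validated by
refitting the choice inside each training fold) and an elastic net
(`glmnet`, α = 0.5). The model with the higher k-fold cross-validation R²
is retained; a model whose cv R² is not positive is unusable and excluded
from PWAS. The elastic net uses the conservative `lambda.1se` rule for both
the reported cv R² and the weights: at `lambda.min` the optimism of
minimizing over the lambda path lets a nontrivial fraction of pure-noise
proteins slip past the cv-R² gate, which defeats the gate's purpose.

`pwas_assoc()` computes z = w'z / √(w'Rw) against GWAS z-scores, with the
LD matrix regularized by clipping eigenvalues below 1e-8 and weights
harmonized to the GWAS effect alleles. The statistic is scale-invariant in
w, reduces to the SNP's own GWAS z for single-weight models, and is
calibrated (sd of z near 1) under a null GWAS — all three are tests.
`postprocess_loci()` BH-flags significant features, merges significant
features whose weight-SNP spans come within 100 kb into loci, and computes
conditional z-scores against the locus's top feature from the correlation
of genetically predicted protein levels.

# Mendelian randomization

`select_instruments()` keeps exposure SNPs at p < 5e-8, prunes them to
pairwise independence at the two-sample-MR clumping convention r² < 0.001
(configurable), intersects with the outcome GWAS, harmonizes alleles
(swapped orientations flip the outcome beta; palindromic A/T and C/G SNPs
with allele frequency in \[0.42, 0.58\] are dropped as strand-ambiguous),
and enforces instrument strength F = (β/se)² ≥ 10. Estimation is the Wald
ratio for one instrument (θ = β_out/β_exp, first-order se = se_out/|β_exp|)
and fixed-effect IVW otherwise (weighted regression of outcome on exposure
betas through the origin, weights 1/se_out²). Fixed-effect IVW was chosen
over multiplicative-random-effects because the instrument counts in this
setting are small (≤ 4); the cited two-sample-MR package would switch to
random effects above 3 SNPs, a documented divergence. `mr_sensitivity()`
runs three configurations: all instruments; excluding a pleiotropic region
(default chr12:39–41.5 Mb); and cis-only (instruments within 1 Mb of the
gene's coding span) — the pattern that separates pleiotropy-robust signals
from region-driven ones.

# Differential levels and cell-type enrichment

`group_compare()` regresses, per aptamer, normalized levels on a group
indicator plus covariates (age, sex, and the categorical array batch by
default), with BH q-values within the contrast; with no covariates it
reduces exactly to the equal-variance two-sample t-test.
`sex_difference()` runs male-vs-female contrasts within phenotype strata,
never including sex among the covariates; stratification and the sex
covariate toggle are both exposed since the two designs answer slightly
different questions.

`assign_specificity()` calls a gene cell-type specific when one cell type
carries strictly more than 50% of the gene's sum-total expression (a share
of exactly one half gives no call). `celltype_enrichment()` reports fold
change = (specific fraction in target)/(specific fraction in background)
and an upper-tail hypergeometric p (equivalently one-sided Fisher) for
drawing at least the observed number of specific genes in a target-sized
sample from the background; the source analyses do not state their test, so
the standard set-enrichment tail was chosen and is validated against
brute-force enumeration on small backgrounds.

# The synthetic-data generator

**Genotypes.** Per LD block, two haplotypes per sample are drawn from a
latent AR(1) Gaussian (parameter ρ, so variants k apart have latent
correlation ρ^k), thresholded at each variant's MAF quantile, and summed.
This gives tunable LD without a reference panel, Hardy–Weinberg-consistent
dosages, and exact reproducibility from one seed. One caveat the tests
encode explicitly: dichotomization attenuates correlation, so the
*genotype* correlation of adjacent variants is the phi coefficient of the
thresholded bivariate normal, not ρ itself (at ρ = 0.95, MAF 0.3 the
genotype r² is ≈ 0.62; proxy-grade r² ≥ 0.81 needs ρ ≈ 0.995). The
numerical oracle for this attenuation lives in the test suite.

**Proteins.** The latent (log10-scale) level is
Σ β·dosage + covariate effects + N(0, noise_sd), with age, sex and a
per-cohort array batch as covariates. The raw export is
10^(3 + 0.15·latent): RFU-like magnitudes with a realistic ~40% geometric
dispersion. Any affine calibration on the log10 scale is inverted exactly
by the z-score normalization, so planted effects are untouched; a bare
10^latent export would give a pathologically heavy-tailed raw scale whose
IQR screen flags ~15% of clean values. Plate scale factors, inflated CVs
and random missingness are injectable per aptamer with stated rates.

**Disease.** Liability = Σ θ·(genetic component of protein)/sd(protein)
+ direct SNP effects + N(0,1); cases are the top `prevalence` quantile.
Standardizing the mediated component makes θ (liability units per SD of
protein) the *exact* estimand of a two-sample MR that uses z-scored protein
levels as exposure — the recovery tests depend on this identity. The GWAS
export is liability-linear by default; a logistic (log-odds) export is
available since the effect scale of published GWAS varies.

**Cell types.** Expression shares follow a specificity plan (dominant cell
type and share), with totals drawn lognormally; the >50% rule recovers the
plan by construction.

What the generator does *not* emulate: population structure and
relatedness, imputation uncertainty, realistic human LD maps,
X-chromosome, batch effects correlated with genotype. Passing recovery
tests therefore demonstrates correctness of the statistical machinery
under its stated assumptions, not robustness to confounding the generator
never produces.

# Problem sizes, numerical choices and limitations

- The bundled demo study (`demo_config()`) uses two cohorts of 1000
  samples, 500 variants in three LD blocks (a chr12 sentinel block inside
  39–41.5 Mb, a chr5 trans block, a chr2 null block), 60 aptamers, a
  sentinel SNP affecting three aptamers, an independent trans SNP affecting
  two more plus one shared, one mediating protein at θ = 0.3, and an
  independent GWAS cohort of 10000. These sizes give comfortable power at
  genome-wide thresholds while keeping a full run around half a minute.
- Calibration and recovery simulations use 100–1000 replicates (100 for
  stepwise-selection recovery, 200 per θ for MR recovery and type-I error,
  1000 for PWAS null calibration), sizes at which Monte-Carlo error is
  small against the properties asserted.
- Numerical tie-breaks are deterministic everywhere (smallest p, then
  lexicographic ID); the LD-prune threshold carries a 1e-12 epsilon; the
  PWAS quadratic form clips eigenvalues at 1e-8; degenerate inputs
  (zero-variance SNPs, constant aptamers, empty instrument sets, all-zero
  genes) produce flagged records or typed errors rather than silent
  results.
- Known limitations: the Wald-ratio se is first-order (exposure
  uncertainty ignored), as is conventional; in-sample LD sidesteps
  reference-panel mismatch corrections, which are out of scope; the
  conditional z in PWAS post-processing conditions on the single top
  feature per locus rather than fitting a full joint model; BH is the
  canonical step-up, which can differ in edge cases from FDR-estimation
  packages built on estimating the null proportion.
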