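---
title: "Models and methods behind scdeqtl"
author: "scdeqtl maintainers"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods behind scdeqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdeqtl)
```

# Scope

`scdeqtl` implements a joint gene-expression / genome-wide-genotype
analysis pipeline for a pediatric sickle-cell-disease (SCD) cohort with
healthy sibling controls: expression QC and normalization, probe-level
ANCOVA, expression/genotype structure analysis, genome-wide eSNP mapping,
SNP-by-clinical-status interaction mapping with relatedness-corrected
refits, and an eSNP-conditioning comparison.  Because the underlying
microarray/genotype data cannot ship with the package, a first-class
synthetic-cohort generator reproduces the cohort's statistical structure
with known ground truth; every statistical guarantee the package makes is
demonstrated by recovery, calibration, or exactness tests against that
generator or against brute-force oracles.

# The cohort the generator emulates

The default `sim_config()` mirrors the joint-data subset of the study
design: 79 steady-state patients sampled at entry (E), 41 patients under
follow-up care (FU), and 53 controls (n = 173).  Patients are HbSS;
controls are healthy siblings carrying at least one normal β-globin
allele, HbAS and HbAA in 3:1 proportion.  A configurable fraction of
samples (default 0.4) belongs to full-sib pairs, preferentially pairing a
patient with a control sibling, which is how the real cohort recruited
its controls.

Covariates: sex is Bernoulli(0.5); white-cell counts are log-normal with
patient mean 14 vs control mean 8 (10^9/L), reflecting SCD leukocytosis;
red-cell counts are log-normal with patient mean 2.7 vs control mean 4.6
(10^12/L), reflecting hemolytic anemia.  No reference distributions exist
for these covariates, so the parameters are fixed at values a
hematologist would call typical for a pediatric HbSS population; they are
generator inputs, not fitted quantities.

Per-probe expression is

```
value = intercept + Hb effect + status effect + sex effect
        + WBC slope * (wbc - mean) + RBC slope * (rbc - mean)
        + eSNP term [+ group-specific allelic slopes] + N(0, noise_sd^2)
```

on the log2 scale, with `noise_sd = 0.5` (a typical residual SD for
whole-blood arrays after normalization).  Effects are *per-probe draws*
rather than fixed constants: a probe receives a nonzero status (or Hb, or
sex) shift with probability `de_fraction` (default 0.10), drawn
N(0, sd^2) with sd 0.5 / 0.8 / 0.25 respectively.  This yields a
realistic null/non-null mixture so that FDR behavior is testable; probes
with a group-specific allelic slope (interaction probes) always receive a
status shift so that a differential-expression screen retains them, as
the interaction stage assumes.

## eSNP calibration

An embedded eSNP's slope is set to

```
beta = sqrt(r2 / (1 - r2)) * noise_sd / sd(g)
```

so that the SNP's expected partial R² — the fraction of residual variance
explained when the SNP enters the model last — equals `esnp_r2` (default
0.33, i.e. the planted associations explain about a third of residual
transcript variance).  `sd(g)` is the realized dosage SD, so calibration
holds per-SNP rather than only in expectation over allele frequencies.
The recorded ground-truth partial R² uses the realized slope and dosage
variance.

## Genotypes, sibships, LD

Founder dosages are binomial(2, MAF) with MAF uniform on `maf_range`
(default 0.1–0.5), so Hardy-Weinberg equilibrium holds among founders.
Sib pairs are gene-dropped from two simulated parents with free
recombination between SNPs; the expected relationship (π̂) is 0.5 for
full sibs and 0 otherwise, which is the recorded kinship truth.
Optionally an AR(1) Gaussian copula on the latent gametes (`ld_rho`)
induces LD between map-adjacent SNPs; the default 0 keeps null
calibration clean, while `ld_rho > 0` exercises the LD pruner.  After
missingness is applied, dosages are re-oriented to the observed minor
allele, which keeps the minor-allele-count contract and makes ped/map
round trips exact.

What the generator does **not** emulate: bead-level array artifacts,
batch structure beyond technical replicates, β-globin-locus haplotypes,
linkage between chromosomes, assortative mating, or population
structure.  Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
real-data pathology.

# QC components

**Exact HWE test.** Two-sided exact test on genotype counts: the sum of
conditional probabilities (heterozygote count given allele counts) no
larger than the observed table's, computed by the standard stable
recurrence from the distribution's mode.  Monomorphic tables return 1.
The test suite verifies agreement with a full-enumeration oracle for
*every* genotype table with n ≤ 50 to 1e-12.  In sibship data HWE is
computed in founders by default (relatedness distorts genotype
proportions); `filter_snps(hwe_samples=)` controls this.

**SNP filters.** Defaults follow the study: MAF ≥ 5%, call rate ≥ 99%,
exact HWE p ≥ 0.001.  In per-group mode (used before the interaction
scan) every criterion must hold within every clinical-status group.  The
source description of the per-group filter has inverted comparison signs;
the package implements the conventional exclusions and documents that
reading.

**Quantile normalization.** `limma::normalizeQuantiles(ties = TRUE)`
after log2: every sample's sorted vector becomes the cross-sample mean of
order statistics, ties receiving the mean of the quantile values they
span.  An optional per-probe winsorization at 4 SD stands in for the
unspecified outlier-filtering step of the original workflow.

**Background filter.** Probes are ranked by mean normalized intensity;
the curve is smoothed by a running mean (window ≈ 2% of probes, minimum
5) and the cutoff placed at the rank minimizing the discrete second
difference — the knee where expression drops to the background plateau.
A monotone featureless curve has no knee and requires an explicit cutoff;
the knee is also constrained away from the smoothing edges.

# Differential expression

Per-probe OLS of `expression = μ + Hb genotype + ClinStatus + Sex + WBC +
RBC + ε` with marginal (Type III) F tests under sum-to-zero contrasts,
vectorized across probes through one shared design (samples with missing
covariates are dropped globally so all probes share identical df).
Benjamini–Hochberg FDR is applied separately within each term at q = 0.01.
Constant probes report F = 0, p = 1 by convention.

A structural subtlety: in a cohort whose patients are all HbSS, the Hb
factor and clinical status are partially aliased (the HbSS indicator
equals E + FU).  Rather than refuse the fit, each term's marginal test
uses the rank it actually adds (`df1 = rank_full − rank_reduced`), so the
status test in such a design carries 1 df (E vs FU adjusted for the
patient/control split, which Hb absorbs) and a term adding no rank is
flagged non-estimable.  With three separable status levels the test has
its nominal 2 df, which the suite asserts.  Pairwise status contrasts
(E−FU, E−Ctl, FU−Ctl) default to the model without Hb for the same
reason.

# Structure analysis

Expression PCA is ordinary centered sample PCA with a deterministic sign
convention (largest-magnitude loading positive).  Genotype PCA uses the
Eigenstrat normalization — center by 2p̂, scale by √(p̂(1−p̂)), missing
dosages mean-imputed for the decomposition only.

Variance components of the leading expression PCs are estimated by REML
(`lme4`), every factor (and optionally all pairwise factor combinations)
entering as a random intercept; negative estimates are truncated at zero
by the fitter and proportions are component/total.  The pooled summary is
the variance-weighted mean of per-PC proportions, a stated convention
since no pooling rule is standard.  Factors with fewer than two observed
levels, or factors whose grouping is aliased by another factor, are
reported non-identifiable.

Hierarchical clustering operates on 1 − correlation with average linkage
(the linkage is a documented choice; none is standard for this display).
Fst uses the Weir–Cockerham (1984) variance-component estimator per SNP
and ratio-of-sums aggregation over SNP sets; monomorphic SNPs are
excluded from the sums.

# eSNP mapping

Model 1 is `expression = μ + SNP + ClinStatus + WBC + RBC + Sex + ε` with
additive minor-allele dosage.  The genome-wide scan residualizes both the
expression matrix and the fully observed dosage columns against the
covariate design once (Frisch–Waugh–Lovell), after which the per-pair
correlation of residuals reproduces the OLS t test of the SNP coefficient
*exactly* — identical RSS bookkeeping with df = n − p − 1 — at matrix-multiply
cost.  SNPs with missing calls take a per-SNP path on their complete
samples (PLINK-style pairwise deletion); SNPs monomorphic in-sample are
skipped and counted.  The suite verifies scan-vs-single-fit equality at
1e-9 and single-fit-vs-`lm()` equality at 1e-8.

Local means probe and SNP on the same chromosome; distal means different
chromosomes; probes without a validated chromosome are excluded.  The
two-tier Bonferroni scheme corrects local tests for `n_probes × 200`
(200 being the fixed convention for the average number of SNPs tested per
probe — a configuration input, never recomputed) and distal tests for
`n_probes × n_snps_total`.  Peak selection takes, per probe and per
class, the minimum-p significant record, ties broken by larger |beta|
then lexicographic SNP id — an interpretation consistent with per-class
peak accounting.

A note on familywise behavior: because each tier spends α = 0.05 on its
own family, the union-scheme familywise error on null data is bounded by
2α, and when chromosomes carry more than 200 SNPs the local tier is
slightly anti-conservative relative to an exact Bonferroni.  The null
calibration test therefore checks (a) near-perfect zero-hit behavior
under the published genome-scale thresholds and (b) a zero-hit rate
consistent with FWE ≤ 2α under the scan's own thresholds.

The conditioning analysis refits the status ANCOVA with and without a
probe's peak eSNP and reports both p-values (and NLPs), their rank
correlation across probes, significance counts in either model, and
whether the direction of the adjusted status effects agrees between fits.

# Interaction mapping and the Q-K mixed model

Model 2 adds `SNP × ClinStatus`; the screen is the partial F test of
Model 2 against Model 1, computed per SNP from shared QR decompositions
across all probes, restricted to the differentially expressed probe set
and to SNPs passing the per-group filter.  Pairs in which any status
group is monomorphic for the SNP are non-estimable and skipped.
Per-group allelic slopes (reference-group slope plus interaction
coefficients) are reported for every emitted record.

Relatedness is estimated on an LD-pruned SNP set (greedy windowed
pruning, r² < 0.3 within a 50-SNP window stepping by 5, MAF ≥ 0.1, zero
missingness; the earlier-position SNP of a correlated pair is kept) by
the PLINK-style method of moments: pairwise IBS counts converted to IBD
state probabilities through their allele-frequency expectations, with
π̂ = P(IBD=1)/2 + P(IBD=2), truncated to [0, 1].  Finite-sample
allele-count corrections are omitted; on the common-variant pruned panels
this is used for, sib π̂ is unbiased to within ±0.01 in the suite's
checks.

The Q-K refit fits `y = Xβ + u + ε` with `cov(u) = σ_g² A`, where A is
the π̂ matrix (twice the kinship-coefficient matrix, 1 on the diagonal,
0.5 for full sibs; any scale constant is absorbed into σ_g²).  REML
estimation is by a one-dimensional profile of the variance ratio over the
spectral decomposition of A — eigendecompose once, rotate, and optimize
the restricted likelihood of the ratio on a log grid — so refitting many
screened pairs against one kinship matrix is cheap.  Non-PSD input is
bent by truncating negative eigenvalues at zero (flagged).  Inference on
the interaction columns is a Wald F with residual denominator df, a
documented approximation (it ignores variance-component estimation
error).  With K = identity the fit reduces to OLS exactly and reproduces
the screen's partial F p-value, which the suite asserts at 1e-6.  The
refit is applied only to screen-significant records, mirroring the
original two-stage workflow, and `finalize_interactions()` keeps records
whose mixed-model p stays below the class-appropriate threshold.

## Why the type-I simulation pairs sibs within a status group

Under a polygenic null with family structure, OLS misstates the variance
of the interaction contrast only where the interaction regressor has
nonzero within-family cross products: a patient–control sib pair
contributes `z_i z_j = 0` to the relevant terms because the control sib's
interaction dummy is zero.  The calibration scenario therefore assigns
clinical status at the sib-pair level (both sibs share a status —
plausible for siblings sharing a household and disease), uses h² = 0.8,
and places every sample in a sib pair.  There OLS rejects ~8–9% of null
interactions at α = 0.05 while the Q-K refit stays near 5–6%.  The
acceptance band for the mixed model's size (0.02–0.08) is wider than the
naive binomial band because the ~2000 test pairs share 100 polygenic
probes (strongly correlated outcomes) and because of the Wald-df
approximation above.

# Problem sizes and numerical choices

The test and acceptance workloads are scaled to what the properties need:
null calibration uses 20 cohorts of 500 probes × 5000 SNPs at n = 173
with uniformity assessed on 200k pooled per-pair p-values; eSNP recovery
plants 90 local eSNPs at partial R² 0.33 across three cohorts; exactness
checks run ~35 random designs per estimator at tolerance 1e-8; the HWE
oracle sweep enumerates all ~23,000 genotype tables with n ≤ 50.  Other
conventions: tolerance for treating a profile-REML optimum at the lower
boundary as λ = 0; quantile-normalization tie rule as above; peak and
pruning tie-breaks as above; 1-based inclusive coordinates and
"chr1" ≡ "1" chromosome normalization throughout; missing dosages are a
distinct NA state and are never silently imputed outside PCA (mean
imputation, decomposition only) and the simulator's causal-signal
construction (documented).

# Known limitations

Allele strandedness is ignored (alleles are opaque labels, appropriate
for array data).  The VCA pooling rule and the clustering linkage are
conventions, not estimates.  The mixed-model df is approximate; exact
small-sample df methods (Kenward–Roger-type) are out of scope.  The
background-knee locator assumes a plateau exists; expression panels
without background probes need an explicit cutoff.  The generator's
effect magnitudes for Hb vs status are tunable, not calibrated to any
published variance fractions.
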