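# scdeqtl

Expression QTL and genotype-by-clinical-status interaction mapping for
sickle-cell-disease (SCD) cohorts with sibling controls.

## The problem

Children with HbSS sickle-cell disease show genome-wide changes in
whole-blood gene expression relative to healthy sibling controls, and the
expression of many transcripts is under genetic control that may itself
depend on clinical state (newly enrolled at entry, E; under follow-up
care, FU; versus controls, Ctls).  Analyzing this requires a chain of
steps — expression normalization, genotype QC, structure analysis,
probe-level ANCOVA, genome-wide eSNP scans, and interaction scans that
respect the family structure of a sibling-based cohort — each with
well-defined statistical conventions.  `scdeqtl` packages that chain as
tested, reusable R functions, driven by a synthetic-cohort generator with
known ground truth so every guarantee is verifiable.

## Models

Probe-level differential expression (ANCOVA, per-term FDR 1%):

    Expression = mu + HbGenotype + ClinStatus + Sex + WBC + RBC + eps

eSNP mapping (Model 1, additive minor-allele dosage):

    Expression = mu + SNP + ClinStatus + WBC + RBC + Sex + eps

Interaction mapping (Model 2, screened by partial F against Model 1):

    Expression = mu + SNP + ClinStatus + WBC + RBC + Sex
                 + SNP x ClinStatus + eps

Associations are *local* when probe and SNP share a chromosome, *distal*
otherwise, with a two-tier Bonferroni correction: local tests at
`alpha / (n_probes x 200)` (200 = assumed average SNPs tested per probe)
and distal tests at `alpha / (n_probes x n_SNPs)`.  Screened interaction
hits are refit in a Q-K linear mixed model, `y = Xb + u + eps` with
`cov(u) = sigma_g^2 A`, where A is the pairwise-relatedness (pi-hat)
matrix estimated from an LD-pruned SNP panel, and optional genotype PCs
(Q) enter as fixed covariates.

## Worked example

```r
library(scdeqtl)

# the published two-tier thresholds for 19,431 probes x 560,675 SNPs
thr <- compute_bonferroni_thresholds(19431, 560675,
                                     avg_local_snps = 200, alpha = 0.05)
# local  threshold: 1.29e-08 (NLP 7.89)
# distal threshold: 4.59e-12 (NLP 11.34)

# a synthetic cohort: 120 HbSS patients + 53 sibling controls (n = 173),
# 25 embedded eSNPs explaining a third of residual probe variance
cfg <- sim_config(seed = 7)
sim <- simulate_cohort(cfg)
qc  <- filter_snps(sim$genotypes, analysis_config(),
                   hwe_samples = sim$truth$founders)
# SNP QC: 2000 -> 1910 (90 removed)

scan  <- scan_esnps(sim$expression, qc$genotypes, sim$metadata)
scan$summary
# $n_tested: 955000   $n_significant: 23
# $n_local_significant: 18   $n_distal_significant: 5

peaks <- select_peak_associations(scan)
head(peaks[, c("probe_id", "snp_id", "class", "beta", "p", "partial_r2")], 3)
#   probe_id   snp_id class       beta            p partial_r2
# 1   P00001 rs000491 local  0.4987638 2.050753e-16  0.3351095
# 2   P00002 rs001673 local -0.5303423 2.291664e-11  0.2379461
# 3   P00003 rs001354 local -0.5013497 2.689101e-11  0.2364945
```

Each peak row is the strongest significant SNP for one probe within its
class: `beta` is the expression change (log2 units) per copy of the minor
allele, `p` the OLS t-test p-value against the class-appropriate
threshold, and `partial_r2` the fraction of residual probe variance the
SNP explains — here centered on the planted value of one third.

The same surface drives the rest of the pipeline:
`fit_ancova()` / `pairwise_contrasts()` / `unique_de_sets()` for
differential expression, `expression_pca()` / `variance_components()` /
`fst_weir_cockerham()` for structure, `ld_prune()` /
`estimate_kinship()` / `scan_interactions()` / `refit_interactions()` /
`finalize_interactions()` for interaction mapping, and
`condition_on_esnp()` for the conditioning comparison.  A thin
command-line wrapper with subcommands
`simulate | qc | structure | de | esnp | interact | condition` lives at
`inst/cli/scdeqtl.R`.  The methods vignette
(`vignettes/scdeqtl-methods.Rmd`) documents the models, conventions and
their rationale.

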