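#' Simulation configuration for a synthetic cohort
#'
#' Builds and validates the parameter set driving the synthetic-cohort
#' generator.  Defaults emulate the joint expression/genotype subset of a
#' pediatric sickle-cell cohort with healthy sibling controls: 79 steady-state
#' patients at entry (E), 41 patients under follow-up care (FU) and 53
#' controls (n = 173 in total), a fraction of samples belonging to
#' patient-control sibling pairs, sex and blood-count covariate effects, and
#' embedded local/distal eSNPs and SNP-by-clinical-status interaction
#' effects with known ground truth.
#'
#' @param n_patients_E number of steady-state patients sampled at entry.
#' @param n_patients_FU number of patients sampled under follow-up care.
#' @param n_controls number of healthy sibling controls.
#' @param n_snps,n_probes,n_chromosomes dimensions of the genotype and
#'   expression matrices and the number of autosomes positions are spread
#'   over.
#' @param maf_range length-2 numeric in (0, 0.5]; per-SNP minor-allele
#'   frequencies are drawn uniformly from this interval.
#' @param sibling_fraction proportion of samples belonging to sib pairs
#'   (each pair contributes 2 samples).
#' @param n_local_esnps,n_distal_esnps numbers of probes given a causal SNP
#'   on the same (local) or a different (distal) chromosome.
#' @param esnp_r2 target fraction of a probe's residual variance explained
#'   by its embedded eSNP (partial R-squared), in [0, 1).
#' @param n_interaction_effects number of probes with a group-specific
#'   allelic slope (the slope differs in the FU group).
#' @param interaction_delta difference in per-group allelic slope, in
#'   log2-expression units per minor allele.
#' @param de_fraction proportion of probes with a nonzero clinical-status
#'   effect (the same proportion is used for Hb-genotype and sex effects).
#' @param clinstatus_effect_sd,hb_effect_sd,sex_effect_sd standard
#'   deviations of the per-probe group-shift draws (log2 units).
#' @param wbc_slope_sd,rbc_slope_sd standard deviations of the per-probe
#'   slopes on centered WBC (10^9/L) and RBC (10^12/L) counts.
#' @param noise_sd residual standard deviation (log2 units).
#' @param missing_rate per-genotype missingness probability.
#' @param ld_rho autoregressive correlation between adjacent SNPs' latent
#'   gametes; 0 (default) simulates independent SNPs.
#' @param seed integer seed controlling all randomness.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_patients_E = 79, n_patients_FU = 41,
                       n_controls = 53,
                       n_snps = 2000, n_probes = 500, n_chromosomes = 22,
                       maf_range = c(0.1, 0.5), sibling_fraction = 0.4,
                       n_local_esnps = 20, n_distal_esnps = 5,
                       esnp_r2 = 0.33,
                       n_interaction_effects = 5, interaction_delta = 0.5,
                       de_fraction = 0.10,
                       clinstatus_effect_sd = 0.5, hb_effect_sd = 0.8,
                       sex_effect_sd = 0.25,
                       wbc_slope_sd = 0.02, rbc_slope_sd = 0.1,
                       noise_sd = 0.5, missing_rate = 0.002,
                       ld_rho = 0, seed = 1L) {
  cfg <- list(n_patients_E = n_patients_E, n_patients_FU = n_patients_FU,
              n_controls = n_controls, n_snps = n_snps, n_probes = n_probes,
              n_chromosomes = n_chromosomes, maf_range = maf_range,
              sibling_fraction = sibling_fraction,
              n_local_esnps = n_local_esnps, n_distal_esnps = n_distal_esnps,
              esnp_r2 = esnp_r2,
              n_interaction_effects = n_interaction_effects,
              interaction_delta = interaction_delta,
              de_fraction = de_fraction,
              clinstatus_effect_sd = clinstatus_effect_sd,
              hb_effect_sd = hb_effect_sd, sex_effect_sd = sex_effect_sd,
              wbc_slope_sd = wbc_slope_sd, rbc_slope_sd = rbc_slope_sd,
              noise_sd = noise_sd, missing_rate = missing_rate,
              ld_rho = ld_rho, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != floor(v)) {
      stopf("invalid configuration: '%s' must be a non-negative count", field)
    }
  }
  for (f in c("n_patients_E", "n_patients_FU", "n_controls", "n_snps",
              "n_probes", "n_chromosomes", "n_local_esnps", "n_distal_esnps",
              "n_interaction_effects")) chk_count(f)
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stopf("invalid configuration: '%s' must be a probability in [0, 1]",
            field)
    }
  }
  for (f in c("sibling_fraction", "missing_rate", "de_fraction")) chk_prob(f)
  mr <- cfg$maf_range
  if (!is.numeric(mr) || length(mr) != 2L || any(is.na(mr)) ||
      mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2]) {
    stopf("invalid configuration: 'maf_range' must lie within (0, 0.5]")
  }
  if (!is.numeric(cfg$esnp_r2) || cfg$esnp_r2 < 0 || cfg$esnp_r2 >= 1) {
    stopf("invalid configuration: 'esnp_r2' must be in [0, 1)")
  }
  for (f in c("clinstatus_effect_sd", "hb_effect_sd", "sex_effect_sd",
              "wbc_slope_sd", "rbc_slope_sd", "noise_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      stopf("invalid configuration: '%s' must be non-negative", f)
    }
  }
  if (cfg$n_local_esnps + cfg$n_distal_esnps + cfg$n_interaction_effects >
      cfg$n_probes) {
    stopf(paste0("invalid configuration: 'n_local_esnps' + 'n_distal_esnps'",
                 " + 'n_interaction_effects' exceeds 'n_probes'"))
  }
  if (abs(cfg$ld_rho) >= 1) {
    stopf("invalid configuration: 'ld_rho' must be in (-1, 1)")
  }
  invisible(cfg)
}

#' Analysis configuration: the pipeline's filter and threshold constants
#'
#' Houses the QC and significance constants used across the pipeline:
#' minimum minor-allele frequency and call rate, the exact Hardy-Weinberg
#' p-value floor, the per-term FDR level for differential expression, the
#' LD-pruning r-squared ceiling and MAF floor used for relatedness
#' estimation, the assumed average number of local SNPs per probe for the
#' two-tier Bonferroni scheme, and the family-wise alpha.
#'
#' @param maf_min minimum minor-allele frequency for SNP retention.
#' @param hwe_p_min minimum exact HWE p-value.
#' @param callrate_min minimum genotype call rate.
#' @param fdr_q FDR level applied per model term.
#' @param prune_r2 squared-correlation ceiling for LD pruning.
#' @param prune_maf_min MAF floor for the pruned relatedness SNP set.
#' @param avg_local_snps assumed number of SNPs tested against each probe
#'   locally (a fixed convention, not recomputed from the data).
#' @param alpha family-wise error level for the Bonferroni thresholds.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(maf_min = 0.05, hwe_p_min = 0.001,
                            callrate_min = 0.99, fdr_q = 0.01,
                            prune_r2 = 0.3, prune_maf_min = 0.10,
                            avg_local_snps = 200, alpha = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, hwe_p_min >= 0, hwe_p_min <= 1,
            callrate_min >= 0, callrate_min <= 1, fdr_q > 0, fdr_q < 1,
            prune_r2 > 0, prune_r2 <= 1, prune_maf_min >= 0,
            prune_maf_min <= 0.5, avg_local_snps >= 1, alpha > 0, alpha < 1)
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 callrate_min = callrate_min, fdr_q = fdr_q,
                 prune_r2 = prune_r2, prune_maf_min = prune_maf_min,
                 avg_local_snps = avg_local_snps, alpha = alpha),
            class = "analysis_config")
}
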