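#' Synthetic cohort generation
#'
#' The generator emulates the statistical structure of a pediatric
#' sickle-cell cohort with healthy sibling controls: two clinical-status
#' patient groups (E: steady state at entry; FU: under follow-up care) plus
#' controls, sibling pairs, sex and blood-count covariate effects on
#' expression, embedded local/distal eSNPs explaining a configurable
#' fraction of probe variance, and SNP-by-clinical-status interaction
#' effects.  Every embedded effect is returned as machine-readable ground
#' truth so that recovery can be tested.
#'
#' @name simulate
NULL

## Deterministic sample roster shared by the genotype and metadata
## generators: ids, clinical status, family structure and sib pairing.
## Controls are paired with patients first (sibling controls), remaining
## pairs are patient-patient.
cohort_layout <- function(config) {
  set.seed(config$seed)
  n <- config$n_patients_E + config$n_patients_FU + config$n_controls
  if (n < 1L) stopf("invalid configuration: cohort has zero samples")
  status <- c(rep("E", config$n_patients_E),
              rep("FU", config$n_patients_FU),
              rep("Ctl", config$n_controls))
  sample_id <- sprintf("S%04d", seq_len(n))
  n_pairs <- floor(config$sibling_fraction * n / 2)
  family_id <- sprintf("F%04d", seq_len(n))
  sib_pairs <- NULL
  if (n_pairs > 0L) {
    patients <- which(status != "Ctl")
    controls <- which(status == "Ctl")
    k_pc <- min(n_pairs, length(patients), length(controls))
    pairs <- cbind(patients[seq_len(k_pc)], controls[seq_len(k_pc)])
    if (n_pairs > k_pc) {
      spare <- setdiff(patients, pairs[, 1])
      k_pp <- min(n_pairs - k_pc, floor(length(spare) / 2))
      if (k_pp > 0L) {
        pairs <- rbind(pairs, cbind(spare[seq_len(k_pp)],
                                    spare[k_pp + seq_len(k_pp)]))
      }
    }
    family_id[pairs[, 2]] <- family_id[pairs[, 1]]
    sib_pairs <- pairs
  }
  list(n = n, sample_id = sample_id, status = status,
       family_id = family_id, sib_pairs = sib_pairs)
}

## One founder gamete per row: n_gametes x n_snps matrix of 0/1 alleles
## (1 = simulated minor allele).  With ld_rho > 0 an AR(1) Gaussian copula
## along the map order of each chromosome induces LD between adjacent SNPs.
draw_gametes <- function(n_gametes, maf, chrom, ld_rho) {
  m <- length(maf)
  if (ld_rho == 0) {
    return(matrix(rbinom(n_gametes * m, 1L, rep(maf, each = n_gametes)),
                  nrow = n_gametes))
  }
  z <- matrix(rnorm(n_gametes * m), nrow = n_gametes)
  for (j in 2:m) {
    if (chrom[j] == chrom[j - 1L]) {
      z[, j] <- ld_rho * z[, j - 1L] + sqrt(1 - ld_rho^2) * z[, j]
    }
  }
  thr <- qnorm(maf)
  (z < rep(thr, each = n_gametes)) + 0L
}

#' Simulate a genotype matrix with sibships
#'
#' Founder genotypes are drawn binomially per SNP at a minor-allele
#' frequency sampled from `maf_range`, so Hardy-Weinberg equilibrium holds
#' among founders.  Sib pairs are generated by gene-dropping from two
#' simulated parents (free recombination between SNPs).  Missing calls are
#' introduced at `missing_rate` and SNP positions are spread uniformly
#' across `n_chromosomes` autosomes.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `genotype_matrix` with elements `dosage`
#'   (samples x SNPs minor-allele counts, `NA` = missing), `map` (data
#'   frame: snp_id, chrom, pos, allele_minor, allele_major, maf_true) and
#'   `sample_ids`; plus attribute-free ground truth under `$truth`
#'   (`kinship_true`: expected pairwise relationship, 1 on the diagonal,
#'   0.5 for full sibs; `founders`: logical, one entry per sample).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  layout <- cohort_layout(config)
  set.seed(config$seed + 1L)
  n <- layout$n
  m <- config$n_snps
  if (m < 1L) stopf("invalid configuration: 'n_snps' must be positive")
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  chrom <- sort(sample.int(config$n_chromosomes, m, replace = TRUE))
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(2.5e8, length(idx)))
  }
  map <- data.frame(snp_id = sprintf("rs%06d", seq_len(m)),
                    chrom = as.character(chrom), pos = pos,
                    allele_minor = "B", allele_major = "A",
                    maf_true = maf, stringsAsFactors = FALSE)

  dosage <- matrix(NA_integer_, n, m,
                   dimnames = list(layout$sample_id, map$snp_id))
  is_sib <- rep(FALSE, n)
  if (!is.null(layout$sib_pairs)) is_sib[as.vector(layout$sib_pairs)] <- TRUE
  n_founders <- sum(!is_sib)
  if (n_founders > 0L) {
    g <- draw_gametes(2L * n_founders, maf, chrom, config$ld_rho)
    dosage[!is_sib, ] <- g[seq_len(n_founders), ] +
      g[n_founders + seq_len(n_founders), ]
  }
  if (!is.null(layout$sib_pairs)) {
    for (k in seq_len(nrow(layout$sib_pairs))) {
      par_gam <- draw_gametes(4L, maf, chrom, config$ld_rho)
      for (child in layout$sib_pairs[k, ]) {
        from_p1 <- sample(c(TRUE, FALSE), m, replace = TRUE)
        from_p2 <- sample(c(TRUE, FALSE), m, replace = TRUE)
        gam1 <- ifelse(from_p1, par_gam[1L, ], par_gam[2L, ])
        gam2 <- ifelse(from_p2, par_gam[3L, ], par_gam[4L, ])
        dosage[child, ] <- gam1 + gam2
      }
    }
  }
  if (config$missing_rate > 0) {
    miss <- matrix(runif(n * m) < config$missing_rate, n, m)
    dosage[miss] <- NA_integer_
  }
  # orient dosages to the observed minor allele (sampling can push a
  # simulated frequency past 0.5); keeps the minor-allele-count contract
  # and makes ped/map round trips exact
  obs_freq <- colMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(obs_freq) & obs_freq > 0.5
  if (any(flip)) {
    dosage[, flip] <- 2L - dosage[, flip]
    map$allele_minor[flip] <- "A"
    map$allele_major[flip] <- "B"
    map$maf_true[flip] <- 1 - map$maf_true[flip]
  }
  kin <- diag(1, n)
  dimnames(kin) <- list(layout$sample_id, layout$sample_id)
  if (!is.null(layout$sib_pairs)) {
    for (k in seq_len(nrow(layout$sib_pairs))) {
      i <- layout$sib_pairs[k, 1]; j <- layout$sib_pairs[k, 2]
      kin[i, j] <- kin[j, i] <- 0.5
    }
  }
  structure(list(dosage = dosage, map = map, sample_ids = layout$sample_id,
                 truth = list(kinship_true = kin, founders = !is_sib)),
            class = "genotype_matrix")
}

#' Simulate sample metadata
#'
#' Clinical statuses follow the configured group sizes; sex is Bernoulli(0.5);
#' white and red blood cell counts are log-normal with group-specific means
#' (patients show leukocytosis and anemia relative to controls); patients
#' are HbSS and controls are HbAS or HbAA in 3:1 proportion; family ids
#' encode the sibling structure shared with [simulate_genotypes()].
#'
#' @param config a [sim_config()] object.
#' @return data frame with columns sample_id, family_id, hb_genotype,
#'   clin_status, sex, wbc (10^9/L), rbc (10^12/L), phase.
#' @export
simulate_metadata <- function(config) {
  validate_sim_config(config)
  layout <- cohort_layout(config)
  set.seed(config$seed + 2L)
  n <- layout$n
  patient <- layout$status != "Ctl"
  hb <- ifelse(patient, "HbSS",
               ifelse(runif(n) < 0.75, "HbAS", "HbAA"))
  sex <- ifelse(runif(n) < 0.5, "F", "M")
  # patients: leukocytosis (WBC ~ 14 vs 8 x10^9/L) and anemia
  # (RBC ~ 2.7 vs 4.6 x10^12/L) relative to sibling controls
  wbc <- exp(rnorm(n, mean = ifelse(patient, log(14), log(8)), sd = 0.25))
  rbc <- exp(rnorm(n, mean = ifelse(patient, log(2.7), log(4.6)), sd = 0.12))
  phase <- ifelse(runif(n) < 0.5, "discovery", "replication")
  data.frame(sample_id = layout$sample_id, family_id = layout$family_id,
             hb_genotype = hb, clin_status = layout$status, sex = sex,
             wbc = wbc, rbc = rbc, phase = phase, stringsAsFactors = FALSE)
}

## Pick the probe -> causal-SNP assignments.  Local probes share the SNP's
## chromosome; distal probes are forced onto a different one.
assign_causal <- function(map, n_local, n_distal, n_inter, n_probes,
                          n_chromosomes) {
  total <- n_local + n_distal + n_inter
  snp_idx <- if (total > 0L) {
    sample.int(nrow(map), total, replace = FALSE)
  } else integer(0)
  probe_chrom <- as.character(sample.int(n_chromosomes, n_probes,
                                         replace = TRUE))
  probe_pos <- sample.int(2.5e8, n_probes, replace = TRUE)
  classes <- c(rep("local", n_local), rep("distal", n_distal),
               rep("local", n_inter))
  for (k in seq_len(total)) {
    sc <- map$chrom[snp_idx[k]]
    if (classes[k] == "local") {
      probe_chrom[k] <- sc
    } else if (probe_chrom[k] == sc) {
      probe_chrom[k] <- as.character(
        sample(setdiff(as.character(seq_len(n_chromosomes)), sc), 1L))
    }
  }
  list(snp_idx = snp_idx, probe_chrom = probe_chrom, probe_pos = probe_pos)
}

#' Simulate a log2 expression matrix with embedded genetic effects
#'
#' Each probe's expression is
#' intercept + Hb effect + status effect + sex effect + WBC and RBC slopes
#' (on centered counts) + an optional eSNP term + optional group-specific
#' allelic slopes + Gaussian noise.  The eSNP slope is calibrated as
#' `beta = sqrt(r2 / (1 - r2)) * noise_sd / sd(g)` so the SNP's expected
#' partial R-squared equals `esnp_r2`.  Probes with a nonzero
#' clinical-status shift are recorded as the differential-expression truth;
#' interaction probes always receive one so that a DE screen retains them.
#'
#' @param genotypes result of [simulate_genotypes()].
#' @param metadata result of [simulate_metadata()].
#' @param config the same [sim_config()] object used for both.
#' @return a list of class `expression_matrix` with `values` (probes x
#'   samples, log2 scale), `probes` (data frame: probe_id, gene_symbol,
#'   chrom, pos) and `sample_ids`, plus `$truth` of class `ground_truth`
#'   (`esnp`, `interactions`, `de_probes`).
#' @export
simulate_expression <- function(genotypes, metadata, config) {
  validate_sim_config(config)
  if (!identical(genotypes$sample_ids, metadata$sample_id)) {
    stopf("alignment error: genotype and metadata sample ids differ")
  }
  set.seed(config$seed + 3L)
  n <- length(genotypes$sample_ids)
  np <- config$n_probes
  nl <- config$n_local_esnps; nd <- config$n_distal_esnps
  ni <- config$n_interaction_effects
  ca <- assign_causal(genotypes$map, nl, nd, ni, np, config$n_chromosomes)
  probes <- data.frame(probe_id = sprintf("P%05d", seq_len(np)),
                       gene_symbol = sprintf("GENE%05d", seq_len(np)),
                       chrom = ca$probe_chrom, pos = ca$probe_pos,
                       stringsAsFactors = FALSE)

  patient <- metadata$clin_status != "Ctl"
  d_fu <- as.numeric(metadata$clin_status == "FU")
  d_ctl <- as.numeric(metadata$clin_status == "Ctl")
  d_ss <- as.numeric(metadata$hb_genotype == "HbSS")
  d_as <- as.numeric(metadata$hb_genotype == "HbAS")
  d_m <- as.numeric(metadata$sex == "M")
  wbc_c <- metadata$wbc - mean(metadata$wbc)
  rbc_c <- metadata$rbc - mean(metadata$rbc)

  intercept <- rnorm(np, 8, 1)
  de_sel <- runif(np) < config$de_fraction
  inter_rows <- if (ni > 0L) nl + nd + seq_len(ni) else integer(0)
  de_sel[inter_rows] <- TRUE            # interaction probes must survive a DE screen
  b_fu <- ifelse(de_sel, rnorm(np, 0, config$clinstatus_effect_sd), 0)
  b_ctl <- ifelse(de_sel, rnorm(np, 0, config$clinstatus_effect_sd), 0)
  hb_sel <- runif(np) < config$de_fraction
  b_ss <- ifelse(hb_sel, rnorm(np, 0, config$hb_effect_sd), 0)
  b_as <- ifelse(hb_sel, rnorm(np, 0, config$hb_effect_sd), 0)
  sex_sel <- runif(np) < config$de_fraction
  b_m <- ifelse(sex_sel, rnorm(np, 0, config$sex_effect_sd), 0)
  b_wbc <- rnorm(np, 0, config$wbc_slope_sd)
  b_rbc <- rnorm(np, 0, config$rbc_slope_sd)

  values <- intercept +
    outer(b_fu, d_fu) + outer(b_ctl, d_ctl) +
    outer(b_ss, d_ss) + outer(b_as, d_as) +
    outer(b_m, d_m) + outer(b_wbc, wbc_c) + outer(b_rbc, rbc_c)

  esnp_truth <- NULL
  if (nl + nd > 0L) {
    rows <- seq_len(nl + nd)
    esnp_truth <- data.frame(probe_id = probes$probe_id[rows],
                             snp_id = genotypes$map$snp_id[ca$snp_idx[rows]],
                             class = c(rep("local", nl), rep("distal", nd)),
                             slope = NA_real_, partial_r2 = NA_real_,
                             stringsAsFactors = FALSE)
    for (k in rows) {
      g <- genotypes$dosage[, ca$snp_idx[k]]
      g[is.na(g)] <- mean(g, na.rm = TRUE)   # observed-dosage signal
      sg <- sd(g)
      if (sg == 0 || config$esnp_r2 == 0) {
        esnp_truth$slope[k] <- 0; esnp_truth$partial_r2[k] <- 0
        next
      }
      beta <- sample(c(-1, 1), 1L) *
        sqrt(config$esnp_r2 / (1 - config$esnp_r2)) * config$noise_sd / sg
      values[k, ] <- values[k, ] + beta * g
      esnp_truth$slope[k] <- beta
      esnp_truth$partial_r2[k] <- beta^2 * sg^2 /
        (beta^2 * sg^2 + config$noise_sd^2)
    }
  }

  inter_truth <- NULL
  if (ni > 0L) {
    inter_truth <- data.frame(
      probe_id = probes$probe_id[inter_rows],
      snp_id = genotypes$map$snp_id[ca$snp_idx[nl + nd + seq_len(ni)]],
      slope_E = 0, slope_FU = config$interaction_delta, slope_Ctl = 0,
      stringsAsFactors = FALSE)
    for (k in seq_len(ni)) {
      g <- genotypes$dosage[, ca$snp_idx[nl + nd + k]]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      values[inter_rows[k], ] <- values[inter_rows[k], ] +
        config$interaction_delta * g * d_fu
    }
  }

  values <- values + matrix(rnorm(np * n, 0, config$noise_sd), np, n)
  dimnames(values) <- list(probes$probe_id, genotypes$sample_ids)

  truth <- structure(list(esnp = esnp_truth, interactions = inter_truth,
                          de_probes = probes$probe_id[de_sel]),
                     class = "ground_truth")
  structure(list(values = values, probes = probes,
                 sample_ids = genotypes$sample_ids, truth = truth),
            class = "expression_matrix")
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_metadata()] and [simulate_expression()] with a shared
#' configuration, merging the ground truth.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `genotypes`, `expression`, `metadata`,
#'   `truth`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  meta <- simulate_metadata(config)
  e <- simulate_expression(g, meta, config)
  truth <- e$truth
  truth$kinship_true <- g$truth$kinship_true
  truth$founders <- g$truth$founders
  list(genotypes = g, expression = e, metadata = meta, truth = truth)
}
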