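test_that("LD pruning drops duplicates and leaves independent SNPs alone", {
  set.seed(71)
  n <- 150
  base <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  d <- cbind(base, dup = base[, 1])
  colnames(d) <- NULL
  g <- genotype_matrix(d, data.frame(snp_id = sprintf("v%02d", 1:11),
                                     chrom = "1", pos = seq(1000, 11000,
                                                            by = 1000)))
  pruned <- ld_prune(g, verbose = FALSE)
  expect_true(xor("v01" %in% pruned$map$snp_id,
                  "v11" %in% pruned$map$snp_id))
  # the earlier-position SNP of the duplicated pair is the one kept
  expect_true("v01" %in% pruned$map$snp_id)
  # independent SNPs (simulated) are essentially all retained
  g2 <- simulate_genotypes(sim_config(seed = 71, sibling_fraction = 0,
                                      n_snps = 300, missing_rate = 0))
  p2 <- ld_prune(g2, verbose = FALSE)
  expect_gte(ncol(p2$dosage), 0.95 * 300)
  # MAF floor and missingness pre-filter
  d3 <- cbind(rare = rbinom(n, 2, 0.02), miss = base[, 2], ok = base[, 3])
  d3[1, "miss"] <- NA
  g3 <- genotype_matrix(d3, data.frame(snp_id = c("rare", "miss", "ok"),
                                       chrom = "1", pos = 1:3))
  p3 <- ld_prune(g3, verbose = FALSE)
  expect_identical(p3$map$snp_id, "ok")
})

test_that("survivors of pruning an autocorrelated block satisfy r2 < 0.3", {
  g <- simulate_genotypes(sim_config(seed = 72, sibling_fraction = 0,
                                     n_snps = 400, n_chromosomes = 2,
                                     ld_rho = 0.8, missing_rate = 0))
  pruned <- ld_prune(g, r2_max = 0.3, verbose = FALSE)
  expect_lt(ncol(pruned$dosage), 400)
  for (cc in unique(pruned$map$chrom)) {
    idx <- which(pruned$map$chrom == cc)
    if (length(idx) < 2) next
    r2 <- cor(pruned$dosage[, idx])^2
    adj <- r2[row(r2) == col(r2) - 1]   # window guarantees adjacent pairs
    expect_true(all(adj < 0.3))
  }
})

test_that("pi-hat recovers the expected relatedness structure", {
  cfg <- sim_config(seed = 73, n_patients_E = 60, n_patients_FU = 60,
                    n_controls = 60, sibling_fraction = 0.6,
                    n_snps = 2000, missing_rate = 0)
  g <- simulate_genotypes(cfg)
  kin <- estimate_kinship(ld_prune(g, verbose = FALSE))
  expect_true(all(diag(kin$pihat) == 1))
  expect_true(isSymmetric(kin$pihat))
  kt <- g$truth$kinship_true
  off <- upper.tri(kt)
  sibs <- kt[off] == 0.5
  expect_gte(sum(sibs), 50)
  expect_equal(mean(kin$pihat[off][sibs]), 0.5, tolerance = 0.05)
  expect_lt(mean(kin$pihat[off][!sibs]), 0.02)
  # regression of estimate on truth has slope ~ 1
  fit <- lm(kin$pihat[off] ~ kt[off])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
})

test_that("interaction F equals explicit RSS bookkeeping and lm oracle", {
  sim <- tiny_cohort(seed = 74, n_snps = 15, n_probes = 8,
                     missing_rate = 0)
  isc <- scan_interactions(sim$expression, sim$genotypes, sim$metadata,
                           emit = "all")
  rec <- isc$records
  set.seed(74)
  pick <- rec[sample(nrow(rec), 25), ]
  for (k in seq_len(nrow(pick))) {
    y <- sim$expression$values[pick$probe_id[k], ]
    gd <- sim$genotypes$dosage[, pick$snp_id[k]]
    covars <- data.frame(sex = factor(sim$metadata$sex),
                         wbc = sim$metadata$wbc, rbc = sim$metadata$rbc)
    orc <- model2_lm_oracle(y, gd, sim$metadata$clin_status, covars)
    expect_equal(pick$F[k], orc$F, tolerance = 1e-8)
    expect_equal(pick$p[k], orc$p, tolerance = 1e-8)
    expect_equal(pick$df1[k], orc$df1)
  }
})

test_that("per-group slopes are recovered for planted interactions", {
  slopes <- NULL
  for (s in 1:5) {
    sim <- tiny_cohort(seed = 700 + s, n_snps = 300, n_probes = 60,
                       n_local_esnps = 0, n_distal_esnps = 0,
                       n_interaction_effects = 10,
                       interaction_delta = 0.5, missing_rate = 0)
    tr <- sim$truth$interactions
    isc <- scan_interactions(sim$expression, sim$genotypes, sim$metadata,
                             de_probes = tr$probe_id, emit = "all")
    rec <- isc$records
    m <- match(paste(tr$probe_id, tr$snp_id),
               paste(rec$probe_id, rec$snp_id))
    slopes <- rbind(slopes, cbind(rec$slope_FU[m] - rec$slope_E[m],
                                  rec$slope_E[m]))
  }
  expect_lt(abs(mean(slopes[, 1]) - 0.5), 0.06)
  expect_lt(abs(mean(slopes[, 2])), 0.05)
})

test_that("pairs monomorphic within a status group are skipped", {
  sim <- tiny_cohort(seed = 75, n_snps = 10, n_probes = 4,
                     missing_rate = 0)
  # make SNP 1 monomorphic among controls
  ctl <- sim$metadata$clin_status == "Ctl"
  sim$genotypes$dosage[ctl, 1] <- 0L
  isc <- scan_interactions(sim$expression, sim$genotypes, sim$metadata,
                           emit = "all")
  expect_gte(isc$summary$n_skipped, 1)
  expect_false(sim$genotypes$map$snp_id[1] %in% isc$records$snp_id)
})

test_that("the Q-K refit with an identity K reproduces the OLS p-value", {
  sim <- tiny_cohort(seed = 76, n_snps = 40, n_probes = 10,
                     missing_rate = 0)
  isc <- scan_interactions(sim$expression, sim$genotypes, sim$metadata,
                           emit = "all")
  some <- isc$records[1:20, ]
  some$significant <- TRUE
  n <- length(sim$genotypes$sample_ids)
  ref <- refit_interactions(some, sim$expression, sim$genotypes,
                            sim$metadata, K = diag(n))
  expect_equal(ref$mixedmodel_p, ref$p, tolerance = 1e-6)
  expect_true(all(ref$refit_converged))
})

test_that("the refit honors the subset property and ancestry covariates", {
  sim <- tiny_cohort(seed = 77, n_snps = 50, n_probes = 20,
                     missing_rate = 0)
  isc <- scan_interactions(sim$expression, sim$genotypes, sim$metadata,
                           emit = "all")
  # refit_interactions on a scan object only touches screened hits
  ref <- refit_interactions(isc, sim$expression, sim$genotypes,
                            sim$metadata,
                            K = diag(length(sim$genotypes$sample_ids)))
  expect_true(all(paste(ref$probe_id, ref$snp_id) %in%
                    paste(isc$records$probe_id[isc$records$significant],
                          isc$records$snp_id[isc$records$significant])))
  # gPC covariates are accepted as fixed effects
  some <- isc$records[1:3, ]
  gpc <- genotype_pca(sim$genotypes, n_components = 2)$scores
  dz <- scdeqtl:::model_covariates(sim$metadata)
  X0 <- dz$X
  S <- X0[, grepl("^clin_status", colnames(X0)), drop = FALSE]
  gk <- sim$genotypes$dosage[, some$snp_id[1]]
  XI <- gk * S; colnames(XI) <- paste0("SNP:", colnames(S))
  fit <- fit_qk_mixed(sim$expression$values[some$probe_id[1], ],
                      cbind(X0, SNP = gk, XI), colnames(XI),
                      K = diag(nrow(X0)), Q = gpc)
  expect_true(fit$converged)
  expect_true(is.finite(fit$p))
})

test_that("finalize_interactions keeps only refit-significant records", {
  thr <- compute_bonferroni_thresholds(100, 1000)
  rec <- data.frame(probe_id = paste0("p", 1:4), snp_id = paste0("s", 1:4),
                    class = c("local", "local", "distal", "local"),
                    p = c(1e-10, 1e-9, 1e-14, 1e-9),
                    mixedmodel_p = c(thr$local / 10, thr$local * 10,
                                     thr$distal / 2, NA),
                    refit_converged = c(TRUE, TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  fin <- finalize_interactions(rec, thr)
  expect_equal(fin$n_final, 2)
  expect_setequal(fin$final$probe_id, c("p1", "p3"))
  expect_true("refit_failed" %in% fin$excluded$reason)
  # ordered by mixed-model p
  expect_true(all(diff(fin$final$mixedmodel_p) >= 0))
  empty <- finalize_interactions(rec[0, ], thr)
  expect_equal(empty$n_final, 0)
})

test_that("bending is applied to a non-PSD relatedness matrix", {
  K <- diag(5); K[1, 2] <- K[2, 1] <- 1.2   # forces a negative eigenvalue
  ev <- kinship_eigen(K)
  expect_true(ev$bent)
  expect_true(all(ev$values >= 0))
})
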