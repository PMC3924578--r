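test_that("two-tier Bonferroni arithmetic reproduces the printed thresholds", {
  # discovery-stage counts: 19,431 probes x 560,675 SNPs
  t1 <- compute_bonferroni_thresholds(19431, 560675, 200, 0.05)
  expect_equal(t1$distal, 0.05 / (19431 * 560675))
  expect_equal(t1$distal, 4.59e-12, tolerance = 0.005)
  expect_equal(t1$local, 1.28e-08, tolerance = 0.01)
  expect_equal(t1$distal_nlp, 11.34, tolerance = 0.001)
  expect_equal(t1$local_nlp, 7.89, tolerance = 0.001)
  # interaction-stage counts: 7,002 probes x 455,750 SNPs
  t2 <- compute_bonferroni_thresholds(7002, 455750, 200, 0.05)
  expect_equal(t2$distal, 1.57e-11, tolerance = 0.005)
  expect_equal(t2$local, 3.57e-08, tolerance = 0.005)
  expect_lt(t1$distal, t1$local)
  # degenerate single test: both tiers collapse to alpha
  t3 <- compute_bonferroni_thresholds(1, 1, 1, 0.05)
  expect_equal(t3$local, 0.05); expect_equal(t3$distal, 0.05)
  expect_error(compute_bonferroni_thresholds(0, 10), "positive")
})

test_that("local/distal classification follows chromosome identity", {
  expect_equal(classify_association("12", "12"), "local")
  expect_equal(classify_association("1", "2"), "distal")
  expect_equal(classify_association("chr7", "7"), "local")
  expect_true(is.na(classify_association(NA, "7")))
  expect_equal(classify_association(c("1", "2"), "1"),
               c("local", "distal"))
})

test_that("fit_model1 is exact in the noiseless case and matches lm", {
  g <- c(0, 1, 2, 0, 1, 2, 0, 1)
  fit <- fit_model1(2 * g, g)
  expect_equal(fit$beta, 2)
  expect_equal(fit$partial_r2, 1)
  # random small designs against the lm oracle
  for (s in 1:20) {
    set.seed(600 + s)
    n <- 25
    meta <- random_meta(n, seed = 600 + s)
    gd <- rbinom(n, 2, 0.4)
    if (length(unique(gd)) < 2) next
    y <- rnorm(n) + 0.3 * gd
    mine <- fit_model1(y, gd, meta)
    covars <- data.frame(status = factor(meta$clin_status),
                         sex = factor(meta$sex),
                         wbc = meta$wbc, rbc = meta$rbc)
    orc <- model1_lm_oracle(y, gd, covars)
    expect_equal(mine$beta, unname(orc$beta), tolerance = 1e-8)
    expect_equal(mine$se, unname(orc$se), tolerance = 1e-8)
    expect_equal(mine$p, unname(orc$p), tolerance = 1e-8)
    expect_equal(mine$partial_r2, orc$partial_r2, tolerance = 1e-8)
  }
  # monomorphic SNP in sample is not estimable
  expect_null(fit_model1(rnorm(8), rep(1, 8)))
})

test_that("the matrix scan equals per-pair brute-force OLS", {
  sim <- tiny_cohort(seed = 61, n_snps = 60, n_probes = 15,
                     missing_rate = 0.01)
  sc <- scan_esnps(sim$expression, sim$genotypes, sim$metadata,
                   emit = "all")
  rec <- sc$records
  set.seed(61)
  pick <- rec[sample(nrow(rec), 40), ]
  for (k in seq_len(nrow(pick))) {
    fit <- fit_model1(sim$expression$values[pick$probe_id[k], ],
                      sim$genotypes$dosage[, pick$snp_id[k]],
                      sim$metadata)
    expect_equal(pick$p[k], fit$p, tolerance = 1e-9)
    expect_equal(pick$beta[k], fit$beta, tolerance = 1e-9)
    expect_equal(pick$partial_r2[k], fit$partial_r2, tolerance = 1e-9)
  }
})

test_that("probes without a chromosome annotation are excluded", {
  sim <- tiny_cohort(seed = 62, n_snps = 30, n_probes = 10,
                     n_local_esnps = 0, n_distal_esnps = 0,
                     n_interaction_effects = 0)
  sim$expression$probes$chrom[1:3] <- NA
  sc <- scan_esnps(sim$expression, sim$genotypes, sim$metadata,
                   emit = "all")
  expect_equal(sc$summary$n_probes_excluded, 3)
  expect_false(any(sc$records$probe_id %in%
                     sim$expression$probes$probe_id[1:3]))
})

test_that("planted eSNPs are recovered and classified by chromosome", {
  sim <- tiny_cohort(seed = 63, n_local_esnps = 15, n_distal_esnps = 5,
                     esnp_r2 = 0.33, missing_rate = 0)
  sc <- scan_esnps(sim$expression, sim$genotypes, sim$metadata)
  tr <- sim$truth$esnp
  hits <- paste(sc$records$probe_id, sc$records$snp_id)
  found <- paste(tr$probe_id, tr$snp_id) %in% hits
  expect_gte(mean(found), 0.9)
  got <- sc$records[match(paste(tr$probe_id, tr$snp_id), hits), ]
  expect_identical(got$class[!is.na(got$class)],
                   tr$class[!is.na(got$class)])
})

test_that("peak selection takes the argmin with a deterministic tie rule", {
  rec <- data.frame(
    probe_id = c("p1", "p1", "p1", "p1", "p2", "p2"),
    snp_id = c("s1", "s2", "s3", "s4", "s9", "s5"),
    class = c("local", "local", "local", "distal", "local", "local"),
    beta = c(1, 2, 0.5, 1, 1, -1),
    p = c(1e-10, 1e-12, 1e-9, 1e-11, 1e-8, 1e-8),
    significant = TRUE, stringsAsFactors = FALSE)
  pk <- select_peak_associations(rec)
  expect_equal(nrow(pk), 3)     # p1 local, p1 distal, p2 local
  expect_equal(pk$snp_id[pk$probe_id == "p1" & pk$class == "local"], "s2")
  expect_equal(pk$snp_id[pk$probe_id == "p1" & pk$class == "distal"], "s4")
  # exact p tie on p2: equal |beta| -> lexicographically smaller snp_id
  expect_equal(pk$snp_id[pk$probe_id == "p2"], "s5")
})

test_that("conditioning attenuates a genotype-driven status effect only", {
  set.seed(64)
  n <- 200
  status <- sample(c("E", "FU", "Ctl"), n, replace = TRUE)
  meta <- data.frame(sample_id = sprintf("s%03d", 1:n),
                     family_id = sprintf("f%03d", 1:n),
                     hb_genotype = ifelse(status == "Ctl", "HbAA", "HbSS"),
                     clin_status = status,
                     sex = sample(c("M", "F"), n, TRUE),
                     wbc = rlnorm(n, log(10), 0.2),
                     rbc = rlnorm(n, log(3.5), 0.1),
                     phase = "discovery", stringsAsFactors = FALSE)
  # SNP correlated with status; probe A driven by the SNP only, probe B
  # by status directly
  g_raw <- rbinom(n, 2, ifelse(status == "FU", 0.7, 0.2))
  gm <- genotype_matrix(cbind(snp1 = as.integer(g_raw)),
                        data.frame(snp_id = "snp1", chrom = "1", pos = 100))
  rownames(gm$dosage) <- meta$sample_id
  gm$sample_ids <- meta$sample_id
  v <- rbind(A = 0.8 * g_raw + rnorm(n, 0, 0.4),
             B = ifelse(status == "FU", 1, 0) + rnorm(n, 0, 0.4))
  colnames(v) <- meta$sample_id
  e <- expression_matrix(v, data.frame(probe_id = c("A", "B"),
                                       chrom = "1", pos = c(90, 95)))
  peaks <- data.frame(probe_id = c("A", "B"), snp_id = "snp1",
                      stringsAsFactors = FALSE)
  cond <- condition_on_esnp(e, gm, meta, peaks)
  tab <- cond$table
  # genotype-driven probe: status NLP collapses after conditioning
  expect_gt(tab$nlp_nosnp[tab$probe_id == "A"] -
              tab$nlp_snp[tab$probe_id == "A"], 2)
  # direct status probe: NLP stays within noise
  expect_lt(abs(tab$nlp_nosnp[tab$probe_id == "B"] -
                  tab$nlp_snp[tab$probe_id == "B"]),
            0.5 * tab$nlp_nosnp[tab$probe_id == "B"])
})

test_that("conditioning on a null SNP leaves the fit unchanged up to df", {
  sim <- tiny_cohort(seed = 65, n_snps = 20, n_probes = 5,
                     n_local_esnps = 0, n_distal_esnps = 0,
                     n_interaction_effects = 0, missing_rate = 0)
  # a SNP with zero planted effect on the probe
  peaks <- data.frame(probe_id = "P00001", snp_id = "rs000001",
                      stringsAsFactors = FALSE)
  cond <- condition_on_esnp(sim$expression, sim$genotypes, sim$metadata,
                            peaks)
  expect_equal(cond$table$nlp_nosnp, cond$table$nlp_snp, tolerance = 0.5)
})
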