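test_that("minor allele frequency handles edge cases and allele counting", {
  expect_equal(minor_allele_frequency(rep(0L, 10)), 0)
  expect_equal(minor_allele_frequency(rep(1L, 10)), 0.5)
  # counts AA=50, Aa=30, aa=20 -> (2*20 + 30) / 200 = 0.35
  expect_equal(minor_allele_frequency(rep(c(0L, 1L, 2L), c(50, 30, 20))),
               0.35)
  expect_true(is.na(minor_allele_frequency(c(NA_integer_, NA_integer_))))
})

test_that("exact HWE p-values match full enumeration", {
  expect_equal(hwe_exact_pvalue(10, 0, 0), 1.0)
  expect_equal(hwe_exact_pvalue(0, 2, 0), hwe_enum_oracle(0, 2, 0))
  expect_equal(hwe_exact_pvalue(25, 50, 25), hwe_enum_oracle(25, 50, 25),
               tolerance = 1e-12)
  # a spread of tables including skewed and boundary cases
  cases <- rbind(c(5, 1, 4), c(20, 5, 0), c(1, 1, 1), c(0, 10, 0),
                 c(12, 2, 6), c(40, 9, 1))
  for (k in seq_len(nrow(cases))) {
    expect_equal(hwe_exact_pvalue(cases[k, 1], cases[k, 2], cases[k, 3]),
                 hwe_enum_oracle(cases[k, 1], cases[k, 2], cases[k, 3]),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_pvalue(-1, 2, 0), "non-negative")
})

test_that("SNP filters enforce MAF, call rate and HWE thresholds", {
  set.seed(31)
  n <- 400
  d <- cbind(
    maf04 = rbinom(n, 2, 0.04),         # below the 5% MAF floor
    good = rbinom(n, 2, 0.3),
    lowcall = ifelse(runif(n) < 0.05, NA_integer_, rbinom(n, 2, 0.3)),
    hwe_bad = rep(c(0L, 2L), n / 2))    # no heterozygotes at freq 0.5
  g <- genotype_matrix(d, data.frame(snp_id = colnames(d), chrom = "1",
                                     pos = 1:4))
  res <- filter_snps(g, analysis_config(), verbose = FALSE)
  expect_identical(res$genotypes$map$snp_id, "good")
  rep_ <- res$report
  expect_match(rep_$reason[rep_$snp_id == "maf04"], "maf")
  expect_match(rep_$reason[rep_$snp_id == "lowcall"], "callrate")
  expect_match(rep_$reason[rep_$snp_id == "hwe_bad"], "hwe")
})

test_that("per-group filtering applies every criterion in every group", {
  set.seed(32)
  grp <- rep(c("E", "Ctl"), each = 200)
  d <- cbind(ok = rbinom(400, 2, 0.3),
             rare_in_ctl = c(rbinom(200, 2, 0.20), rbinom(200, 2, 0.01)))
  g <- genotype_matrix(d, data.frame(snp_id = colnames(d), chrom = "1",
                                     pos = 1:2))
  res <- filter_snps(g, analysis_config(), groups = grp, verbose = FALSE)
  expect_identical(res$genotypes$map$snp_id, "ok")
})

test_that("simulated common SNPs survive QC at nominal thresholds", {
  cfg <- sim_config(seed = 15, sibling_fraction = 0, n_snps = 500,
                    maf_range = c(0.3, 0.3), missing_rate = 0)
  g <- simulate_genotypes(cfg)
  res <- filter_snps(g, analysis_config(), verbose = FALSE)
  expect_gte(ncol(res$genotypes$dosage), 0.98 * 500)
})

test_that("quantile normalization equalizes per-sample distributions", {
  # hand-computed 3 x 2 case on the log2 scale
  raw <- cbind(s1 = c(1, 2, 3), s2 = c(4, 8, 16))
  e <- expression_matrix(raw, data.frame(probe_id = c("a", "b", "c")))
  qn <- log2_quantile_normalize(e)
  target <- (sort(log2(raw[, 1])) + sort(log2(raw[, 2]))) / 2
  expect_equal(sort(qn$values[, 1]), target, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sort(qn$values[, 2]), target, tolerance = 1e-12,
               ignore_attr = TRUE)
  # idempotence and exact sorted-column equality on a larger matrix
  set.seed(33)
  big <- expression_matrix(matrix(rlnorm(500 * 8, 5, 1), 500, 8,
                                  dimnames = list(sprintf("p%03d", 1:500),
                                                  sprintf("s%d", 1:8))),
                           data.frame(probe_id = sprintf("p%03d", 1:500)))
  qn1 <- log2_quantile_normalize(big)
  for (j in 2:8) {
    expect_equal(sort(qn1$values[, j]), sort(qn1$values[, 1]),
                 ignore_attr = TRUE)
  }
  qn2 <- log2_quantile_normalize(qn1, log2_input = FALSE)
  expect_equal(qn2$values, qn1$values, tolerance = 1e-12)
  # identical columns stay identical; single sample is log2 only
  same <- expression_matrix(cbind(a = c(2, 4), b = c(2, 4)),
                            data.frame(probe_id = c("x", "y")))
  expect_equal(log2_quantile_normalize(same)$values,
               log2(same$values), tolerance = 1e-12)
  single <- expression_matrix(cbind(only = c(2, 4, 8)),
                              data.frame(probe_id = c("x", "y", "z")))
  expect_equal(log2_quantile_normalize(single)$values,
               log2(single$values))
  # non-positive intensities are rejected with the cell named
  bad <- expression_matrix(cbind(s1 = c(1, -2), s2 = c(3, 4)),
                           data.frame(probe_id = c("pa", "pb")))
  expect_error(log2_quantile_normalize(bad), "pb")
})

test_that("background knee filter separates bimodal probe intensities", {
  set.seed(34)
  mu <- c(rnorm(600, 10, 0.5), rnorm(400, 4, 0.5))   # expressed vs background
  v <- matrix(rnorm(1000 * 6, mu, 0.2), 1000, 6,
              dimnames = list(sprintf("p%04d", 1:1000), sprintf("s%d", 1:6)))
  e <- expression_matrix(v, data.frame(probe_id = rownames(v)))
  res <- background_filter(e, verbose = FALSE)
  expect_gt(res$cutoff, 6); expect_lt(res$cutoff, 9.5)
  kept_high <- sum(res$report$retained[1:600])
  kept_low <- sum(res$report$retained[601:1000])
  expect_gte(kept_high, 590)
  expect_lte(kept_low, 10)
  # explicit cutoffs: keep everything / drop everything
  all_in <- background_filter(e, cutoff = min(rowMeans(v)) - 1,
                              verbose = FALSE)
  expect_equal(nrow(all_in$expression$values), 1000)
  expect_warning(
    none <- background_filter(e, cutoff = max(rowMeans(v)) + 1,
                              verbose = FALSE),
    "no probes")
  expect_equal(nrow(none$expression$values), 0)
  # snp-overlap probes are removed regardless of intensity
  ov <- background_filter(e, cutoff = 0, snp_overlap = c("p0001", "p0002"),
                          verbose = FALSE)
  expect_false(any(c("p0001", "p0002") %in%
                     rownames(ov$expression$values)))
  # a featureless linear ramp has no knee
  ramp <- matrix(seq(1, 10, length.out = 500), 500, 4,
                 dimnames = list(sprintf("r%03d", 1:500), paste0("s", 1:4)))
  er <- expression_matrix(ramp, data.frame(probe_id = rownames(ramp)))
  expect_error(background_filter(er, verbose = FALSE), "knee")
})

test_that("technical replicate averaging collapses arrays per sample", {
  v <- cbind(a1 = c(4, 1), a2 = c(6, 3), b = c(5, 5))
  rownames(v) <- c("p1", "p2")
  e <- expression_matrix(v, data.frame(probe_id = c("p1", "p2")))
  rm_ <- data.frame(array_id = c("a1", "a2"), sample_id = c("sA", "sA"))
  avg <- average_technical_replicates(e, rm_)
  expect_equal(unname(avg$values[, "sA"]), c(5, 2))
  expect_equal(unname(avg$values[, "b"]), c(5, 5))
  # no replicates declared -> identity; absent arrays -> error
  expect_identical(average_technical_replicates(e, NULL)$values, e$values)
  expect_error(average_technical_replicates(
    e, data.frame(array_id = "zz", sample_id = "s")), "zz")
})
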