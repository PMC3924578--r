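# Independent oracles used across the suite.  These deliberately use
# brute-force formulations (full enumeration, lm()-based normal equations)
# rather than the package's own code paths.

# Exact HWE p by full enumeration of the conditional distribution of
# heterozygote counts given allele counts: P(h) proportional to
# n! / (hr! h! hc!) * 2^h, normalized over the support.
hwe_enum_oracle <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  rare <- 2L * min(n_hom_major, n_hom_minor) + n_het
  if (rare == 0L) return(1.0)
  hs <- seq.int(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  logp <- vapply(hs, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# lm()-based oracle for the SNP term of Model 1: returns beta, se, t, p
# and the partial R^2 from explicit RSS bookkeeping.
model1_lm_oracle <- function(y, g, covars) {
  dat <- data.frame(y = y, g = g, covars)
  full <- lm(y ~ ., data = dat)
  red <- lm(y ~ . - g, data = dat)
  sm <- summary(full)$coefficients["g", ]
  list(beta = sm[1], se = sm[2], t = sm[3], p = sm[4],
       partial_r2 = (deviance(red) - deviance(full)) / deviance(red))
}

# lm()/anova()-based partial F oracle for the SNP-by-status interaction.
model2_lm_oracle <- function(y, g, status, covars) {
  dat <- data.frame(y = y, g = g, status = factor(status), covars)
  m1 <- lm(y ~ ., data = dat)
  m2 <- lm(y ~ . + g:status, data = dat)
  a <- anova(m1, m2)
  list(F = a$F[2], p = a$`Pr(>F)`[2], df1 = a$Df[2], df2 = a$Res.Df[2])
}

# Small random metadata table with independent (non-aliased) factors.
random_meta <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    family_id = sprintf("f%03d", seq_len(n)),
    hb_genotype = sample(c("HbSS", "HbSC"), n, replace = TRUE),
    clin_status = sample(c("E", "FU", "Ctl"), n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    wbc = rlnorm(n, log(10), 0.3),
    rbc = rlnorm(n, log(3.5), 0.15),
    phase = sample(c("discovery", "replication"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Tiny aligned cohort wrapper for scan-level tests: planted effects are
# off unless a test asks for them, so small probe panels stay valid.
tiny_cohort <- function(seed = 1, ...) {
  args <- list(seed = seed, ...)
  for (nm in c("n_local_esnps", "n_distal_esnps",
               "n_interaction_effects")) {
    if (is.null(args[[nm]])) args[[nm]] <- 0L
  }
  simulate_cohort(do.call(sim_config, args))
}
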