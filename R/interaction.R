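#' Greedy windowed LD pruning
#'
#' Pre-filters to SNPs with MAF >= `maf_min` and zero missingness, then
#' slides a window along each chromosome dropping one SNP of every pair
#' whose squared dosage correlation reaches `r2_max` (the
#' earlier-position SNP is kept).  This is the SNP set used for
#' relatedness estimation.
#'
#' @param g a `genotype_matrix`.
#' @param r2_max squared-correlation ceiling.
#' @param maf_min MAF floor.
#' @param window,step window size and slide step, in SNPs.
#' @param verbose log before/after counts.
#' @return the pruned `genotype_matrix`.
#' @export
ld_prune <- function(g, r2_max = 0.3, maf_min = 0.10, window = 50L,
                     step = 5L, verbose = TRUE) {
  maf <- minor_allele_frequency(g$dosage)
  complete <- colSums(is.na(g$dosage)) == 0L
  pre <- !is.na(maf) & maf >= maf_min & complete
  keep <- pre
  ord <- order(norm_chrom(g$map$chrom), g$map$pos)
  for (cc in unique(norm_chrom(g$map$chrom))) {
    idx <- ord[norm_chrom(g$map$chrom)[ord] == cc]
    idx <- idx[keep[idx]]
    if (length(idx) < 2L) next
    start <- 1L
    repeat {
      stop_at <- min(start + window - 1L, length(idx))
      win <- idx[start:stop_at]
      win <- win[keep[win]]
      if (length(win) >= 2L) {
        cm <- suppressWarnings(cor(g$dosage[, win, drop = FALSE]))^2
        for (a in seq_len(length(win) - 1L)) {
          if (!keep[win[a]]) next
          for (b in seq.int(a + 1L, length(win))) {
            if (keep[win[b]] && is.finite(cm[a, b]) && cm[a, b] >= r2_max) {
              keep[win[b]] <- FALSE
            }
          }
        }
      }
      if (stop_at >= length(idx)) break
      start <- start + step
    }
  }
  log_filter("LD pruning", ncol(g$dosage), sum(keep), verbose)
  g$dosage <- g$dosage[, keep, drop = FALSE]
  g$map <- g$map[keep, , drop = FALSE]
  rownames(g$map) <- NULL
  g
}

#' Pairwise relatedness (pi-hat) by method of moments
#'
#' PLINK-style estimation: per-pair identity-by-state (IBS) counts are
#' converted to IBD state probabilities using their allele-frequency
#' expectations, and `pihat = P(IBD=1)/2 + P(IBD=2)`.  Estimates are
#' truncated to [0, 1]; the diagonal is fixed at 1.  Pairs sharing fewer
#' than `min_snps` comparable SNPs are returned as `NA`.  Finite-sample
#' allele-count corrections are omitted (adequate for the pruned,
#' common-variant SNP sets this is run on).
#'
#' @param g a (pruned) `genotype_matrix`.
#' @param min_snps minimum comparable SNPs per pair.
#' @return list of class `kinship_matrix`: `pihat` (symmetric matrix),
#'   `sample_ids`, `n_snps`.
#' @export
estimate_kinship <- function(g, min_snps = 50L) {
  d <- g$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  if (ncol(d) == 0L) stopf("no polymorphic SNPs for kinship estimation")
  q <- 1 - p
  ok <- !is.na(d)
  I0 <- (d == 0L) & ok; I1 <- (d == 1L) & ok; I2 <- (d == 2L) & ok
  mode(I0) <- "numeric"; mode(I1) <- "numeric"; mode(I2) <- "numeric"
  okn <- ok; mode(okn) <- "numeric"
  n_obs <- tcrossprod(okn)
  ibs0 <- tcrossprod(I0, I2) + tcrossprod(I2, I0)
  ibs2 <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  ibs1 <- n_obs - ibs0 - ibs2
  # per-SNP IBS expectations given IBD state
  e0_z0 <- 2 * p^2 * q^2
  e1_z0 <- 4 * p^3 * q + 4 * p * q^3
  e2_z0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_z1 <- 2 * p^2 * q + 2 * p * q^2
  e2_z1 <- p^3 + q^3 + p^2 * q + p * q^2
  exp_pair <- function(e) tcrossprod(okn, sweep(okn, 2, e, "*"))
  E0_0 <- exp_pair(e0_z0); E1_0 <- exp_pair(e1_z0); E2_0 <- exp_pair(e2_z0)
  E1_1 <- exp_pair(e1_z1); E2_1 <- exp_pair(e2_z1)
  P0 <- ibs0 / E0_0
  P1 <- (ibs1 - P0 * E1_0) / E1_1
  P2 <- (ibs2 - P0 * E2_0 - P1 * E2_1) / n_obs
  pihat <- P1 / 2 + P2
  pihat <- pmin(pmax(pihat, 0), 1)
  pihat[n_obs < min_snps] <- NA_real_
  diag(pihat) <- 1
  dimnames(pihat) <- list(g$sample_ids, g$sample_ids)
  structure(list(pihat = pihat, sample_ids = g$sample_ids,
                 n_snps = ncol(d)),
            class = "kinship_matrix")
}

#' SNP-by-clinical-status interaction scan (Model 2)
#'
#' For each probe-SNP pair, compares
#' `expression = mu + SNP + ClinStatus + WBC + RBC + Sex + SNP:ClinStatus`
#' (Model 2) against the same model without the interaction (Model 1) by
#' partial F test, vectorized over probes per SNP.  Pairs where any
#' status group is monomorphic for the SNP are skipped (non-estimable
#' interaction).  Per-group allelic slopes are reported alongside the
#' test.  Significance uses the two-tier Bonferroni scheme with the
#' interaction-stage probe and SNP counts.
#'
#' @param e an `expression_matrix`, typically already restricted to
#'   differentially expressed probes (or pass `de_probes`).
#' @param g a `genotype_matrix` after per-group QC.
#' @param meta aligned metadata.
#' @param thresholds a `threshold_scheme`; default computed from the
#'   scanned dimensions.
#' @param de_probes optional probe-id vector restricting the scan.
#' @param covariate_terms covariates besides the SNP.
#' @param emit "significant" or "all".
#' @return list of class `interaction_scan`: `records` (probe_id,
#'   snp_id, class, F, df1, df2, p, per-level `slope_*`, significant),
#'   `summary`, `thresholds`.
#' @export
scan_interactions <- function(e, g, meta, thresholds = NULL,
                              de_probes = NULL,
                              covariate_terms = c("clin_status", "sex",
                                                  "wbc", "rbc"),
                              emit = c("significant", "all")) {
  emit <- match.arg(emit)
  stopifnot(identical(e$sample_ids, g$sample_ids),
            identical(e$sample_ids, meta$sample_id))
  if (!is.null(de_probes)) {
    keep <- rownames(e$values) %in% de_probes
    e$values <- e$values[keep, , drop = FALSE]
    e$probes <- e$probes[keep, , drop = FALSE]
  }
  probe_ok <- !is.na(norm_chrom(e$probes$chrom))
  probes <- e$probes[probe_ok, , drop = FALSE]
  Y <- t(e$values[probe_ok, , drop = FALSE])
  if (is.null(thresholds)) {
    thresholds <- compute_bonferroni_thresholds(nrow(probes),
                                                ncol(g$dosage))
  }
  dz <- model_covariates(meta, covariate_terms)
  if (!all(dz$keep)) stopf("samples with missing covariates")
  X0 <- dz$X
  status <- factor(meta$clin_status)
  lv <- levels(status)
  S <- X0[, grepl("^clin_status", colnames(X0)), drop = FALSE]
  probe_chrom <- norm_chrom(probes$chrom)
  snp_chrom <- norm_chrom(g$map$chrom)
  n_skipped <- 0L
  n_tested <- 0L
  recs <- list()
  for (j in seq_len(ncol(g$dosage))) {
    gj <- g$dosage[, j]
    ok <- !is.na(gj)
    mono_in_group <- vapply(lv, function(l) {
      length(unique(gj[ok & status == l])) < 2L
    }, logical(1))
    if (any(mono_in_group)) { n_skipped <- n_skipped + 1L; next }
    X1 <- cbind(X0[ok, , drop = FALSE], SNP = gj[ok])
    XI <- gj[ok] * S[ok, , drop = FALSE]
    colnames(XI) <- paste0("SNP:", colnames(S))
    X2 <- cbind(X1, XI)
    q1 <- qr(X1); q2 <- qr(X2)
    df1 <- q2$rank - q1$rank
    df2 <- sum(ok) - q2$rank
    if (df1 < 1L || df2 < 1L) { n_skipped <- n_skipped + 1L; next }
    Ys <- Y[ok, , drop = FALSE]
    rss1 <- colSums(qr.resid(q1, Ys)^2)
    rss2 <- colSums(qr.resid(q2, Ys)^2)
    fstat <- pmax(0, ((rss1 - rss2) / df1) / (rss2 / df2))
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
    n_tested <- n_tested + length(p)
    cls <- ifelse(probe_chrom == snp_chrom[j], "local", "distal")
    thr <- ifelse(cls == "local", thresholds$local, thresholds$distal)
    keep <- if (emit == "all") rep(TRUE, length(p)) else p < thr
    if (!any(keep)) next
    B <- qr.coef(q2, Ys[, keep, drop = FALSE])
    ref <- lv[1]
    slope_ref <- B["SNP", ]
    slopes <- matrix(slope_ref, nrow = length(lv), ncol = sum(keep),
                     byrow = TRUE,
                     dimnames = list(lv, NULL))
    for (l in lv[-1]) {
      rn <- paste0("SNP:clin_status", l)
      if (rn %in% rownames(B)) slopes[l, ] <- slope_ref + B[rn, ]
    }
    df <- data.frame(probe_id = probes$probe_id[keep],
                     snp_id = g$map$snp_id[j], class = cls[keep],
                     F = fstat[keep], df1 = df1, df2 = df2, p = p[keep],
                     stringsAsFactors = FALSE)
    for (l in lv) df[[paste0("slope_", l)]] <- slopes[l, ]
    recs[[length(recs) + 1L]] <- df
  }
  records <- if (length(recs)) do.call(rbind, recs) else NULL
  if (is.null(records)) {
    records <- data.frame(probe_id = character(0), snp_id = character(0),
                          class = character(0), F = numeric(0),
                          df1 = integer(0), df2 = integer(0),
                          p = numeric(0), stringsAsFactors = FALSE)
    for (l in lv) records[[paste0("slope_", l)]] <- numeric(0)
  }
  thr_of <- ifelse(records$class == "local", thresholds$local,
                   thresholds$distal)
  records$significant <- records$p < thr_of
  rownames(records) <- NULL
  structure(list(records = records,
                 summary = list(n_probes = nrow(probes),
                                n_snps = ncol(g$dosage),
                                n_tested = n_tested,
                                n_skipped = n_skipped,
                                n_significant = sum(records$significant)),
                 thresholds = thresholds),
            class = "interaction_scan")
}

#' Precompute the spectral decomposition of a relationship matrix
#'
#' @param K symmetric relatedness matrix (pihat scale, diagonal 1) or a
#'   `kinship_matrix`.
#' @return list of class `kinship_eigen` with `values` (negative
#'   eigenvalues bent up to zero, logged via attribute `bent`) and
#'   `vectors`.
#' @export
kinship_eigen <- function(K) {
  if (inherits(K, "kinship_matrix")) K <- K$pihat
  if (!isSymmetric(unname(K), tol = 1e-8)) stopf("K must be symmetric")
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
  bent <- any(ev$values < -1e-8)
  ev$values <- pmax(ev$values, 0)
  structure(list(values = ev$values, vectors = ev$vectors, bent = bent),
            class = "kinship_eigen")
}

#' Q-K mixed-model fit with a Wald F test on selected coefficients
#'
#' Linear mixed model `y = X beta + u + eps` with
#' `cov(u) = sigma_g^2 * A`, where `A` is the relationship matrix
#' (pihat scale: 1 on the diagonal, 0.5 for full sibs, i.e. twice the
#' kinship coefficient).  The variance ratio is estimated by REML via a
#' one-dimensional profile over the spectral decomposition of `A`;
#' non-positive-definite input is bent by truncating negative eigenvalues
#' at zero.  Inference on `test_cols` is a Wald F with residual-based
#' denominator degrees of freedom.  Ancestry covariates `Q` (genotype PC
#' scores) enter as fixed effects.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (including intercept, SNP and
#'   interaction columns).
#' @param test_cols column names (or indices) of `X` tested jointly.
#' @param K relationship matrix, `kinship_matrix`, or a precomputed
#'   [kinship_eigen()].
#' @param Q optional matrix of ancestry covariates appended to `X`.
#' @return list of class `qk_fit`: `p`, `F`, `df1`, `df2`, `lambda`
#'   (sigma_g^2 / sigma_e^2), `sigma_g2`, `sigma_e2`, `beta`,
#'   `converged`, `bent`.
#' @export
fit_qk_mixed <- function(y, X, test_cols, K, Q = NULL) {
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    colnames(Q) <- paste0("Q", seq_len(ncol(Q)))
    X <- cbind(X, Q)
  }
  if (is.character(test_cols)) test_cols <- match(test_cols, colnames(X))
  if (anyNA(test_cols)) stopf("test_cols not found in design")
  ev <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  n <- length(y)
  stopifnot(nrow(X) == n, length(ev$values) == n)
  U <- ev$vectors
  d <- ev$values
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  p_rank <- qr(X)$rank
  reml_ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (1 + lam * d)
    sw <- sqrt(w)
    qw <- qr(Xs * sw)
    rss <- sum(qr.resid(qw, ys * sw)^2)
    sigma_e2 <- rss / (n - p_rank)
    logdet_xvx <- 2 * sum(log(abs(diag(qr.R(qw))[seq_len(qw$rank)])))
    -0.5 * ((n - p_rank) * log(sigma_e2) - sum(log(w)) + logdet_xvx)
  }
  opt <- tryCatch(
    stats::optimize(reml_ll, interval = c(-12, 12), maximum = TRUE),
    error = function(e) NULL)
  if (is.null(opt)) {
    return(structure(list(p = NA_real_, F = NA_real_, df1 = NA,
                          df2 = NA, lambda = NA_real_,
                          sigma_g2 = NA_real_, sigma_e2 = NA_real_,
                          beta = NULL, converged = FALSE,
                          bent = isTRUE(ev$bent)), class = "qk_fit"))
  }
  lam <- exp(opt$maximum)
  # boundary polish: a flat profile at the lower edge means lambda ~ 0
  if (reml_ll(-12) >= opt$objective) lam <- 0
  w <- 1 / (1 + lam * d)
  sw <- sqrt(w)
  qw <- qr(Xs * sw)
  beta <- qr.coef(qw, ys * sw)
  rss <- sum(qr.resid(qw, ys * sw)^2)
  df2 <- n - p_rank
  sigma_e2 <- rss / df2
  XtVX_inv <- chol2inv(qr.R(qw))
  # chol2inv returns the inverse in pivoted order; restore
  piv <- qw$pivot[seq_len(qw$rank)]
  covb <- matrix(NA_real_, ncol(X), ncol(X))
  covb[piv, piv] <- XtVX_inv[seq_len(qw$rank), seq_len(qw$rank)] * sigma_e2
  b <- beta[test_cols]
  Vb <- covb[test_cols, test_cols, drop = FALSE]
  if (anyNA(b) || anyNA(Vb)) {
    fstat <- NA_real_; pval <- NA_real_; df1 <- NA_integer_
  } else {
    df1 <- length(test_cols)
    fstat <- as.numeric(t(b) %*% solve(Vb, b)) / df1
    pval <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  }
  structure(list(p = pval, F = fstat, df1 = df1, df2 = df2,
                 lambda = lam, sigma_g2 = lam * sigma_e2,
                 sigma_e2 = sigma_e2, beta = beta, converged = TRUE,
                 bent = isTRUE(ev$bent)), class = "qk_fit")
}

#' Mixed-model refit of OLS-significant interaction records
#'
#' Re-tests each OLS-significant SNP-by-status interaction in the Q-K
#' mixed model (relatedness as a random effect, optional ancestry PCs as
#' fixed covariates).  Applied only to the screened hits because the
#' mixed fit is the expensive step.
#'
#' @param scan an `interaction_scan` (or its significant records).
#' @param e,g,meta aligned inputs.
#' @param K relationship matrix / `kinship_matrix` / `kinship_eigen`.
#' @param Q optional ancestry covariate matrix (rows = samples).
#' @param covariate_terms covariates besides the SNP.
#' @return the records data frame with added `mixedmodel_p`,
#'   `mixedmodel_F`, `refit_converged` columns.
#' @export
refit_interactions <- function(scan, e, g, meta, K, Q = NULL,
                               covariate_terms = c("clin_status", "sex",
                                                   "wbc", "rbc")) {
  records <- if (inherits(scan, "interaction_scan")) {
    scan$records[scan$records$significant, , drop = FALSE]
  } else scan
  if (nrow(records) == 0L) {
    records$mixedmodel_p <- numeric(0)
    records$mixedmodel_F <- numeric(0)
    records$refit_converged <- logical(0)
    return(records)
  }
  dz <- model_covariates(meta, covariate_terms)
  X0 <- dz$X
  S <- X0[, grepl("^clin_status", colnames(X0)), drop = FALSE]
  ev <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  records$mixedmodel_p <- NA_real_
  records$mixedmodel_F <- NA_real_
  records$refit_converged <- FALSE
  for (k in seq_len(nrow(records))) {
    gk <- g$dosage[, records$snp_id[k]]
    if (anyNA(gk)) next    # refit requires the zero-missingness SNP set
    XI <- gk * S
    colnames(XI) <- paste0("SNP:", colnames(S))
    X <- cbind(X0, SNP = gk, XI)
    fit <- fit_qk_mixed(e$values[records$probe_id[k], ], X,
                        test_cols = colnames(XI), K = ev, Q = Q)
    records$mixedmodel_p[k] <- fit$p
    records$mixedmodel_F[k] <- fit$F
    records$refit_converged[k] <- fit$converged
  }
  records
}

#' Final relatedness-corrected interaction set
#'
#' Records whose mixed-model p-value stays below the class-appropriate
#' interaction threshold are flagged final; non-converged refits are
#' excluded with a reason.  Ordered by mixed-model p.
#'
#' @param records output of [refit_interactions()].
#' @param thresholds the interaction-stage `threshold_scheme`.
#' @return list: `final` (surviving records), `excluded` (records with a
#'   `reason` column), `n_screen`, `n_final`.
#' @export
finalize_interactions <- function(records, thresholds) {
  if (nrow(records) == 0L) {
    return(list(final = records, excluded = records, n_screen = 0L,
                n_final = 0L))
  }
  thr <- ifelse(records$class == "local", thresholds$local,
                thresholds$distal)
  ok_fit <- records$refit_converged & !is.na(records$mixedmodel_p)
  final_flag <- ok_fit & records$mixedmodel_p < thr
  excluded <- records[!final_flag, , drop = FALSE]
  excluded$reason <- ifelse(!ok_fit[!final_flag], "refit_failed",
                            "not_significant_after_refit")
  final <- records[final_flag, , drop = FALSE]
  final <- final[order(final$mixedmodel_p), , drop = FALSE]
  rownames(final) <- NULL
  list(final = final, excluded = excluded, n_screen = nrow(records),
       n_final = nrow(final))
}
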