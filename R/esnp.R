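#' Two-tier Bonferroni thresholds for eSNP scans
#'
#' Distal (different-chromosome) tests are corrected for all probe x SNP
#' pairs, `alpha / (n_probes * n_snps_total)`; local (same-chromosome)
#' tests for the assumed average number of SNPs tested against each probe,
#' `alpha / (n_probes * avg_local_snps)`.
#'
#' @param n_probes number of expressed probes tested.
#' @param n_snps_total total number of SNPs tested.
#' @param avg_local_snps assumed SNPs per probe for the local tier
#'   (a fixed convention, default 200).
#' @param alpha family-wise error level.
#' @return list of class `threshold_scheme`: `local`, `distal`,
#'   `local_nlp`, `distal_nlp` plus the input counts.
#' @export
compute_bonferroni_thresholds <- function(n_probes, n_snps_total,
                                          avg_local_snps = 200,
                                          alpha = 0.05) {
  if (n_probes < 1 || n_snps_total < 1 || avg_local_snps < 1) {
    stopf("counts must be positive")
  }
  local <- alpha / (n_probes * avg_local_snps)
  distal <- alpha / (n_probes * n_snps_total)
  structure(list(local = local, distal = distal,
                 local_nlp = -log10(local), distal_nlp = -log10(distal),
                 n_probes = n_probes, n_snps_total = n_snps_total,
                 avg_local_snps = avg_local_snps, alpha = alpha),
            class = "threshold_scheme")
}

#' Classify a probe-SNP pair as local or distal
#'
#' Same chromosome is local, different chromosomes distal; a pair with a
#' missing probe location is excluded (`NA`).
#'
#' @param probe_chrom,snp_chrom chromosome labels (vectors recycle).
#' @return character vector "local"/"distal"/`NA`.
#' @export
classify_association <- function(probe_chrom, snp_chrom) {
  pc <- norm_chrom(probe_chrom)
  sc <- norm_chrom(snp_chrom)
  ifelse(is.na(pc) | is.na(sc), NA_character_,
         ifelse(pc == sc, "local", "distal"))
}

## Covariate design for Model 1 / Model 2 (everything except the SNP).
model_covariates <- function(meta, terms = c("clin_status", "sex",
                                             "wbc", "rbc")) {
  build_design(meta, terms, contrasts = "contr.treatment")
}

#' Fit Model 1 for one probe-SNP pair
#'
#' OLS of `expression = mu + SNP + ClinStatus + WBC + RBC + Sex + error`
#' with additive minor-allele-dosage coding; samples with a missing
#' dosage are dropped for this pair.  The SNP's partial R-squared is
#' `(RSS_reduced - RSS_full) / RSS_reduced`, the reduced model omitting
#' the SNP term.
#'
#' @param y numeric expression vector.
#' @param dosage numeric dosage vector (`NA` = missing call).
#' @param meta aligned metadata (or `NULL` for a covariate-free fit).
#' @param covariate_terms covariate columns of `meta`.
#' @return one-row data frame: beta, se, t, p, partial_r2, n_used; or
#'   `NULL` when the SNP is monomorphic among the used samples.
#' @export
fit_model1 <- function(y, dosage, meta = NULL,
                       covariate_terms = c("clin_status", "sex",
                                           "wbc", "rbc")) {
  ok <- !is.na(dosage) & !is.na(y)
  if (!is.null(meta)) {
    ok <- ok & stats::complete.cases(meta[, covariate_terms, drop = FALSE])
  }
  y <- y[ok]; g <- dosage[ok]
  if (length(unique(g)) < 2L) return(NULL)
  X0 <- if (is.null(meta)) {
    matrix(1, length(y), 1)
  } else {
    model_covariates(meta[ok, , drop = FALSE], covariate_terms)$X
  }
  X <- cbind(X0, SNP = g)
  qf <- qr(X)
  q0 <- qr(X0)
  rss_f <- sum(qr.resid(qf, y)^2)
  rss_r <- sum(qr.resid(q0, y)^2)
  df <- length(y) - qf$rank
  beta <- qr.coef(qf, y)[["SNP"]]
  partial_r2 <- if (rss_r > 0) (rss_r - rss_f) / rss_r else 0
  if (rss_f <= 0) {
    t_stat <- sign(beta) * Inf
    se <- 0
    p <- 0
  } else {
    XtXinv <- chol2inv(qr.R(qf))       # in pivoted column order
    jj <- match(which(colnames(X) == "SNP"), qf$pivot)
    se <- sqrt(XtXinv[jj, jj] * rss_f / df)
    t_stat <- beta / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  data.frame(beta = beta, se = se, t = t_stat, p = p,
             partial_r2 = partial_r2, n_used = length(y))
}

## Fast scan core: Frisch-Waugh-Lovell residualization.  Both expression
## and dosage are residualized against the covariate design, after which
## the per-pair correlation of residuals reproduces the OLS t test of the
## SNP coefficient exactly (identical RSS bookkeeping, df = n - p - 1).
scan_pairs_complete <- function(Yr, Gr, df) {
  ey <- colSums(Yr^2)
  eg <- colSums(Gr^2)
  num <- crossprod(Yr, Gr)                      # probes x snps
  denom <- outer(sqrt(ey), sqrt(eg))
  r <- num / denom
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(t_stat), df)
  beta <- sweep(num, 2, eg, "/")
  list(r2 = r^2, t = t_stat, p = p, beta = beta)
}

#' Genome-wide eSNP scan under Model 1
#'
#' Tests every probe-SNP pair for association between expression and
#' minor-allele dosage, adjusting for clinical status, sex and blood cell
#' counts.  Pairs are classified local/distal by chromosome and compared
#' to the class-appropriate two-tier Bonferroni threshold.  Probes
#' without a chromosome annotation are excluded; SNPs monomorphic among
#' the used samples are skipped and counted.  SNPs with missing calls are
#' refitted per SNP on their complete samples; fully observed SNPs go
#' through a residualized matrix path that reproduces per-pair OLS
#' exactly.
#'
#' @param e an `expression_matrix` (aligned).
#' @param g a `genotype_matrix` (aligned).
#' @param meta aligned metadata.
#' @param thresholds a `threshold_scheme`; default computed from the
#'   input dimensions with `avg_local_snps = 200`.
#' @param covariate_terms model covariates.
#' @param emit "significant" (default) returns only sub-threshold
#'   records; "all" returns every estimable pair.
#' @param block number of SNPs per processing block.
#' @return list of class `esnp_scan`: `records` (probe_id, snp_id, class,
#'   beta, t, p, partial_r2, n_used, significant), `summary` (test and
#'   hit counts), `thresholds`.
#' @export
scan_esnps <- function(e, g, meta, thresholds = NULL,
                       covariate_terms = c("clin_status", "sex",
                                           "wbc", "rbc"),
                       emit = c("significant", "all"), block = 2000L) {
  emit <- match.arg(emit)
  stopifnot(identical(e$sample_ids, g$sample_ids),
            identical(e$sample_ids, meta$sample_id))
  probe_ok <- !is.na(norm_chrom(e$probes$chrom))
  n_probes_excluded <- sum(!probe_ok)
  probes <- e$probes[probe_ok, , drop = FALSE]
  Y <- t(e$values[probe_ok, , drop = FALSE])
  if (is.null(thresholds)) {
    thresholds <- compute_bonferroni_thresholds(nrow(probes),
                                                ncol(g$dosage))
  }
  dz <- model_covariates(meta, covariate_terms)
  if (!all(dz$keep)) {
    stopf("samples with missing covariates; align/complete metadata first")
  }
  X <- dz$X
  qx <- qr(X)
  n <- nrow(Y)
  df <- n - qx$rank - 1L
  Yr <- qr.resid(qx, Y)
  probe_chrom <- norm_chrom(probes$chrom)
  snp_chrom <- norm_chrom(g$map$chrom)

  n_tested <- 0L
  n_mono <- 0L
  recs <- list()
  m <- ncol(g$dosage)
  for (start in seq(1L, m, by = block)) {
    idx <- start:min(start + block - 1L, m)
    D <- g$dosage[, idx, drop = FALSE]
    has_na <- colSums(is.na(D)) > 0L
    mono <- apply(D, 2, function(v) length(unique(v[!is.na(v)])) < 2L)
    n_mono <- n_mono + sum(mono)
    use_fast <- !has_na & !mono
    cls_blk <- outer(probe_chrom, snp_chrom[idx], "==")
    thr_blk <- ifelse(cls_blk, thresholds$local, thresholds$distal)
    if (any(use_fast)) {
      Gr <- qr.resid(qx, D[, use_fast, drop = FALSE])
      st <- scan_pairs_complete(Yr, Gr, df)
      n_tested <- n_tested + length(st$p)
      keep <- if (emit == "all") st$p <= 1 else
        st$p < thr_blk[, use_fast, drop = FALSE]
      if (any(keep)) {
        w <- which(keep, arr.ind = TRUE)
        sj <- idx[use_fast][w[, 2]]
        recs[[length(recs) + 1L]] <- data.frame(
          probe_id = probes$probe_id[w[, 1]],
          snp_id = g$map$snp_id[sj],
          class = ifelse(probe_chrom[w[, 1]] == snp_chrom[sj],
                         "local", "distal"),
          beta = st$beta[keep], t = st$t[keep], p = st$p[keep],
          partial_r2 = st$r2[keep], n_used = n,
          stringsAsFactors = FALSE)
      }
    }
    for (j in which(has_na & !mono)) {    # slow path: per-SNP refit
      gj <- D[, j]
      ok <- !is.na(gj)
      qs <- qr(X[ok, , drop = FALSE])
      dfj <- sum(ok) - qs$rank - 1L
      if (dfj < 1L) next
      Yrj <- qr.resid(qs, Y[ok, , drop = FALSE])
      Grj <- qr.resid(qs, matrix(gj[ok], ncol = 1))
      st <- scan_pairs_complete(Yrj, Grj, dfj)
      n_tested <- n_tested + length(st$p)
      thr_j <- thr_blk[, match(j, seq_along(idx))]
      keep <- if (emit == "all") rep(TRUE, length(st$p)) else
        as.vector(st$p) < thr_j
      if (any(keep)) {
        recs[[length(recs) + 1L]] <- data.frame(
          probe_id = probes$probe_id[keep],
          snp_id = g$map$snp_id[idx[j]],
          class = ifelse(probe_chrom[keep] == snp_chrom[idx[j]],
                         "local", "distal"),
          beta = st$beta[keep], t = st$t[keep], p = st$p[keep],
          partial_r2 = st$r2[keep], n_used = sum(ok),
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(probe_id = character(0), snp_id = character(0),
               class = character(0), beta = numeric(0), t = numeric(0),
               p = numeric(0), partial_r2 = numeric(0),
               n_used = integer(0), stringsAsFactors = FALSE)
  thr_of <- ifelse(records$class == "local", thresholds$local,
                   thresholds$distal)
  records$significant <- records$p < thr_of
  summary <- list(
    n_probes = nrow(probes), n_snps = m, n_tested = n_tested,
    n_monomorphic_skipped = n_mono,
    n_probes_excluded = n_probes_excluded,
    n_significant = sum(records$significant),
    n_local_significant = sum(records$significant &
                                records$class == "local"),
    n_distal_significant = sum(records$significant &
                                 records$class == "distal"))
  structure(list(records = records, summary = summary,
                 thresholds = thresholds), class = "esnp_scan")
}

#' Select peak associations
#'
#' Per probe and per class (local/distal), the minimum-p significant
#' record; ties broken by larger `|beta|`, then lexicographically smaller
#' `snp_id`.
#'
#' @param records data frame of significant `esnp_scan` records (or an
#'   `esnp_scan` object).
#' @return data frame of peak records, one row per probe x class.
#' @export
select_peak_associations <- function(records) {
  if (inherits(records, "esnp_scan")) {
    records <- records$records[records$records$significant, , drop = FALSE]
  }
  if (nrow(records) == 0L) return(records)
  ord <- order(records$probe_id, records$class, records$p,
               -abs(records$beta), records$snp_id)
  records <- records[ord, , drop = FALSE]
  keep <- !duplicated(records[, c("probe_id", "class")])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare the clinical-status effect before and after eSNP conditioning
#'
#' For every probe with a peak eSNP, fits the status ANCOVA with and
#' without its peak SNP as a covariate and reports both clinical-status
#' p-values, their negative log10 values, the rank correlation of the two
#' series across probes, counts significant at a Bonferroni level in
#' either model, and whether the direction of the (adjusted) patient vs
#' control effect is consistent between the two fits.
#'
#' @param e,g,meta aligned inputs.
#' @param peaks peak table from [select_peak_associations()].
#' @param covariate_terms model covariates besides the SNP.
#' @param sig_threshold p-value threshold for the significance counts
#'   (default Bonferroni over the probes conditioned).
#' @return list of class `esnp_conditioning`: `table` (probe_id, snp_id,
#'   p_status_nosnp, p_status_snp, nlp_nosnp, nlp_snp, dir_consistent),
#'   `rank_correlation`, `n_significant_nosnp`, `n_significant_snp`,
#'   `prop_direction_consistent`.
#' @export
condition_on_esnp <- function(e, g, meta, peaks,
                              covariate_terms = c("clin_status", "sex",
                                                  "wbc", "rbc"),
                              sig_threshold = NULL) {
  stopifnot(identical(e$sample_ids, g$sample_ids),
            identical(e$sample_ids, meta$sample_id))
  peaks <- peaks[peaks$probe_id %in% rownames(e$values) &
                   peaks$snp_id %in% g$map$snp_id, , drop = FALSE]
  if (nrow(peaks) == 0L) stopf("no conditioning peaks available")
  if (is.null(sig_threshold)) sig_threshold <- 0.05 / nrow(peaks)
  dz <- model_covariates(meta, covariate_terms)
  X <- dz$X
  status_cols <- grepl("^clin_status", colnames(X))
  rows <- lapply(seq_len(nrow(peaks)), function(k) {
    y <- e$values[peaks$probe_id[k], ]
    gk <- g$dosage[, peaks$snp_id[k]]
    ok <- !is.na(gk)
    status_p <- function(Xf) {
      qf <- qr(Xf)
      rssf <- sum(qr.resid(qf, y[ok])^2)
      Xr <- Xf[, !grepl("^clin_status", colnames(Xf)), drop = FALSE]
      qr_ <- qr(Xr)
      rssr <- sum(qr.resid(qr_, y[ok])^2)
      df1 <- qf$rank - qr_$rank
      df2 <- sum(ok) - qf$rank
      fstat <- max(0, ((rssr - rssf) / df1) / (rssf / df2))
      p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
      bet <- qr.coef(qf, y[ok])
      list(p = p, status_coefs = bet[status_cols[seq_along(bet)] &
                                       !is.na(bet)])
    }
    f0 <- status_p(X[ok, , drop = FALSE])
    f1 <- status_p(cbind(X[ok, , drop = FALSE], SNP = gk[ok]))
    cs0 <- qr.coef(qr(X[ok, , drop = FALSE]), y[ok])[status_cols]
    Xs <- cbind(X[ok, , drop = FALSE], SNP = gk[ok])
    cs1 <- qr.coef(qr(Xs), y[ok])[status_cols]
    data.frame(probe_id = peaks$probe_id[k], snp_id = peaks$snp_id[k],
               p_status_nosnp = f0$p, p_status_snp = f1$p,
               nlp_nosnp = -log10(f0$p), nlp_snp = -log10(f1$p),
               dir_consistent = all(sign(cs0) == sign(cs1), na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(
    table = tab,
    rank_correlation = suppressWarnings(
      stats::cor(tab$nlp_nosnp, tab$nlp_snp, method = "spearman")),
    n_significant_nosnp = sum(tab$p_status_nosnp < sig_threshold),
    n_significant_snp = sum(tab$p_status_snp < sig_threshold),
    prop_direction_consistent = mean(tab$dir_consistent),
    sig_threshold = sig_threshold), class = "esnp_conditioning")
}
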