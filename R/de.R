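#' ANCOVA model terms
#'
#' Default term set for probe-level differential expression:
#' `expression = mu + Hb genotype + ClinStatus + Sex + WBC + RBC + error`,
#' with a normal mean-zero residual.  Factors use sum-to-zero contrasts so
#' marginal (Type III) tests are well defined in unbalanced designs.
#' @name ancova
NULL

de_default_terms <- c("hb_genotype", "clin_status", "sex", "wbc", "rbc")

de_factor_terms <- c("hb_genotype", "clin_status", "sex", "phase")

## Build the common design matrix for a term list.  Returns the matrix,
## the term of each column, and the rows (samples) kept (complete
## covariates only, dropped globally so every probe shares one design).
build_design <- function(meta, terms, contrasts = "contr.sum") {
  keep <- stats::complete.cases(meta[, terms, drop = FALSE])
  dat <- meta[keep, terms, drop = FALSE]
  for (tm in intersect(terms, de_factor_terms)) {
    dat[[tm]] <- factor(dat[[tm]])
  }
  ctr <- lapply(dat[intersect(terms, names(dat)[vapply(dat, is.factor,
                                                       logical(1))])],
                function(f) contrasts)
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  mf <- stats::model.frame(fml, dat)
  X <- stats::model.matrix(fml, mf,
                           contrasts.arg = if (length(ctr)) ctr else NULL)
  col_term <- attr(X, "assign")           # 0 = intercept
  term_labels <- c("(Intercept)", attr(stats::terms(fml), "term.labels"))
  list(X = X, col_term = col_term, term_labels = term_labels,
       keep = keep, data = dat)
}

#' Probe-by-probe analysis of covariance
#'
#' Ordinary least squares per probe with per-term F tests, vectorized over
#' probes through a single shared design matrix.  Type III (marginal)
#' tests drop one term's columns at a time from the sum-contrast design;
#' Type I (sequential) adds terms in the listed order.  Samples with any
#' missing covariate are dropped globally so all probes share identical
#' degrees of freedom.  Constant-response probes report F = 0, p = 1 by
#' convention.  Terms whose design columns are aliased (e.g. a factor
#' confounded with another) are flagged non-estimable (`NA` statistics).
#'
#' @param e an `expression_matrix`.
#' @param meta aligned metadata data frame.
#' @param terms model terms (metadata column names); default Hb genotype,
#'   clinical status, sex, WBC, RBC.
#' @param type 3 (marginal, default) or 1 (sequential).
#' @param fdr_q per-term FDR level for the significance flag.
#' @return list of class `de_result`: `table` (probe_id, term, F, df1,
#'   df2, p, q, significant), `n_used`, `terms`, `design` internals.
#' @export
fit_ancova <- function(e, meta, terms = de_default_terms, type = 3,
                       fdr_q = 0.01) {
  stopifnot(identical(e$sample_ids, meta$sample_id))
  dz <- build_design(meta, terms)
  X <- dz$X
  Y <- t(e$values[, dz$keep, drop = FALSE])
  n <- nrow(Y)
  qx <- qr(X)
  rss_full <- colSums(qr.resid(qx, Y)^2)
  df_res <- n - qx$rank
  const_probe <- apply(Y, 2, function(y) var(y) == 0)
  term_ids <- setdiff(unique(dz$col_term), 0L)
  rows <- list()
  aliased <- character(0)
  for (tm in term_ids) {
    label <- dz$term_labels[tm + 1L]
    if (type == 3) {
      Xr <- X[, dz$col_term != tm, drop = FALSE]
    } else {
      Xr <- X[, dz$col_term < tm, drop = FALSE]
    }
    red <- rss_columns(Y, Xr)
    # with a partially aliased design (e.g. Hb genotype vs status in an
    # all-HbSS patient cohort) the marginal test keeps only the rank the
    # term actually adds; a term adding no rank is non-estimable
    df1 <- qx$rank - red$rank
    if (df1 == 0L) {
      aliased <- c(aliased, label)
      rows[[label]] <- data.frame(probe_id = colnames(Y), term = label,
                                  F = NA_real_, df1 = 0L,
                                  df2 = df_res, p = NA_real_,
                                  stringsAsFactors = FALSE)
      next
    }
    fstat <- ((red$rss - rss_full) / df1) / (rss_full / df_res)
    fstat[const_probe] <- 0
    fstat <- pmax(fstat, 0)
    p <- stats::pf(fstat, df1, df_res, lower.tail = FALSE)
    p[const_probe] <- 1
    rows[[label]] <- data.frame(probe_id = colnames(Y), term = label,
                                F = fstat, df1 = df1, df2 = df_res, p = p,
                                stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # FDR applied separately within each model term
  tab$q <- NA_real_
  tab$significant <- NA
  for (label in unique(tab$term)) {
    idx <- tab$term == label
    if (all(is.na(tab$p[idx]))) next
    fdr <- bh_fdr(tab$p[idx], fdr_q)
    tab$q[idx] <- fdr$q
    tab$significant[idx] <- fdr$significant
  }
  structure(list(table = tab, n_used = n, terms = terms,
                 df_residual = df_res, fdr_q = fdr_q,
                 aliased_terms = aliased),
            class = "de_result")
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up q-values and significance flags at FDR level `q`.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (`NA` allowed).
#' @param q FDR level.
#' @return list: `q` (adjusted p-values), `significant` (logical flags).
#' @export
bh_fdr <- function(pvalues, q = 0.01) {
  if (length(pvalues) == 0L) {
    return(list(q = numeric(0), significant = logical(0)))
  }
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  qv <- stats::p.adjust(pvalues, method = "BH")
  list(q = qv, significant = !is.na(qv) & qv <= q)
}

#' Pairwise clinical-status contrasts
#'
#' Linear contrasts between status-group means (E - FU, E - Ctl,
#' FU - Ctl) from the full ANCOVA fit, with per-contrast t tests and BH
#' FDR.  Absent levels cause the affected contrasts to be skipped with a
#' warning.
#'
#' @param e an `expression_matrix`.
#' @param meta aligned metadata.
#' @param factor_term the factor whose levels are contrasted.
#' @param terms model term list.  The default omits Hb genotype: in a
#'   cohort whose patients are all HbSS the Hb factor is aliased with
#'   clinical status and group contrasts would be non-estimable.
#' @param fdr_q per-contrast FDR level.
#' @return data frame: probe_id, contrast, estimate, se, t, p, q,
#'   significant.
#' @export
pairwise_contrasts <- function(e, meta, factor_term = "clin_status",
                               terms = c("clin_status", "sex",
                                         "wbc", "rbc"), fdr_q = 0.01) {
  stopifnot(identical(e$sample_ids, meta$sample_id))
  dz <- build_design(meta, terms, contrasts = "contr.treatment")
  X <- dz$X
  Y <- t(e$values[, dz$keep, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) stopf("aliased design; contrasts not estimable")
  B <- qr.coef(qx, Y)                     # p x probes
  rss <- colSums(qr.resid(qx, Y)^2)
  df_res <- nrow(Y) - qx$rank
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(qr.R(qx))
  lv <- levels(factor(dz$data[[factor_term]]))
  if (length(lv) < 2L) stopf("factor '%s' has < 2 observed levels",
                             factor_term)
  coef_of <- function(level) {
    # treatment coding: reference level has a zero coefficient vector
    v <- numeric(ncol(X))
    nm <- paste0(factor_term, level)
    j <- match(nm, colnames(X))
    if (!is.na(j)) v[j] <- 1
    v
  }
  pairs <- utils::combn(lv, 2)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    l1 <- pairs[1, k]; l2 <- pairs[2, k]
    L <- coef_of(l1) - coef_of(l2)
    est <- as.vector(crossprod(L, B))
    vL <- as.numeric(t(L) %*% XtXinv %*% L)
    se <- sqrt(vL * sigma2)
    t_stat <- ifelse(se > 0, est / se, 0)
    p <- 2 * stats::pt(-abs(t_stat), df_res)
    fdr <- bh_fdr(p, fdr_q)
    out[[k]] <- data.frame(probe_id = colnames(Y),
                           contrast = paste0(l1, "-", l2),
                           estimate = est, se = se, t = t_stat, p = p,
                           q = fdr$q, significant = fdr$significant,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Venn-style summary of contrast-specific differential expression
#'
#' Counts probes significant in exactly each combination of contrasts
#' (e.g. probes differentially expressed uniquely between E and FU).
#'
#' @param flags logical matrix, probes x contrasts (column names label
#'   the contrasts), or the output of [pairwise_contrasts()].
#' @return data frame: `subset` (contrast combination, "+"-joined),
#'   `count`; plus attribute `total_significant`.
#' @export
unique_de_sets <- function(flags) {
  if (is.data.frame(flags) && all(c("probe_id", "contrast") %in%
                                  names(flags))) {
    wide <- tapply(flags$significant,
                   list(flags$probe_id, flags$contrast), isTRUE)
    flags <- wide
  }
  flags <- as.matrix(flags)
  mode(flags) <- "logical"
  flags[is.na(flags)] <- FALSE
  cn <- colnames(flags) %||% paste0("contrast", seq_len(ncol(flags)))
  key <- apply(flags, 1, function(r) paste(cn[r], collapse = "+"))
  key <- key[key != ""]
  combos <- unlist(lapply(seq_along(cn), function(k) {
    apply(utils::combn(cn, k), 2, paste, collapse = "+")
  }))
  counts <- vapply(combos, function(cb) sum(key == cb), integer(1))
  out <- data.frame(subset = combos, count = counts,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "total_significant") <- length(key)
  out
}
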