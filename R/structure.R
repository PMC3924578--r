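#' Principal component analysis of samples
#'
#' PCA of the sample covariance of centered (optionally scaled) data with
#' a deterministic sign convention: each component's largest-magnitude
#' loading is positive.
#'
#' @param x samples x features numeric matrix.
#' @param n_components number of components to return (capped at the
#'   matrix rank).
#' @param center,scale passed to the underlying decomposition.
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `loadings` (features x components), `variance_explained` (fraction of
#'   total variance per component).
#' @export
pca_samples <- function(x, n_components = 3L, center = TRUE, scale = FALSE) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  if (!all(is.finite(x))) stopf("PCA input must be finite")
  if (scale) {
    sds <- apply(x, 2, sd)
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = center, scale. = scale)
  total_var <- sum(pc$sdev^2)
  k <- min(n_components, sum(pc$sdev > max(pc$sdev) * 1e-8))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {           # sign convention: top loading positive
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = pc$sdev[seq_len(k)]^2 / total_var),
            class = "pca_result")
}

#' Expression PCA (samples in rows)
#'
#' @param e an `expression_matrix`.
#' @param n_components number of expression PCs (ePCs).
#' @param ... passed to [pca_samples()].
#' @return a `pca_result`; scores rows are samples.
#' @export
expression_pca <- function(e, n_components = 3L, ...) {
  pca_samples(t(e$values), n_components = n_components, ...)
}

#' Genotype PCA with Eigenstrat normalization
#'
#' Each SNP column is centered by twice its allele frequency and scaled by
#' the binomial standard deviation `sqrt(p(1-p))`; missing dosages are
#' mean-imputed for the decomposition only.  Monomorphic SNPs are dropped.
#'
#' @param g a `genotype_matrix`.
#' @param n_components number of genotype PCs (gPCs).
#' @return a `pca_result`.
#' @export
genotype_pca <- function(g, n_components = 10L) {
  d <- g$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(d, 2, 2 * p)
  z[is.na(z)] <- 0                   # mean imputation after centering
  z <- sweep(z, 2, sqrt(p * (1 - p)), "/")
  pca_samples(z, n_components = n_components, center = TRUE, scale = FALSE)
}

#' Variance-component analysis of expression PC scores
#'
#' Fits each factor (and optionally all pairwise factor combinations) as a
#' random intercept in a REML variance-components model per score column,
#' and reports the proportion of variance attributed to each component
#' (negative REML estimates are truncated at zero by the fitter).  A
#' pooled summary weights the per-PC proportions by each PC's share of
#' total variance.
#'
#' @param scores samples x PCs numeric matrix (e.g. `pca_result$scores`).
#' @param factors data frame of factors aligned with the score rows.
#' @param include_interactions add all pairwise factor-combination
#'   components.
#' @param weights per-PC weights for pooling; defaults to the PC variances
#'   of `scores`.
#' @return data frame of class `vca_table`: one row per component
#'   (factors, interactions, residual), one column per PC plus `pooled`;
#'   entries are variance proportions in [0, 1], `NA` for
#'   non-identifiable components (a factor with fewer than two observed
#'   levels).
#' @export
variance_components <- function(scores, factors,
                                include_interactions = TRUE,
                                weights = NULL) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == nrow(factors))
  if (is.null(weights)) weights <- apply(scores, 2, var)
  weights <- weights / sum(weights)
  terms <- as.list(factors)
  terms <- lapply(terms, function(f) factor(as.character(f)))
  names(terms) <- names(factors)
  if (include_interactions && ncol(factors) >= 2L) {
    cmb <- utils::combn(names(factors), 2)
    for (k in seq_len(ncol(cmb))) {
      nm <- paste(cmb[, k], collapse = ":")
      terms[[nm]] <- interaction(terms[[cmb[1, k]]], terms[[cmb[2, k]]],
                                 drop = TRUE)
    }
  }
  identifiable <- vapply(terms, function(f) nlevels(droplevels(f)) >= 2L,
                         logical(1))
  # a factor aliased with another (identical groupings) is non-identifiable
  for (i in seq_along(terms)) {
    for (j in seq_along(terms)) {
      if (i < j && identifiable[i] && identifiable[j] &&
          nlevels(droplevels(terms[[i]])) ==
            nlevels(droplevels(terms[[j]])) &&
          all(tapply(as.integer(terms[[j]]), terms[[i]],
                     function(v) length(unique(v))) == 1L)) {
        identifiable[j] <- FALSE
      }
    }
  }
  used <- names(terms)[identifiable]
  out <- matrix(NA_real_, length(terms) + 1L, ncol(scores),
                dimnames = list(c(names(terms), "residual"),
                                colnames(scores) %||%
                                  paste0("PC", seq_len(ncol(scores)))))
  for (k in seq_len(ncol(scores))) {
    y <- scores[, k]
    if (length(used) == 0L) {
      out["residual", k] <- 1
      next
    }
    dat <- data.frame(y = y, terms[used], check.names = FALSE)
    rhs <- paste(sprintf("(1 | `%s`)", used), collapse = " + ")
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(paste("y ~", rhs)), data = dat,
                 REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    comp <- stats::setNames(vc$vcov, vc$grp)
    total <- sum(comp)
    for (nm in used) out[nm, k] <- comp[[nm]] / total
    out["residual", k] <- comp[["Residual"]] / total
  }
  pooled <- as.vector(out %*% weights)
  res <- data.frame(component = rownames(out), out, pooled = pooled,
                    check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("vca_table", "data.frame")
  res
}

#' Leaf order of hierarchical clustering of a correlation matrix
#'
#' Clusters on distance `1 - correlation` with the requested linkage and
#' returns the deterministic dendrogram leaf order (ties resolved by
#' original index order, the behavior of \code{\link[stats]{hclust}}).
#'
#' @param corr square symmetric correlation matrix.
#' @param linkage linkage method, default "average".
#' @return list: `order` (integer leaf order), `labels`, `hclust` (the
#'   full tree).
#' @export
hierarchical_cluster_order <- function(corr, linkage = "average") {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr) ||
      !isSymmetric(unname(corr), tol = 1e-8)) {
    stopf("input must be a square symmetric matrix")
  }
  hc <- stats::hclust(stats::as.dist(1 - corr), method = linkage)
  list(order = hc$order, labels = colnames(corr)[hc$order], hclust = hc)
}

#' Weir-Cockerham Fst
#'
#' Per-SNP Weir-Cockerham (1984) variance-component estimator of
#' differentiation among groups, and ratio-of-sums estimates over SNP sets
#' (e.g. the SNPs of one gene).  Monomorphic SNPs have an undefined
#' per-SNP value and are excluded from the sums.
#'
#' @param g a `genotype_matrix`.
#' @param groups character/factor vector of group labels, one per sample;
#'   every group must contain at least 2 samples.
#' @param snp_sets optional named list of SNP-id vectors defining gene-wise
#'   sets; the full SNP panel is always reported as set "all".
#' @return list: `per_snp` (snp_id, fst, fst_clipped, a, b, c),
#'   `per_set` (set, n_snps, fst, fst_clipped).
#' @export
fst_weir_cockerham <- function(g, groups, snp_sets = NULL) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stopf("need >= 2 groups each with >= 2 samples")
  }
  r <- length(tab)
  gl <- names(tab)
  d <- g$dosage
  m <- ncol(d)
  n_i <- matrix(0, r, m)     # per-group non-missing sample counts
  p_i <- matrix(0, r, m)     # per-group allele frequencies
  h_i <- matrix(0, r, m)     # per-group observed heterozygosity
  for (k in seq_len(r)) {
    sub <- d[groups == gl[k], , drop = FALSE]
    n_i[k, ] <- colSums(!is.na(sub))
    p_i[k, ] <- colSums(sub, na.rm = TRUE) / (2 * n_i[k, ])
    h_i[k, ] <- colSums(sub == 1L, na.rm = TRUE) / n_i[k, ]
  }
  nbar <- colMeans(n_i)
  nsum <- colSums(n_i)
  nc <- (nsum - colSums(n_i^2) / nsum) / (r - 1)
  pbar <- colSums(n_i * p_i) / nsum
  s2 <- colSums(n_i * sweep(p_i, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- ifelse(abs(denom) < .Machine$double.eps | pbar %in% c(0, 1),
                NA_real_, a / denom)
  per_snp <- data.frame(snp_id = g$map$snp_id, fst = fst,
                        fst_clipped = pmin(pmax(fst, 0), 1),
                        a = a, b = b, c = cc, stringsAsFactors = FALSE)
  sets <- c(list(all = g$map$snp_id), snp_sets %||% list())
  per_set <- do.call(rbind, lapply(names(sets), function(nm) {
    idx <- match(sets[[nm]], g$map$snp_id)
    idx <- idx[!is.na(idx) & !is.na(fst[idx])]
    val <- if (length(idx)) sum(a[idx]) / sum(denom[idx]) else NA_real_
    data.frame(set = nm, n_snps = length(idx), fst = val,
               fst_clipped = min(max(val, 0), 1),
               stringsAsFactors = FALSE)
  }))
  list(per_snp = per_snp, per_set = per_set)
}
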