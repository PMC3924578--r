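#' Minor allele frequency from dosages
#'
#' Frequency of the less common allele among non-missing calls.
#'
#' @param dosage numeric vector (or samples x SNPs matrix) of minor-allele
#'   counts 0/1/2 with `NA` for missing.
#' @return frequency in [0, 0.5] (per SNP for a matrix); `NA` when all
#'   calls are missing.
#' @export
minor_allele_frequency <- function(dosage) {
  if (is.matrix(dosage)) {
    n_ok <- colSums(!is.na(dosage))
    f <- colSums(dosage, na.rm = TRUE) / (2 * n_ok)
    f[n_ok == 0L] <- NA_real_
    return(pmin(f, 1 - f))
  }
  n_ok <- sum(!is.na(dosage))
  if (n_ok == 0L) return(NA_real_)
  f <- sum(dosage, na.rm = TRUE) / (2 * n_ok)
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium p-value
#'
#' Two-sided exact test: the probability, under the conditional
#' distribution of heterozygote counts given the allele counts, of any
#' table as or less probable than the observed one.  Computed by the
#' standard stable recurrence over heterozygote counts.  Monomorphic
#' tables give p = 1.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_hom_major, n_het, n_hom_minor) {
  if (length(n_hom_major) > 1L) {
    return(mapply(hwe_exact_pvalue, n_hom_major, n_het, n_hom_minor))
  }
  if (any(c(n_hom_major, n_het, n_hom_minor) < 0)) {
    stopf("genotype counts must be non-negative")
  }
  n <- n_hom_major + n_het + n_hom_minor
  if (n < 1L) stopf("total genotype count must be >= 1")
  rare <- 2L * min(n_hom_major, n_hom_minor) + n_het
  if (rare == 0L) return(1.0)
  # heterozygote support: same parity as the rare-allele count
  h_min <- rare %% 2L
  h_max <- min(rare, 2L * n - rare)
  hs <- seq.int(h_min, h_max, by = 2L)
  probs <- numeric(length(hs))
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  mid <- min(max(mid, h_min), h_max)
  i_mid <- match(mid, hs)
  probs[i_mid] <- 1
  if (i_mid < length(hs)) {          # upward: h -> h + 2
    for (i in seq.int(i_mid, length(hs) - 1L)) {
      h <- hs[i]
      hr <- (rare - h) / 2           # rare homozygotes at h hets
      hc <- n - h - hr
      probs[i + 1L] <- probs[i] * 4 * hr * hc / ((h + 2) * (h + 1))
    }
  }
  if (i_mid > 1L) {                  # downward: h -> h - 2
    for (i in seq.int(i_mid, 2L)) {
      h <- hs[i]
      hr <- (rare - h) / 2
      hc <- n - h - hr
      probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (hr + 1) * (hc + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hs)]
  if (is.na(p_obs)) stopf("inconsistent genotype counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

hwe_from_dosage <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (length(d) == 0L) return(NA_real_)
  hwe_exact_pvalue(sum(d == 0L), sum(d == 1L), sum(d == 2L))
}

#' Filter SNPs on MAF, call rate and Hardy-Weinberg equilibrium
#'
#' Retains SNPs with MAF >= `maf_min`, call rate >= `callrate_min` and
#' exact HWE p >= `hwe_p_min`.  In per-group mode every criterion must
#' pass in every group separately (the convention for the interaction
#' scan, which also tightens the call-rate floor to 0.99).  HWE can be
#' restricted to a subset of samples (e.g. founders, since sibships
#' distort HWE).
#'
#' @param g a `genotype_matrix`.
#' @param cfg an [analysis_config()].
#' @param groups optional factor/character vector (one per sample) for
#'   per-group filtering.
#' @param hwe_samples optional logical or id vector selecting the samples
#'   HWE is computed in.
#' @param verbose log before/after counts.
#' @return list(genotypes = filtered `genotype_matrix`, report = data
#'   frame with per-SNP maf, call_rate, hwe_p, pass, reason).
#' @export
filter_snps <- function(g, cfg = analysis_config(), groups = NULL,
                        hwe_samples = NULL, verbose = TRUE) {
  d <- g$dosage
  n <- nrow(d)
  hwe_rows <- seq_len(n)
  if (!is.null(hwe_samples)) {
    hwe_rows <- if (is.logical(hwe_samples)) which(hwe_samples)
                else match(hwe_samples, g$sample_ids)
  }
  eval_block <- function(rows) {
    sub <- d[rows, , drop = FALSE]
    hwe_sub <- d[intersect(rows, hwe_rows), , drop = FALSE]
    maf <- minor_allele_frequency(sub)
    call_rate <- colMeans(!is.na(sub))
    hwe_p <- apply(hwe_sub, 2, hwe_from_dosage)
    list(maf = maf, call_rate = call_rate, hwe_p = hwe_p)
  }
  if (is.null(groups)) {
    st <- eval_block(seq_len(n))
    maf <- st$maf; call_rate <- st$call_rate; hwe_p <- st$hwe_p
    ok_maf <- !is.na(maf) & maf >= cfg$maf_min
    ok_cr <- call_rate >= cfg$callrate_min
    ok_hwe <- !is.na(hwe_p) & hwe_p >= cfg$hwe_p_min
  } else {
    groups <- as.character(groups)
    per <- lapply(split(seq_len(n), groups), eval_block)
    maf <- do.call(pmin, c(lapply(per, `[[`, "maf"), na.rm = FALSE))
    call_rate <- do.call(pmin, lapply(per, `[[`, "call_rate"))
    hwe_p <- do.call(pmin, c(lapply(per, `[[`, "hwe_p"), na.rm = FALSE))
    ok_maf <- !is.na(maf) & maf >= cfg$maf_min
    ok_cr <- call_rate >= cfg$callrate_min
    ok_hwe <- !is.na(hwe_p) & hwe_p >= cfg$hwe_p_min
  }
  pass <- ok_maf & ok_cr & ok_hwe
  reason <- rep("", ncol(d))
  reason[!ok_maf] <- paste0(reason[!ok_maf], "maf;")
  reason[!ok_cr] <- paste0(reason[!ok_cr], "callrate;")
  reason[!ok_hwe] <- paste0(reason[!ok_hwe], "hwe;")
  report <- data.frame(snp_id = g$map$snp_id, maf = maf,
                       call_rate = call_rate, hwe_p = hwe_p, pass = pass,
                       reason = reason, stringsAsFactors = FALSE)
  log_filter("SNP QC", ncol(d), sum(pass), verbose)
  if (!any(pass)) warning("no SNPs pass QC")
  g$dosage <- d[, pass, drop = FALSE]
  g$map <- g$map[pass, , drop = FALSE]
  rownames(g$map) <- NULL
  list(genotypes = g, report = report)
}

#' Log2 transform and quantile normalize an expression matrix
#'
#' After log2 transformation each sample's value distribution is replaced
#' by the cross-sample mean of order statistics, with ties receiving the
#' mean of the quantile values they span (via
#' \code{limma::normalizeQuantiles(..., ties = TRUE)}).  Optionally
#' winsorizes per-probe values beyond `winsorize_sd` standard deviations
#' before normalization, a simple outlier-damping step.
#'
#' @param e an `expression_matrix` (raw positive intensities unless
#'   `log2_input = FALSE` data are already on log scale).
#' @param log2_input are the values raw intensities to be log2-transformed
#'   (`TRUE`, default) or already log-scale (`FALSE`)?
#' @param winsorize_sd winsorization limit in per-probe SDs, or `NULL` to
#'   skip.
#' @return the normalized `expression_matrix`.
#' @export
log2_quantile_normalize <- function(e, log2_input = TRUE,
                                    winsorize_sd = NULL) {
  v <- e$values
  if (log2_input) {
    bad <- which(v <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stopf("non-positive intensity at probe '%s', sample '%s'",
            rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]])
    }
    v <- log2(v)
  }
  if (!is.null(winsorize_sd)) {
    mu <- rowMeans(v)
    s <- apply(v, 1, sd)
    lo <- mu - winsorize_sd * s
    hi <- mu + winsorize_sd * s
    v <- pmax(pmin(v, hi), lo)
  }
  if (ncol(v) > 1L) {
    dn <- dimnames(v)
    v <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(v) <- dn
  }
  e$values <- v
  e
}

#' Remove probes below background by the knee of the rank-intensity curve
#'
#' Ranks probes by mean normalized intensity (descending), smooths the
#' curve with a running mean, and places the cutoff at the rank minimizing
#' the discrete second difference (the knee where the curve drops to the
#' background plateau).  An explicit `cutoff` overrides the knee search.
#' Probes in `snp_overlap` (e.g. probes whose sequence overlays a
#' genotyped SNP) are removed regardless of intensity.
#'
#' @param e a normalized `expression_matrix`.
#' @param cutoff explicit mean-intensity cutoff, or `NULL` to locate the
#'   knee.
#' @param snp_overlap character vector of probe ids to drop.
#' @param verbose log before/after counts.
#' @return list(expression = filtered matrix, report = per-probe data
#'   frame with mean_intensity, above_background, overlaps_snp, retained;
#'   cutoff = the cutoff used).
#' @export
background_filter <- function(e, cutoff = NULL, snp_overlap = character(0),
                              verbose = TRUE) {
  mu <- rowMeans(e$values)
  if (is.null(cutoff)) {
    ord <- order(mu, decreasing = TRUE)
    y <- mu[ord]
    np <- length(y)
    w <- max(5L, round(np / 50))
    if (w %% 2L == 0L) w <- w + 1L
    ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
    d2 <- c(NA, diff(ys, differences = 2), NA)
    inner <- seq.int(w + 1L, np - w)    # keep the knee off the smoothing edges
    if (length(inner) < 3L || all(is.na(d2[inner]))) {
      stopf("rank-intensity curve too short for knee detection; supply 'cutoff'")
    }
    span <- diff(range(y))
    if (span == 0 || min(d2[inner], na.rm = TRUE) > -1e-8 * span) {
      stopf("no knee in the rank-intensity curve; supply an explicit 'cutoff'")
    }
    knee <- inner[which.min(d2[inner])]
    cutoff <- ys[knee]
  }
  above <- mu >= cutoff
  overlaps <- rownames(e$values) %in% snp_overlap
  retained <- above & !overlaps
  report <- data.frame(probe_id = rownames(e$values), mean_intensity = mu,
                       above_background = above, overlaps_snp = overlaps,
                       retained = retained, stringsAsFactors = FALSE)
  log_filter("background/overlap probe filter", nrow(e$values),
             sum(retained), verbose)
  if (!any(retained)) warning("no probes retained by background filter")
  e$values <- e$values[retained, , drop = FALSE]
  e$probes <- e$probes[retained, , drop = FALSE]
  rownames(e$probes) <- NULL
  list(expression = e, report = report, cutoff = cutoff)
}

#' Average technical replicate arrays
#'
#' Collapses re-hybridized arrays of the same sample to their per-probe
#' arithmetic mean, leaving one column per sample.
#'
#' @param e an `expression_matrix` whose columns are arrays.
#' @param replicate_map data frame with columns `array_id` (column of
#'   `e`) and `sample_id` (the sample it measures).  Arrays not listed are
#'   assumed to be their own sample.
#' @return an `expression_matrix` with one column per sample.
#' @export
average_technical_replicates <- function(e, replicate_map = NULL) {
  if (is.null(replicate_map) || nrow(replicate_map) == 0L) return(e)
  missing_cols <- setdiff(replicate_map$array_id, colnames(e$values))
  if (length(missing_cols)) {
    stopf("replicate map names absent arrays: %s",
          paste(missing_cols, collapse = ", "))
  }
  sample_of <- colnames(e$values)
  idx <- match(colnames(e$values), replicate_map$array_id)
  sample_of[!is.na(idx)] <- replicate_map$sample_id[idx[!is.na(idx)]]
  uniq <- unique(sample_of)
  out <- matrix(0, nrow(e$values), length(uniq),
                dimnames = list(rownames(e$values), uniq))
  for (s in uniq) {
    out[, s] <- rowMeans(e$values[, sample_of == s, drop = FALSE])
  }
  e$values <- out
  e$sample_ids <- uniq
  e
}
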