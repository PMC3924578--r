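#' Construct a genotype matrix object
#'
#' @param dosage samples x SNPs integer matrix of minor-allele counts with
#'   `NA` for missing calls; dimnames give sample and SNP ids.
#' @param map data frame with columns snp_id, chrom, pos and optionally
#'   allele_minor / allele_major.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, map) {
  stopifnot(is.matrix(dosage), nrow(map) == ncol(dosage),
            all(c("snp_id", "chrom", "pos") %in% names(map)))
  if (anyDuplicated(map$snp_id)) stopf("duplicate snp_id in map")
  map$chrom <- norm_chrom(map$chrom)
  if (any(map$pos < 1, na.rm = TRUE)) stopf("positions must be 1-based (>= 1)")
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = map,
                 sample_ids = rownames(dosage)),
            class = "genotype_matrix")
}

#' Construct an expression matrix object
#'
#' @param values probes x samples numeric matrix (log-intensity scale);
#'   dimnames give probe and sample ids.
#' @param probes data frame with columns probe_id and optionally
#'   gene_symbol, chrom, pos.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probes) {
  stopifnot(is.matrix(values), nrow(probes) == nrow(values),
            "probe_id" %in% names(probes))
  if (anyDuplicated(probes$probe_id)) stopf("duplicate probe_id")
  if (!is.null(probes$chrom)) probes$chrom <- norm_chrom(probes$chrom)
  rownames(values) <- probes$probe_id
  structure(list(values = values, probes = probes,
                 sample_ids = colnames(values)),
            class = "expression_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write genotypes to disk
#'
#' Two dialects are supported: PLINK text `.ped`/`.map` (space-delimited,
#' six leading ped columns, alleles A/B, missing coded "0 0") and a TSV
#' matrix (rows = SNPs, columns = samples, values 0/1/2/NA) with a sidecar
#' `<prefix>.snps.tsv` carrying the map.
#'
#' @param g a `genotype_matrix`.
#' @param prefix output path prefix (extensions are appended).
#' @param dialect "pedmap" or "tsv".
#' @param metadata optional metadata data frame supplying family_id and sex
#'   for the ped columns.
#' @return invisibly, the paths written.
#' @export
write_genotypes <- function(g, prefix, dialect = c("pedmap", "tsv"),
                            metadata = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    mat_path <- paste0(prefix, ".geno.tsv")
    map_path <- paste0(prefix, ".snps.tsv")
    df <- data.frame(snp_id = g$map$snp_id,
                     t(g$dosage), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, mat_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(g$map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(c(mat_path, map_path)))
  }
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  utils::write.table(
    data.frame(chrom = g$map$chrom, snp_id = g$map$snp_id, cm = 0,
               pos = g$map$pos),
    map_path, sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(g$dosage)
  fam <- g$sample_ids
  sex_code <- rep(0L, n)
  if (!is.null(metadata)) {
    idx <- match(g$sample_ids, metadata$sample_id)
    fam <- ifelse(is.na(idx), g$sample_ids, metadata$family_id[idx])
    sex_code <- ifelse(is.na(idx), 0L,
                       ifelse(metadata$sex[idx] == "M", 1L, 2L))
  }
  a_min <- g$map$allele_minor %||% rep("B", ncol(g$dosage))
  a_maj <- g$map$allele_major %||% rep("A", ncol(g$dosage))
  lines <- vapply(seq_len(n), function(i) {
    d <- g$dosage[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, a_min, a_maj))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, a_min, a_maj))
    paste(c(fam[i], g$sample_ids[i], 0, 0, sex_code[i], -9,
            as.vector(rbind(a1, a2))), collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}

#' Read genotypes from disk
#'
#' Reads either PLINK text `.ped`/`.map` or the TSV dialect written by
#' [write_genotypes()].  Dosages are oriented to the minor allele computed
#' from the data itself (ties broken toward the alphabetically later
#' allele, so the A/B convention round-trips); missing calls are preserved
#' as `NA`.
#'
#' @param prefix path prefix (without extension).
#' @param dialect "pedmap" or "tsv".
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(prefix, dialect = c("pedmap", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    mat_path <- paste0(prefix, ".geno.tsv")
    map_path <- paste0(prefix, ".snps.tsv")
    if (!file.exists(mat_path)) stopf("file not found: %s", mat_path)
    df <- utils::read.delim(mat_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
    dosage <- t(as.matrix(df[, -1, drop = FALSE]))
    storage.mode(dosage) <- "integer"
    colnames(dosage) <- df$snp_id
    if (!all(dosage %in% c(0L, 1L, 2L) | is.na(dosage))) {
      stopf("format error: TSV dosages must be 0/1/2/NA")
    }
    map$chrom <- as.character(map$chrom)
    return(genotype_matrix(dosage, map))
  }
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  if (length(readLines(map_path, n = 1L)) == 0L) {
    stopf("parse error: empty map file %s", map_path)
  }
  map_raw <- utils::read.table(map_path, stringsAsFactors = FALSE)
  if (ncol(map_raw) < 4L) stopf("parse error: map file needs 4 columns")
  map <- data.frame(snp_id = as.character(map_raw[[2]]),
                    chrom = as.character(map_raw[[1]]),
                    pos = as.integer(map_raw[[4]]),
                    stringsAsFactors = FALSE)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  if (n == 0L) stopf("parse error: empty ped file %s", ped_path)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  ids <- character(n)
  fams <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6L + 2L * m) {
      stopf("parse error: ped line %d has %d fields, expected %d",
            i, length(tok), 6L + 2L * m)
    }
    fams[i] <- tok[1]; ids[i] <- tok[2]
    al <- tok[-(1:6)]
    a1[i, ] <- al[seq(1L, 2L * m, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * m, by = 2L)]
  }
  dosage <- matrix(NA_integer_, n, m, dimnames = list(ids, map$snp_id))
  allele_minor <- character(m)
  allele_major <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    ok <- x1 != "0" & x2 != "0"
    alleles <- sort(unique(c(x1[ok], x2[ok])))
    if (length(alleles) > 2L) {
      stopf("format error: SNP %s has >2 allele codes (%s)",
            map$snp_id[j], paste(alleles, collapse = ","))
    }
    if (length(alleles) == 0L) {      # all missing
      allele_minor[j] <- allele_major[j] <- NA_character_
      next
    }
    if (length(alleles) == 1L) alleles <- c(alleles, alleles)
    cnt <- c(sum(x1[ok] == alleles[1]) + sum(x2[ok] == alleles[1]),
             sum(x1[ok] == alleles[2]) + sum(x2[ok] == alleles[2]))
    # ties go to the later code so a 0.5-MAF A/B SNP keeps B as minor
    minor <- if (cnt[2] <= cnt[1]) alleles[2] else alleles[1]
    major <- setdiff(alleles, minor)[1] %||% minor
    if (is.na(major)) major <- minor
    allele_minor[j] <- minor; allele_major[j] <- major
    dosage[ok, j] <- (x1[ok, drop = TRUE] == minor) + (x2[ok] == minor)
  }
  map$allele_minor <- allele_minor
  map$allele_major <- allele_major
  g <- genotype_matrix(dosage, map)
  g$family_ids <- fams
  g
}

#' Write / read an expression matrix as TSV
#'
#' The value matrix is written with probes in rows and a header row of
#' sample ids; probe annotation goes in a sidecar `<prefix>.probes.tsv`.
#'
#' @param e an `expression_matrix`.
#' @param prefix path prefix.
#' @return invisibly, the paths written.
#' @export
write_expression <- function(e, prefix) {
  val_path <- paste0(prefix, ".expr.tsv")
  ann_path <- paste0(prefix, ".probes.tsv")
  df <- data.frame(probe_id = rownames(e$values), e$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, val_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(e$probes, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(val_path, ann_path))
}

#' @rdname write_expression
#' @param prefix path prefix used by [write_expression()].
#' @export
read_expression <- function(prefix) {
  val_path <- paste0(prefix, ".expr.tsv")
  ann_path <- paste0(prefix, ".probes.tsv")
  if (!file.exists(val_path)) stopf("file not found: %s", val_path)
  df <- utils::read.delim(val_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  probes <- utils::read.delim(ann_path, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$probe_id
  if (!is.null(probes$chrom)) probes$chrom <- as.character(probes$chrom)
  expression_matrix(values, probes)
}

#' Write / read sample metadata as TSV
#'
#' Fixed column set: sample_id, family_id, hb_genotype, clin_status, sex,
#' wbc, rbc, phase.
#'
#' @param meta metadata data frame.
#' @param path output file.
#' @export
write_metadata <- function(meta, path) {
  cols <- c("sample_id", "family_id", "hb_genotype", "clin_status",
            "sex", "wbc", "rbc", "phase")
  missing_cols <- setdiff(cols, names(meta))
  if (length(missing_cols)) {
    stopf("metadata lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  utils::write.table(meta[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(meta)
  meta
}

validate_metadata <- function(meta) {
  if (!all(meta$clin_status %in% c("E", "FU", "A", "Ctl"))) {
    stopf("invalid clin_status values")
  }
  if (!all(meta$hb_genotype %in% c("HbSS", "HbSC", "HbAS", "HbAA"))) {
    stopf("invalid hb_genotype values")
  }
  ctl <- meta$clin_status == "Ctl"
  carrier <- meta$hb_genotype %in% c("HbAS", "HbAA")
  if (any(ctl != carrier)) {
    stopf("metadata violates control definition: HbAS/HbAA iff Ctl")
  }
  if (any(meta$wbc <= 0) || any(meta$rbc <= 0)) {
    stopf("wbc/rbc must be strictly positive")
  }
  invisible(meta)
}

#' Align genotype, expression and metadata to a common sample set
#'
#' Intersects the sample ids of the three inputs, drops samples missing
#' from any of them (logging the count), and reorders all three to a
#' single shared order.
#'
#' @param g a `genotype_matrix`.
#' @param e an `expression_matrix`.
#' @param meta metadata data frame.
#' @param verbose log drop counts.
#' @return list(genotypes, expression, metadata) with identical sample
#'   order.
#' @export
align_cohort <- function(g, e, meta, verbose = TRUE) {
  common <- intersect(intersect(g$sample_ids, e$sample_ids),
                      meta$sample_id)
  if (length(common) == 0L) {
    stopf("alignment error: no samples shared by all three inputs")
  }
  log_filter("align genotypes", length(g$sample_ids), length(common),
             verbose)
  log_filter("align expression", length(e$sample_ids), length(common),
             verbose)
  log_filter("align metadata", nrow(meta), length(common), verbose)
  g$dosage <- g$dosage[common, , drop = FALSE]
  g$sample_ids <- common
  e$values <- e$values[, common, drop = FALSE]
  e$sample_ids <- common
  meta <- meta[match(common, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(genotypes = g, expression = e, metadata = meta)
}

#' Select a cohort subset by analysis rule
#'
#' `combined_II` keeps HbSS patients in steady state (status E or FU,
#' excluding acute events) plus all controls; `combined_I` keeps all
#' samples; `discovery` / `replication` filter on the phase column.
#'
#' @param meta metadata data frame.
#' @param rule one of "discovery", "replication", "combined_I",
#'   "combined_II".
#' @return character vector of sample ids.
#' @export
subset_dataset <- function(meta, rule = c("combined_II", "combined_I",
                                          "discovery", "replication")) {
  rule <- match.arg(rule)
  keep <- switch(rule,
    combined_I = rep(TRUE, nrow(meta)),
    combined_II = (meta$hb_genotype == "HbSS" &
                     meta$clin_status %in% c("E", "FU")) |
                  meta$clin_status == "Ctl",
    discovery = meta$phase == "discovery",
    replication = meta$phase == "replication")
  if (rule == "combined_II" &&
      !any(keep & meta$clin_status != "Ctl")) {
    warning("combined_II subset contains no HbSS patients")
  }
  meta$sample_id[keep]
}

#' Write a simulated cohort to a directory
#'
#' Emits both genotype dialects, the expression TSV pair, the metadata TSV
#' and a JSON ground-truth sidecar.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "cohort"),
                  dialect = "pedmap", metadata = sim$metadata)
  write_genotypes(sim$genotypes, file.path(dir, "cohort"), dialect = "tsv")
  write_expression(sim$expression, file.path(dir, "cohort"))
  write_metadata(sim$metadata, file.path(dir, "cohort.meta.tsv"))
  truth <- sim$truth
  truth$kinship_true <- NULL            # large; reconstructable from family ids
  jsonlite::write_json(truth, file.path(dir, "cohort.truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
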