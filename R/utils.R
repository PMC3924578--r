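#' @keywords internal
"_PACKAGE"

#' Normalize a chromosome label
#'
#' Strips a leading "chr" prefix and returns the bare label as a character
#' string, so that "chr1" and "1" compare equal.
#'
#' @param x character or integer vector of chromosome labels.
#' @return character vector of normalized labels; `NA` stays `NA`.
#' @export
norm_chrom <- function(x) {
  out <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  out[!nzchar(out)] <- NA_character_
  out
}

## Filter-style logging: every data-reducing step reports before/after counts.
log_filter <- function(what, before, after, verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("%s: %d -> %d (%d removed)", what, before, after,
                    before - after))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

## QR-based residualization: returns Y minus its projection onto col(X).
## Y is n x m (samples in rows); X is an n x p design of full column rank
## (rank-deficiency handled by qr pivoting).
residualize <- function(Y, X) {
  qx <- qr(X)
  Y - qr.fitted(qx, Y)
}

## Column-wise residual sums of squares of Y regressed on X, plus the rank
## used.  Y is n x m; returns list(rss = length-m vector, rank).
rss_columns <- function(Y, X) {
  qx <- qr(X)
  res <- qr.resid(qx, Y)
  list(rss = colSums(res^2), rank = qx$rank)
}
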