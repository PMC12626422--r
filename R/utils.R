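# Shared numerical conventions: correlation clipping and the Fisher
# r-to-z transform used by every correlation-based summary in the package.

#' Clip correlations away from +/-1
#'
#' Correlations are clipped to `|r| <= 1 - eps` before the Fisher transform so
#' that `atanh` stays finite even for degenerate (self- or perfectly
#' correlated) pairs.
#'
#' @param r numeric vector or matrix of correlation coefficients.
#' @param eps clipping margin; default `1e-7`.
#' @return `r` with every entry forced into `[-(1 - eps), 1 - eps]`.
#' @export
clip_r <- function(r, eps = 1e-7) {
  pmin(pmax(r, -(1 - eps)), 1 - eps)
}

#' Fisher r-to-z transform with clipping
#'
#' @param r correlations (vector or matrix).
#' @param eps clipping margin passed to [clip_r()].
#' @return `atanh(clip_r(r))`, same shape as `r`.
#' @export
fisher_z <- function(r, eps = 1e-7) {
  atanh(clip_r(r, eps))
}

# stopifnot-style check with a formatted message
.check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

# Write a data.frame as TSV with full double precision so that
# write -> read round-trips are exact.
.write_tsv <- function(df, path) {
  fmt_col <- function(x) {
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  }
  out <- vapply(df, fmt_col, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(df)))
  lines <- c(
    paste(names(df), collapse = "\t"),
    apply(out, 1L, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
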