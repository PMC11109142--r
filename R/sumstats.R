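#' GWAS summary statistics I/O
#'
#' Summary statistics travel as a tab-separated table with a header row and
#' columns `vid`, `chrom`, `pos`, `a1`, `a2`, `beta`, `se`, `p`, `freq`, `n`.
#' `beta` is the estimated per-allele effect of the counted allele `a1`,
#' `freq` its allele frequency in the association sample, `n` the number of
#' non-missing genotypes used. Numeric fields round-trip at full double
#' precision.
#'
#' @param path file path.
#' @return `read_sumstats` returns a data.frame of class `sumstats`.
#' @name sumstats_io
NULL

sumstats_cols <- c("vid", "chrom", "pos", "a1", "a2", "beta", "se", "p",
                   "freq", "n")

# Validate a summary-statistics table (internal).
validate_sumstats <- function(s) {
  missing_cols <- setdiff(sumstats_cols, names(s))
  if (length(missing_cols)) {
    stop("summary statistics lack column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(s$vid)) {
    stop("duplicated variant id in summary statistics: ",
         s$vid[anyDuplicated(s$vid)])
  }
  if (any(is.na(s$p)) || any(s$p <= 0) || any(s$p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (any(!is.na(s$freq) & (s$freq < 0 | s$freq > 1))) {
    stop("allele frequencies must lie in [0, 1]")
  }
  class(s) <- c("sumstats", "data.frame")
  s
}

#' @rdname sumstats_io
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop("missing summary-statistics file: ", path)
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  for (col in c("pos", "n")) if (col %in% names(s)) s[[col]] <- as.integer(s[[col]])
  for (col in c("beta", "se", "p", "freq")) {
    if (col %in% names(s)) s[[col]] <- as.numeric(s[[col]])
  }
  validate_sumstats(s)
}

#' @rdname sumstats_io
#' @param s a summary-statistics table as returned by [assoc_quantitative()],
#'   [assoc_binary()] or [read_sumstats()].
#' @export
write_sumstats <- function(s, path) {
  s <- validate_sumstats(as.data.frame(s))
  out <- s[, sumstats_cols]
  for (col in c("beta", "se", "p", "freq")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
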