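#' Per-variant missing call rate and allele frequency
#'
#' @param g a [genotype_matrix()].
#' @param vid variant id.
#' @return `missing_rate`: fraction of samples with a missing call.
#'   `allele_freq`: frequency of the counted allele (`a1`) over non-missing
#'   alleles, in `[0, 1]`; `NaN` when every call is missing.
#' @export
missing_rate <- function(g, vid) {
  x <- g$genotypes[, vid]
  mean(is.na(x))
}

#' @rdname missing_rate
#' @export
allele_freq <- function(g, vid) {
  x <- g$genotypes[, vid]
  mean(x, na.rm = TRUE) / 2
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: with the two allele counts fixed, the number of
#' heterozygotes `h` ranges over one parity class; the p-value is the sum of
#' the exact sampling probabilities of every outcome no more probable than
#' the observed one (two-sided by probability ordering, no mid-p
#' correction). Probabilities follow the exact HWE sampling distribution
#' P(h) proportional to n! / (n_AA! n_Aa! n_aa!) * 2^h.
#'
#' @param n_hom1,n_het,n_hom2 non-negative genotype counts (homozygous for
#'   one allele, heterozygous, homozygous for the other); total >= 1.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required")
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  hs <- seq(rare %% 2, rare, by = 2)
  if (length(hs) == 1L) return(1)

  # unnormalised log-probabilities via the recurrence
  # P(h+2)/P(h) = 4 * hom_rare(h) * hom_common(h) / ((h+2) * (h+1))
  logp <- numeric(length(hs))
  for (i in seq_along(hs)[-1]) {
    h <- hs[i - 1]
    hom_rare <- (rare - h) / 2
    hom_common <- (2 * n - rare - h) / 2
    logp[i] <- logp[i - 1] +
      log(4 * hom_rare * hom_common) - log((h + 2) * (h + 1))
  }
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hs)]
  min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
}

#' Variant-level quality-control filters
#'
#' Each filter returns the genotype matrix restricted to surviving variants:
#' \itemize{
#'   \item `filter_missing`: drops variants whose missing call rate is
#'     strictly above `max_rate`.
#'   \item `filter_maf`: drops variants with minor allele frequency strictly
#'     below `min_maf` (computed over non-missing alleles).
#'   \item `filter_hwe`: drops variants whose [hwe_exact_p()] is strictly
#'     below `min_p`; by default counts are pooled over all samples, set
#'     `controls_only = TRUE` to restrict to controls of a binary trait.
#'   \item `remove_ambiguous`: drops strand-ambiguous variants (allele pair
#'     A/T or C/G).
#'   \item `dedup_positions`: collapses variants sharing (chrom, pos),
#'     keeping the one with the lowest missing rate, ties broken by
#'     lexicographically smaller vid.
#'   \item `filter_info`: drops variants with imputation INFO strictly below
#'     `min_info`; variants without an INFO score (array data) pass.
#' }
#'
#' @param g a [genotype_matrix()].
#' @param max_rate,min_maf,min_p,min_info thresholds.
#' @param controls_only compute HWE counts on controls only (binary trait
#'   with phenotype attached required).
#' @return A filtered [genotype_matrix()].
#' @name qc_filters
NULL

#' @rdname qc_filters
#' @export
filter_missing <- function(g, max_rate = 0.05) {
  if (max_rate < 0 || max_rate > 1) stop("max_rate must lie in [0, 1]")
  rates <- colMeans(is.na(g$genotypes))
  subset_variants(g, rates <= max_rate)
}

#' @rdname qc_filters
#' @export
filter_maf <- function(g, min_maf = 0.01) {
  freq <- colMeans(g$genotypes, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0  # all-missing: treated as monomorphic
  subset_variants(g, maf >= min_maf)
}

#' @rdname qc_filters
#' @export
filter_hwe <- function(g, min_p = 1e-10, controls_only = FALSE) {
  x <- g$genotypes
  if (controls_only) {
    if (is.null(g$phenotype) || !identical(g$trait_type, "binary")) {
      stop("controls_only requires a binary phenotype")
    }
    x <- x[!is.na(g$phenotype) & g$phenotype == 0, , drop = FALSE]
  }
  p <- apply(x, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(1)
    hwe_exact_p(sum(col == 2), sum(col == 1), sum(col == 0))
  })
  subset_variants(g, p >= min_p)
}

#' @rdname qc_filters
#' @export
remove_ambiguous <- function(g) {
  pair <- paste(pmin(g$variants$a1, g$variants$a2),
                pmax(g$variants$a1, g$variants$a2))
  subset_variants(g, !(pair %in% c("A T", "C G")))
}

#' @rdname qc_filters
#' @export
dedup_positions <- function(g) {
  rates <- colMeans(is.na(g$genotypes))
  key <- paste(g$variants$chrom, g$variants$pos)
  o <- order(key, rates, g$variants$vid)
  keep_vids <- g$variants$vid[o][!duplicated(key[o])]
  subset_variants(g, g$variants$vid %in% keep_vids)
}

#' @rdname qc_filters
#' @export
filter_info <- function(g, min_info = 0.7) {
  info <- g$variants$info
  subset_variants(g, is.na(info) | info >= min_info)
}

#' Run the full variant quality-control cascade
#'
#' Applies, in order: missing call rate, minor allele frequency,
#' Hardy-Weinberg exact test, ambiguous-SNP removal, position-level
#' deduplication, and imputation INFO score. The order matters for the
#' per-filter counts (e.g. a variant failing both missingness and MAF is
#' charged to the missingness filter).
#'
#' @param g a [genotype_matrix()].
#' @param max_missing,min_maf,hwe_min_p,min_info filter thresholds; the
#'   defaults are the standard pre-PRS settings (0.05, 0.01, 1e-10, 0.7).
#' @param hwe_controls_only restrict HWE counts to controls.
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (a `qc_report`: per-filter removal counts, in order).
#' @export
run_qc <- function(g, max_missing = 0.05, min_maf = 0.01, hwe_min_p = 1e-10,
                   min_info = 0.7, hwe_controls_only = FALSE) {
  steps <- list(
    missing = function(x) filter_missing(x, max_missing),
    maf = function(x) filter_maf(x, min_maf),
    hwe = function(x) filter_hwe(x, hwe_min_p, hwe_controls_only),
    ambiguous = remove_ambiguous,
    dedup = dedup_positions,
    info = function(x) filter_info(x, min_info)
  )
  n_input <- ncol(g$genotypes)
  removed <- integer(length(steps))
  names(removed) <- names(steps)
  for (k in seq_along(steps)) {
    before <- ncol(g$genotypes)
    g <- steps[[k]](g)
    removed[k] <- before - ncol(g$genotypes)
  }
  if (ncol(g$genotypes) == 0L) {
    stop("no variants survive quality control")
  }
  report <- structure(
    list(removed = removed, n_input = n_input,
         n_surviving = ncol(g$genotypes),
         thresholds = c(max_missing = max_missing, min_maf = min_maf,
                        hwe_min_p = hwe_min_p, min_info = min_info)),
    class = "qc_report")
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("variant QC:", x$n_input, "->", x$n_surviving, "variants\n")
  for (nm in names(x$removed)) {
    cat(sprintf("  %-10s removed %d\n", nm, x$removed[[nm]]))
  }
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(filter = names(x$removed), removed = unname(x$removed))
}
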