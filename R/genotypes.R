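#' Genotype matrix container
#'
#' Bundles an n_samples x n_variants allele-count (dosage) matrix with its
#' variant and sample metadata. Dosages count copies of the first allele
#' (`a1`, the "counted" allele, PLINK A1 convention) and are 0, 1, 2 or `NA`
#' for a missing call.
#'
#' @param genotypes integer/numeric matrix, samples in rows, variants in
#'   columns; entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `vid` (unique variant id), `a1`, `a2` (distinct allele strings) and
#'   optionally `info` (imputation quality in `[0, 1]`, `NA` for array data).
#' @param sample_ids character vector of unique sample identifiers.
#' @param phenotype optional numeric phenotype vector aligned with samples
#'   (`NA` = missing); 0/1 for binary traits.
#' @param trait_type `"binary"`, `"quantitative"` or `NA` when no phenotype
#'   is attached.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, variants, sample_ids,
                            phenotype = NULL, trait_type = NA_character_) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (!is.data.frame(variants)) {
    stop("`variants` must be a data.frame")
  }
  needed <- c("chrom", "pos", "vid", "a1", "a2")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols)) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"info" %in% names(variants)) {
    variants$info <- rep(NA_real_, nrow(variants))
  }
  variants <- variants[, c(needed, "info")]
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$vid <- as.character(variants$vid)
  variants$a1 <- as.character(variants$a1)
  variants$a2 <- as.character(variants$a2)
  variants$info <- as.numeric(variants$info)
  sample_ids <- as.character(sample_ids)

  if (ncol(genotypes) != nrow(variants)) {
    stop("genotype matrix has ", ncol(genotypes), " columns but ",
         nrow(variants), " variant records")
  }
  if (nrow(genotypes) != length(sample_ids)) {
    stop("genotype matrix has ", nrow(genotypes), " rows but ",
         length(sample_ids), " sample ids")
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (anyDuplicated(variants$vid)) stop("variant ids must be unique")
  if (any(variants$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(variants$a1 == variants$a2)) stop("a1 and a2 must differ")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("non-missing dosages must be 0, 1 or 2")
  }
  if (!is.null(phenotype)) {
    if (length(phenotype) != length(sample_ids)) {
      stop("phenotype length must match sample count")
    }
    phenotype <- as.numeric(phenotype)
  }
  dimnames(genotypes) <- list(sample_ids, variants$vid)
  structure(
    list(genotypes = genotypes, variants = variants, sample_ids = sample_ids,
         phenotype = phenotype, trait_type = trait_type),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$genotypes))
  cat("genotype_matrix: ", nrow(x$genotypes), " samples x ",
      ncol(x$genotypes), " variants\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$variants$chrom), collapse = ", "),
      "\n", sep = "")
  cat("  missing calls: ", n_miss, " (",
      signif(100 * n_miss / max(1, length(x$genotypes)), 3), "%)\n", sep = "")
  if (!is.null(x$phenotype)) {
    cat("  phenotype: ", x$trait_type, ", ",
        sum(!is.na(x$phenotype)), " observed\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

# Subset a genotype_matrix by variant column index (internal).
subset_variants <- function(g, keep) {
  genotype_matrix(g$genotypes[, keep, drop = FALSE],
                  g$variants[keep, , drop = FALSE],
                  g$sample_ids, g$phenotype, g$trait_type)
}

# Subset by sample index (internal).
subset_samples <- function(g, keep) {
  genotype_matrix(g$genotypes[keep, , drop = FALSE], g$variants,
                  g$sample_ids[keep],
                  if (is.null(g$phenotype)) NULL else g$phenotype[keep],
                  g$trait_type)
}

# Order variants by (chrom, pos, vid); used before any on-disk write.
order_variants <- function(g) {
  o <- order(g$variants$chrom, g$variants$pos, g$variants$vid)
  if (identical(o, seq_len(nrow(g$variants)))) return(g)
  subset_variants(g, o)
}
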