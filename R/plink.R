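#' Read a PLINK-1 binary fileset
#'
#' Reads a `.bed`/`.bim`/`.fam` triple (SNP-major PLINK-1 layout, magic bytes
#' `0x6C 0x1B 0x01`) into a [genotype_matrix()]. Dosages count the bim A1
#' allele: the 2-bit codes 00/10/11 decode to 2/1/0 copies of A1 and 01 to a
#' missing call. The fam phenotype column is attached: values confined to
#' `{1, 2, -9}` are treated as control/case/missing and recoded 0/1/`NA`;
#' anything else is taken as a quantitative trait with `-9` as missing.
#'
#' @param path_prefix path without the `.bed`/`.bim`/`.fam` extension.
#' @return A [genotype_matrix()] with phenotype attached when present.
#' @seealso [write_plink()]
#' @export
read_plink <- function(path_prefix) {
  paths <- paste0(path_prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) {
    if (!file.exists(p)) stop("missing PLINK file: ", p)
  }
  bim <- utils::read.table(paths[2], header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"),
                           col.names = c("chrom", "vid", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"),
                           col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"))
  n_samples <- nrow(fam)
  n_variants <- nrow(bim)

  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L ||
      raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) || raw[3] != as.raw(0x01)) {
    stop("not a PLINK-1 SNP-major bed file (bad magic bytes): ", paths[1])
  }
  bytes_per_variant <- ceiling(n_samples / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_variant * n_variants) {
    stop("bed payload is ", length(payload), " bytes but bim/fam imply ",
         bytes_per_variant * n_variants)
  }

  # 256 x 4 lookup: byte value -> dosages of the four samples it packs.
  lut <- plink_byte_lut()
  codes <- lut[as.integer(payload) + 1L, , drop = FALSE]
  # codes is (bytes_per_variant * n_variants) x 4; rows grouped by variant.
  geno <- matrix(t(codes), nrow = bytes_per_variant * 4L, ncol = n_variants)
  geno <- geno[seq_len(n_samples), , drop = FALSE]

  pheno <- fam$pheno
  trait_type <- NA_character_
  phenotype <- NULL
  obs <- pheno[!is.na(pheno)]
  if (length(obs)) {
    if (all(obs %in% c(1, 2, -9))) {
      trait_type <- "binary"
      phenotype <- ifelse(pheno == -9, NA_real_, pheno - 1)
    } else {
      trait_type <- "quantitative"
      phenotype <- ifelse(pheno == -9, NA_real_, pheno)
    }
  }

  variants <- data.frame(chrom = bim$chrom, pos = bim$pos, vid = bim$vid,
                         a1 = bim$a1, a2 = bim$a2, info = NA_real_,
                         stringsAsFactors = FALSE)
  genotype_matrix(geno, variants, fam$iid, phenotype, trait_type)
}

#' Write a PLINK-1 binary fileset
#'
#' Writes `g` as a SNP-major `.bed`/`.bim`/`.fam` triple. Variants are sorted
#' by (chromosome, position) before writing; A1 is the counted allele. A
#' binary phenotype is written as 1/2 (control/case) with `-9` for missing,
#' a quantitative one as-is.
#'
#' @param g a [genotype_matrix()].
#' @param path_prefix output path without extension.
#' @return `path_prefix`, invisibly.
#' @export
write_plink <- function(g, path_prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (ncol(g$genotypes) == 0L) stop("refusing to write a matrix with no variants")
  if (nrow(g$genotypes) == 0L) stop("refusing to write a matrix with no samples")
  g <- order_variants(g)
  n_samples <- nrow(g$genotypes)
  n_variants <- ncol(g$genotypes)
  bytes_per_variant <- ceiling(n_samples / 4)

  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, nrow = bytes_per_variant * 4L, ncol = n_variants)
  x <- g$genotypes
  code[seq_len(n_samples), ] <- ifelse(is.na(x), 1L, c(3L, 2L, 0L)[x + 1L])
  # pad samples beyond n_samples encode as 0 (hom A2, ignored on read)
  if (bytes_per_variant * 4L > n_samples) {
    code[(n_samples + 1L):(bytes_per_variant * 4L), ] <- 0L
  }
  dim(code) <- c(4L, bytes_per_variant * n_variants)
  bytes <- as.raw(code[1L, ] + bitwShiftL(code[2L, ], 2L) +
                  bitwShiftL(code[3L, ], 4L) + bitwShiftL(code[4L, ], 6L))

  con <- file(paste0(path_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)

  bim <- data.frame(chrom = g$variants$chrom, vid = g$variants$vid, cm = 0,
                    pos = g$variants$pos, a1 = g$variants$a1, a2 = g$variants$a2)
  utils::write.table(bim, paste0(path_prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  pheno <- rep(-9, n_samples)
  if (!is.null(g$phenotype)) {
    if (identical(g$trait_type, "binary")) {
      pheno <- ifelse(is.na(g$phenotype), -9, g$phenotype + 1)
    } else {
      pheno <- ifelse(is.na(g$phenotype), -9, g$phenotype)
    }
  }
  fam <- data.frame(fid = g$sample_ids, iid = g$sample_ids, pid = "0",
                    mid = "0", sex = 0L, pheno = sprintf("%.17g", pheno))
  utils::write.table(fam, paste0(path_prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path_prefix)
}

# byte value (0..255) -> 4 dosages, low bit-pair first; PLINK-1 SNP-major.
plink_byte_lut <- function() {
  b <- 0:255
  lut <- matrix(NA_real_, nrow = 256, ncol = 4)
  for (k in 0:3) {
    two_bit <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
    lut[, k + 1L] <- c(2, NA, 1, 0)[two_bit + 1L]
  }
  lut
}
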