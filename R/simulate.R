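#' Simulate LD-blocked diploid genotypes
#'
#' Generates hard-call dosages for `n_samples` individuals at `n_variants`
#' biallelic variants arranged in contiguous LD blocks. Each gamete is drawn
#' from a Gaussian copula: within a block the latent liabilities follow an
#' AR(1) process with lag-one correlation `within_block_r`, and each latent
#' value is thresholded at `qnorm(maf)` to produce a Bernoulli(maf) allele.
#' The dosage is the sum of two independent gametes, so adjacent variants in
#' a block show tunable genotype correlation while blocks are independent.
#' Block k starts at position `1 + k * 1e6` bp with 1 kb spacing inside the
#' block (single chromosome), so distinct blocks are more than 250 kb apart
#' and clumping windows behave as on real data.
#'
#' @param n_samples,n_variants positive dimensions.
#' @param block_size variants per LD block (the final block may be shorter).
#' @param within_block_r AR(1) correlation of adjacent latent gametes,
#'   `0 <= r < 1`.
#' @param maf_low,maf_high bounds for the per-variant allele frequency of the
#'   counted allele, `0 < maf_low <= maf_high <= 0.5`.
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return A [genotype_matrix()]; the counted allele `a1` is the simulated
#'   effect allele with frequency `maf`.
#' @export
sim_genotypes <- function(n_samples, n_variants, block_size = 10,
                          within_block_r = 0.8, maf_low = 0.05,
                          maf_high = 0.5, seed = 1) {
  if (n_samples < 1 || n_variants < 1) stop("dimensions must be positive")
  if (within_block_r < 0 || within_block_r >= 1) {
    stop("within_block_r must lie in [0, 1)")
  }
  if (maf_low <= 0 || maf_low > maf_high || maf_high > 0.5) {
    stop("require 0 < maf_low <= maf_high <= 0.5")
  }
  set.seed(seed)
  maf <- stats::runif(n_variants, maf_low, maf_high)
  block <- rep(seq_len(ceiling(n_variants / block_size)),
               each = block_size)[seq_len(n_variants)]

  latent_gamete <- function() {
    e <- matrix(stats::rnorm(n_samples * n_variants), n_samples, n_variants)
    z <- e
    r <- within_block_r
    if (r > 0 && n_variants > 1) {
      for (j in 2:n_variants) {
        if (block[j] == block[j - 1]) {
          z[, j] <- r * z[, j - 1] + sqrt(1 - r^2) * e[, j]
        }
      }
    }
    z
  }
  thresh <- matrix(stats::qnorm(maf), n_samples, n_variants, byrow = TRUE)
  geno <- (latent_gamete() < thresh) + (latent_gamete() < thresh)

  within <- seq_len(n_variants) - match(block, block)
  pos <- 1L + (block - 1L) * 1000000L + within * 1000L
  variants <- data.frame(
    chrom = "1", pos = pos,
    vid = sprintf("v%05d", seq_len(n_variants)),
    a1 = "A", a2 = "G", info = NA_real_, stringsAsFactors = FALSE)
  g <- genotype_matrix(geno, variants,
                       sprintf("s%06d", seq_len(n_samples)))
  attr(g, "maf") <- maf
  attr(g, "block") <- block
  g
}

#' Declare a true genetic architecture
#'
#' @param causal_vids variant ids carrying additive effects.
#' @param betas additive per-allele effect sizes, one per causal vid.
#' @param interaction_pairs optional data.frame with columns `vid1`, `vid2`,
#'   `coef`: pairwise epistatic terms applied to products of centred dosages.
#' @param h2 target broad-sense heritability of the simulated trait, in (0,1).
#' @param prevalence case fraction for binary traits, in (0,1).
#' @return An object of class `true_effects`.
#' @export
true_effects <- function(causal_vids, betas, interaction_pairs = NULL,
                         h2 = 0.5, prevalence = 0.1) {
  if (length(causal_vids) != length(betas)) {
    stop("one beta per causal vid required")
  }
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  if (!is.null(interaction_pairs)) {
    stopifnot(all(c("vid1", "vid2", "coef") %in% names(interaction_pairs)))
  }
  structure(list(causal_vids = as.character(causal_vids),
                 betas = as.numeric(betas),
                 interaction_pairs = interaction_pairs,
                 h2 = h2, prevalence = prevalence,
                 liability_threshold = NA_real_),
            class = "true_effects")
}

#' Simulate a phenotype on top of simulated genotypes
#'
#' The genetic score is the sum of additive terms (per-allele effects on
#' centred dosages) and any pairwise interaction terms (products of centred
#' dosages). Centring uses the realised mean dosage, so interaction terms are
#' near-orthogonal to the marginal effects and largely invisible to marginal
#' GWAS unless the interacting variants also carry additive effects.
#' Environmental noise is drawn, residualised against the genetic score and
#' rescaled so the realised variance ratio Var(genetic)/Var(total) equals
#' `effects$h2` exactly on the simulated sample. Binary traits threshold the
#' liability at its empirical `1 - prevalence` quantile.
#'
#' @param g a [genotype_matrix()] containing every vid named in `effects`.
#' @param effects a [true_effects()] object.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param noise_seed integer seed for the environmental noise.
#' @return A list with `phenotype` (numeric; 0/1 for binary), `liability`,
#'   `genetic_score` and the realised `effects` (liability threshold filled
#'   in for binary traits).
#' @export
sim_phenotype <- function(g, effects, trait_type = c("quantitative", "binary"),
                          noise_seed = 1) {
  trait_type <- match.arg(trait_type)
  stopifnot(inherits(g, "genotype_matrix"), inherits(effects, "true_effects"))
  all_vids <- unique(c(effects$causal_vids,
                       effects$interaction_pairs$vid1,
                       effects$interaction_pairs$vid2))
  unknown <- setdiff(all_vids, g$variants$vid)
  if (length(unknown)) {
    stop("effects reference unknown vid(s): ", paste(unknown, collapse = ", "))
  }
  n <- nrow(g$genotypes)
  score <- numeric(n)
  centred <- function(vid) {
    x <- g$genotypes[, vid]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x - mean(x)
  }
  for (k in seq_along(effects$causal_vids)) {
    score <- score + effects$betas[k] * centred(effects$causal_vids[k])
  }
  ip <- effects$interaction_pairs
  if (!is.null(ip)) {
    for (k in seq_len(nrow(ip))) {
      score <- score + ip$coef[k] * centred(ip$vid1[k]) * centred(ip$vid2[k])
    }
  }

  set.seed(noise_seed)
  eps <- stats::rnorm(n)
  vg <- stats::var(score)
  if (vg > 0) {
    # residualise noise against the genetic score, then scale exactly
    eps <- stats::residuals(stats::lm.fit(cbind(1, score), eps))
    eps <- eps / stats::sd(eps) * sqrt(vg * (1 - effects$h2) / effects$h2)
  } else {
    eps <- eps - mean(eps)
    eps <- eps / stats::sd(eps)
  }
  liability <- score + eps

  if (trait_type == "binary") {
    thr <- stats::quantile(liability, 1 - effects$prevalence, names = FALSE)
    phenotype <- as.numeric(liability > thr)
    effects$liability_threshold <- thr
  } else {
    phenotype <- liability
  }
  list(phenotype = phenotype, liability = liability, genetic_score = score,
       effects = effects)
}

#' Write a simulated study to disk
#'
#' Writes the PLINK triple, a tab-separated truth table (vid, true additive
#' beta, interaction partner and coefficient) and a key=value generation
#' config record, so a simulated study is reproducible from its output
#' directory alone.
#'
#' @param g a [genotype_matrix()] with phenotype attached.
#' @param effects the realised [true_effects()].
#' @param path_prefix output prefix.
#' @param config named list recorded verbatim in `<prefix>.config`.
#' @return `path_prefix`, invisibly.
#' @export
write_sim_study <- function(g, effects, path_prefix, config = list()) {
  write_plink(g, path_prefix)
  truth <- data.frame(vid = effects$causal_vids, true_beta = effects$betas,
                      partner = NA_character_, coef = NA_real_,
                      stringsAsFactors = FALSE)
  ip <- effects$interaction_pairs
  if (!is.null(ip) && nrow(ip)) {
    truth <- rbind(truth,
                   data.frame(vid = ip$vid1, true_beta = NA_real_,
                              partner = ip$vid2, coef = ip$coef,
                              stringsAsFactors = FALSE))
  }
  utils::write.table(truth, paste0(path_prefix, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- c(list(h2 = effects$h2, prevalence = effects$prevalence), config)
  writeLines(paste0(names(cfg), "=", vapply(cfg, format, "")),
             paste0(path_prefix, ".config"))
  invisible(path_prefix)
}

#' Benchmark architectures for stacked-PRS evaluation
#'
#' Two ready-made simulated studies exercising the regimes where stacking
#' and non-linear base learners matter:
#' \describe{
#'   \item{`sim_split_signal_study`}{quantitative trait, h2 = 0.4, with the
#'     causal signal split across significance tiers: 5 strong variants in
#'     distinct LD blocks sized to clear genome-wide significance
#'     (about 3\% of phenotypic variance each at the default n) plus 50
#'     weak variants (0.5\% each) whose association p-values land in the
#'     sub-threshold 1e-4 to 5e-2 range, so no single p-value cutoff
#'     captures the full architecture.}
#'   \item{`sim_epistatic_study`}{interaction-dominant quantitative trait,
#'     h2 = 0.4: 10 cross-block variant pairs with pure pairwise-product
#'     effects on centred dosages (3\% of variance per pair) whose members
#'     also carry weak additive tags (0.5\% each) making them marginally
#'     detectable, while the bulk of the signal stays invisible to any
#'     additive score.}
#' }
#'
#' @param n_samples cohort size (default 4000).
#' @param seed integer seed driving genotypes and noise.
#' @return List with `g` (a [genotype_matrix()]), `phenotype`,
#'   `trait_type` and the realised `effects`.
#' @name benchmark_studies
NULL

#' @rdname benchmark_studies
#' @export
sim_split_signal_study <- function(n_samples = 4000, seed = 1) {
  g <- sim_genotypes(n_samples, 300, block_size = 5, within_block_r = 0.5,
                     maf_low = 0.1, maf_high = 0.5, seed = seed)
  strong <- g$variants$vid[c(1, 6, 11, 16, 21)]
  weak <- g$variants$vid[seq(26, 271, 5)]  # one causal per LD block
  beta_for_var <- function(vids, target) {
    f <- colMeans(g$genotypes[, vids, drop = FALSE]) / 2
    sqrt(target / (2 * f * (1 - f)))
  }
  eff <- true_effects(c(strong, weak),
                      c(beta_for_var(strong, 0.04),
                        beta_for_var(weak, 0.004)),
                      h2 = 0.4)
  ph <- sim_phenotype(g, eff, "quantitative",
                      noise_seed = stage_seed(seed, 7))
  list(g = g, phenotype = ph$phenotype, trait_type = "quantitative",
       effects = ph$effects)
}

#' @rdname benchmark_studies
#' @export
sim_epistatic_study <- function(n_samples = 4000, seed = 1) {
  g <- sim_genotypes(n_samples, 150, block_size = 5, within_block_r = 0.5,
                     maf_low = 0.2, maf_high = 0.5, seed = seed)
  # pair members sit in different LD blocks, so the product term carries
  # no marginal signal of its own
  v1 <- g$variants$vid[seq(1, 100, 10)]
  v2 <- g$variants$vid[seq(6, 105, 10)]
  Xc <- scale(g$genotypes[, c(v1, v2)], scale = FALSE)
  prod_var <- vapply(1:10, function(k) {
    stats::var(Xc[, k] * Xc[, k + 10])
  }, 0)
  ip <- data.frame(vid1 = v1, vid2 = v2, coef = sqrt(0.03 / prod_var))
  f <- colMeans(g$genotypes[, c(v1, v2)]) / 2
  tag_beta <- sqrt(0.005 / (2 * f * (1 - f)))
  eff <- true_effects(c(v1, v2), tag_beta, interaction_pairs = ip, h2 = 0.4)
  ph <- sim_phenotype(g, eff, "quantitative",
                      noise_seed = stage_seed(seed, 13))
  list(g = g, phenotype = ph$phenotype, trait_type = "quantitative",
       effects = ph$effects)
}
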