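#' Linear polygenic score
#'
#' Computes the classic additive PRS for every sample: the sum over selected
#' markers of the dosage of the counted allele times its estimated effect
#' size, `PRS_i = sum_j X_ij * b_j`. Alleles are reconciled between the
#' summary statistics and the genotype matrix: if the statistics count the
#' genotype's other allele (directly or as its strand complement) the effect
#' sign is flipped; anything else is an error naming the variant. A missing
#' dosage contributes the association sample's mean dosage (`2 * freq`)
#' times the effect.
#'
#' @param g a [genotype_matrix()].
#' @param stats a `sumstats` table covering `vids`.
#' @param vids variants to score with.
#' @param idx sample indices to score (default: all samples).
#' @return Numeric score vector named by sample id.
#' @export
score_prs <- function(g, stats, vids, idx = seq_along(g$sample_ids)) {
  if (!length(vids)) {
    return(stats::setNames(numeric(length(idx)), g$sample_ids[idx]))
  }
  gi <- match(vids, g$variants$vid)
  si <- match(vids, stats$vid)
  if (anyNA(gi)) stop("vids absent from genotypes: ",
                      paste(vids[is.na(gi)], collapse = ", "))
  if (anyNA(si)) stop("vids absent from summary statistics: ",
                      paste(vids[is.na(si)], collapse = ", "))
  flip <- reconcile_alleles(g$variants[gi, ], stats[si, ])
  beta <- stats$beta[si] * ifelse(flip, -1, 1)
  freq <- stats$freq[si]
  freq[flip] <- 1 - freq[flip]

  X <- g$genotypes[idx, gi, drop = FALSE]
  miss <- is.na(X)
  if (any(miss)) {
    fill <- 2 * freq
    fill[is.na(fill)] <- 0
    X[miss] <- fill[col(X)[miss]]
  }
  stats::setNames(as.vector(X %*% beta), g$sample_ids[idx])
}

# Returns TRUE where the stats allele pair is the genotype pair reversed
# (effect sign must flip), FALSE where they agree; errors otherwise.
# Strand flips (complemented pairs) are accepted either way round.
reconcile_alleles <- function(gvar, svar) {
  comp <- function(a) chartr("ACGT", "TGCA", a)
  same <- (svar$a1 == gvar$a1 & svar$a2 == gvar$a2) |
    (comp(svar$a1) == gvar$a1 & comp(svar$a2) == gvar$a2)
  flipped <- (svar$a1 == gvar$a2 & svar$a2 == gvar$a1) |
    (comp(svar$a1) == gvar$a2 & comp(svar$a2) == gvar$a1)
  bad <- !same & !flipped
  if (any(bad)) {
    stop("allele mismatch between summary statistics and genotypes for: ",
         paste(gvar$vid[bad], collapse = ", "))
  }
  # a pair that matches both ways (shouldn't survive QC) counts as same
  flipped & !same
}

#' Pairwise LD as squared dosage correlation
#'
#' @param g a [genotype_matrix()].
#' @param vid_a,vid_b variant ids.
#' @param idx sample indices (pairwise-complete observations are used).
#' @return Squared Pearson correlation in `[0, 1]`; `NA` when either dosage
#'   is constant.
#' @export
pairwise_r2 <- function(g, vid_a, vid_b, idx = seq_along(g$sample_ids)) {
  x <- g$genotypes[idx, vid_a]
  y <- g$genotypes[idx, vid_b]
  ok <- !is.na(x) & !is.na(y)
  suppressWarnings(stats::cor(x[ok], y[ok]))^2
}

#' Greedy LD clumping
#'
#' Standard pruning-and-thresholding clump: variants are visited in
#' ascending p-value order (ties broken by chromosome, position, then vid);
#' each unremoved variant becomes an index variant and removes every
#' not-yet-processed variant on the same chromosome strictly within
#' `window_kb` kilobases whose squared dosage correlation with it (computed
#' on the `idx` samples) reaches `r2_threshold`.
#'
#' @param g a [genotype_matrix()].
#' @param stats a `sumstats` table covering the variants of `g`.
#' @param idx sample indices used for the LD computation (normally the
#'   training partition).
#' @param r2_threshold,window_kb clumping parameters (defaults 0.1, 250 kb).
#' @return An object of class `clump_result`: `retained` (vids in clump
#'   order) and `removed` (data.frame vid / absorbed_by / r2).
#' @export
clump <- function(g, stats, idx = seq_along(g$sample_ids),
                  r2_threshold = 0.1, window_kb = 250) {
  si <- match(g$variants$vid, stats$vid)
  if (anyNA(si)) stop("summary statistics do not cover all variants")
  v <- g$variants
  p <- stats$p[si]
  o <- order(p, v$chrom, v$pos, v$vid)

  X <- g$genotypes[idx, , drop = FALSE]
  state <- rep("open", nrow(v))  # open | index | removed
  removed <- list()
  for (j in o) {
    if (state[j] != "open") next
    state[j] <- "index"
    near <- which(state == "open" & v$chrom == v$chrom[j] &
                    abs(v$pos - v$pos[j]) < window_kb * 1000)
    for (k in near) {
      x <- X[, j]; yk <- X[, k]
      ok <- !is.na(x) & !is.na(yk)
      r2 <- suppressWarnings(stats::cor(x[ok], yk[ok]))^2
      if (!is.na(r2) && r2 >= r2_threshold) {
        state[k] <- "removed"
        removed[[length(removed) + 1L]] <-
          data.frame(vid = v$vid[k], absorbed_by = v$vid[j], r2 = r2,
                     stringsAsFactors = FALSE)
      }
    }
  }
  retained <- v$vid[o][state[o] == "index"]
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(vid = character(), absorbed_by = character(), r2 = numeric())
  structure(list(retained = retained, removed = removed,
                 r2_threshold = r2_threshold, window_kb = window_kb),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("clump_result:", length(x$retained), "index variants,",
      nrow(x$removed), "removed (r2 >=", x$r2_threshold, "within",
      x$window_kb, "kb)\n")
  invisible(x)
}

#' Pruning-and-thresholding (P+T) polygenic score
#'
#' Clumps on the training partition, keeps index variants with association
#' p-value strictly below `p_threshold` (default the genome-wide 5e-8), and
#' scores with the unaltered GWAS effect sizes via [score_prs()].
#'
#' @inheritParams clump
#' @param split a [make_split()] object; LD is computed on `split$train`.
#' @param p_threshold p-value cutoff applied after clumping.
#' @return A list with `scores` (all samples), `vids` (retained variants)
#'   and the `clump_result`.
#' @export
pt_prs <- function(g, stats, split, p_threshold = 5e-8,
                   r2_threshold = 0.1, window_kb = 250) {
  cl <- clump(g, stats, split$train, r2_threshold, window_kb)
  keep <- cl$retained[stats$p[match(cl$retained, stats$vid)] < p_threshold]
  if (!length(keep)) {
    warning("no clumped variant passes p < ", p_threshold,
            "; returning all-zero scores")
  }
  list(scores = score_prs(g, stats, keep), vids = keep, clump = cl)
}

#' Validation-driven threshold search (PRSice-style)
#'
#' Clumps once on the training partition, then scores the validation
#' partition at every p-value threshold of `grid` and selects the threshold
#' maximising the validation metric (Nagelkerke pseudo-R2 for binary
#' traits, squared correlation for quantitative). Final scores are computed
#' for all samples at the selected threshold; evaluation should use the
#' test partition only.
#'
#' @inheritParams pt_prs
#' @param y phenotype vector for all samples.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param grid decreasing or arbitrary vector of thresholds; the default is
#'   25 log-spaced points from 5e-8 to 1.
#' @return A list: `best_threshold`, `scores`, `vids`, `curve` (data.frame
#'   threshold / n_variants / validation metric) and the `clump_result`.
#' @export
prsice_search <- function(g, stats, split, y,
                          trait_type = c("binary", "quantitative"),
                          grid = prsice_grid(), r2_threshold = 0.1,
                          window_kb = 250) {
  trait_type <- match.arg(trait_type)
  if (!length(grid)) stop("threshold grid is empty")
  cl <- clump(g, stats, split$train, r2_threshold, window_kb)
  p_ret <- stats$p[match(cl$retained, stats$vid)]

  metric <- rep(NA_real_, length(grid))
  n_var <- integer(length(grid))
  for (i in seq_along(grid)) {
    keep <- cl$retained[p_ret < grid[i]]
    n_var[i] <- length(keep)
    if (!length(keep)) next
    sc <- score_prs(g, stats, keep, split$val)
    if (stats::var(sc) == 0) next
    metric[i] <- if (trait_type == "binary") {
      nagelkerke_r2(y[split$val], sc)
    } else {
      r_squared(y[split$val], sc)
    }
  }
  if (all(is.na(metric))) stop("every threshold yields an empty or constant model")
  best <- which.max(metric)
  keep <- cl$retained[p_ret < grid[best]]
  list(best_threshold = grid[best],
       scores = score_prs(g, stats, keep), vids = keep,
       curve = data.frame(threshold = grid, n_variants = n_var,
                          metric = metric),
       clump = cl)
}

#' @rdname prsice_search
#' @param n number of grid points.
#' @param from,to grid end points.
#' @export
prsice_grid <- function(n = 25, from = 5e-8, to = 1) {
  exp(seq(log(from), log(to), length.out = n))
}
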