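#' Train/validation/test split
#'
#' Partitions samples 9:1 into (training+validation) and test, then splits
#' the first part 8:2 into training and validation, i.e. 72% / 18% / 10%
#' overall. Binary traits are stratified by case status so the case fraction
#' of every partition stays within a percentage point of the overall
#' fraction; quantitative traits use a simple random split with the same
#' ratios.
#'
#' @param phenotype numeric phenotype vector (0/1 for binary).
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param seed integer seed; the same seed reproduces the split.
#' @param test_frac,val_frac test fraction of all samples, and validation
#'   fraction of the non-test remainder.
#' @return An object of class `data_split` with integer index vectors
#'   `train`, `val`, `test`.
#' @export
make_split <- function(phenotype, trait_type = c("binary", "quantitative"),
                       seed = 1, test_frac = 0.1, val_frac = 0.2) {
  trait_type <- match.arg(trait_type)
  n <- length(phenotype)
  if (n < 10) stop("need at least 10 samples to split")
  idx <- seq_len(n)
  strata <- if (trait_type == "binary") split(idx, phenotype) else list(idx)
  sizes <- vapply(strata, length, 0L)
  if (any(sizes < 3)) stop("a stratum has fewer than 3 members")

  set.seed(seed)
  train <- val <- test <- integer(0)
  for (s in strata) {
    s <- sample(s)
    n_test <- round(test_frac * length(s))
    test_s <- s[seq_len(n_test)]
    rest <- s[-seq_len(n_test)]
    n_val <- round(val_frac * length(rest))
    val_s <- rest[seq_len(n_val)]
    train_s <- rest[-seq_len(n_val)]
    train <- c(train, train_s); val <- c(val, val_s); test <- c(test, test_s)
  }
  structure(list(train = sort(train), val = sort(val), test = sort(test),
                 stratified = trait_type == "binary", seed = seed),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("data_split: train", length(x$train), "/ val", length(x$val),
      "/ test", length(x$test),
      if (x$stratified) "(stratified)" else "", "\n")
  invisible(x)
}

# Mean-impute missing dosages column-wise over the rows given (internal).
impute_dosages <- function(X) {
  miss <- is.na(X)
  if (any(miss)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    X[miss] <- mu[col(X)[miss]]
  }
  X
}

sumstats_skeleton <- function(g, n_obs) {
  data.frame(vid = g$variants$vid, chrom = g$variants$chrom,
             pos = g$variants$pos, a1 = g$variants$a1, a2 = g$variants$a2,
             beta = 0, se = NA_real_, p = 1, freq = NA_real_,
             n = n_obs, flagged = FALSE, stringsAsFactors = FALSE)
}

#' Per-SNP association on the training partition
#'
#' `assoc_quantitative` regresses the phenotype on each variant's dosage
#' (simple linear regression with intercept); the two-sided p-value comes
#' from the t distribution with n-2 degrees of freedom. `assoc_binary` fits
#' a univariate logistic regression (intercept + dosage) per variant by
#' Newton iteration to gradient norm below 1e-8 and reports the Wald
#' two-sided p-value. Both tests run on the supplied index set only —
#' normally the training partition, so no information leaks from validation
#' or test samples — and mean-impute missing dosages within that set.
#' Degenerate variants (zero dosage variance, perfect separation,
#' non-convergence) are flagged and reported with `beta = 0`, `p = 1`.
#'
#' @param g a [genotype_matrix()].
#' @param y phenotype for all samples (only `idx` is used).
#' @param idx sample indices to fit on (the training partition).
#' @return A `sumstats` data.frame: `vid`, `chrom`, `pos`, `a1`, `a2`,
#'   `beta`, `se`, `p`, `freq` (counted-allele frequency in `idx`), `n`,
#'   plus a logical `flagged` column.
#' @export
assoc_quantitative <- function(g, y, idx = seq_along(y)) {
  X <- impute_dosages(g$genotypes[idx, , drop = FALSE])
  y <- y[idx]
  n <- length(y)
  if (n < 3) stop("need at least 3 samples for association")
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  yc <- y - mean(y)
  sxx <- colSums(Xc^2)
  sxy <- as.vector(crossprod(Xc, yc))
  syy <- sum(yc^2)

  out <- sumstats_skeleton(g, n)
  out$freq <- colMeans(g$genotypes[idx, , drop = FALSE], na.rm = TRUE) / 2
  out$n <- colSums(!is.na(g$genotypes[idx, , drop = FALSE]))
  ok <- sxx > 0
  beta <- ifelse(ok, sxy / sxx, 0)
  rss <- pmax(syy - beta * sxy, 0)
  sigma2 <- rss / (n - 2)
  se <- ifelse(ok, sqrt(sigma2 / sxx), NA_real_)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  out$beta[ok] <- beta[ok]
  out$se[ok] <- se[ok]
  out$p[ok] <- pmax(p[ok], .Machine$double.xmin)
  out$flagged <- !ok
  validate_sumstats(out)
}

#' @rdname assoc_quantitative
#' @export
assoc_binary <- function(g, y, idx = seq_along(y)) {
  X <- impute_dosages(g$genotypes[idx, , drop = FALSE])
  y <- y[idx]
  if (length(unique(y)) < 2) stop("both classes must be present in idx")
  n <- length(y)
  out <- sumstats_skeleton(g, n)
  out$freq <- colMeans(g$genotypes[idx, , drop = FALSE], na.rm = TRUE) / 2
  out$n <- colSums(!is.na(g$genotypes[idx, , drop = FALSE]))

  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (stats::var(x) == 0) { out$flagged[j] <- TRUE; next }
    fit <- logistic_newton(x, y)
    if (!fit$converged) { out$flagged[j] <- TRUE; next }
    out$beta[j] <- fit$beta
    out$se[j] <- fit$se
    out$p[j] <- max(2 * stats::pnorm(-abs(fit$beta / fit$se)),
                    .Machine$double.xmin)
  }
  validate_sumstats(out)
}

# Univariate logistic regression (intercept + slope) by Newton iteration.
# Declares failure (non-convergence / separation) instead of diverging.
logistic_newton <- function(x, y, tol = 1e-8, max_iter = 60) {
  b <- c(log(mean(y) / (1 - mean(y))), 0)
  for (iter in seq_len(max_iter)) {
    eta <- b[1] + b[2] * x
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    grad <- c(sum(y - p), sum((y - p) * x))
    if (max(abs(grad)) < tol) {
      H <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2)
      cov <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(cov) || any(diag(cov) <= 0) || abs(b[2]) > 10) {
        # a per-allele log-odds beyond +-10 is (quasi-)separation
        return(list(converged = FALSE))
      }
      return(list(converged = TRUE, beta = b[2], se = sqrt(cov[2, 2]),
                  intercept = b[1],
                  loglik = sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta))))))
    }
    H <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      return(list(converged = FALSE))
    }
    # dampen huge steps; |eta| growing without bound signals separation
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    b <- b + step
    if (max(abs(b)) > 1e3) return(list(converged = FALSE))
  }
  list(converged = FALSE)
}

#' Select variants passing a p-value threshold
#'
#' @param stats a `sumstats` table.
#' @param p_t p-value threshold; variants with `p < p_t` (strictly) are
#'   selected.
#' @return Character vector of vids in (chrom, pos) order.
#' @export
threshold_variants <- function(stats, p_t) {
  sel <- stats[stats$p < p_t, , drop = FALSE]
  sel$vid[order(sel$chrom, sel$pos, sel$vid)]
}
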