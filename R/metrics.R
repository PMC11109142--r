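#' ROC area under the curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' case receives a higher score than a randomly chosen control, ties counted
#' one half.
#'
#' @param y 0/1 phenotype vector.
#' @param scores numeric scores, higher meaning more case-like.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y, scores) {
  y <- check_binary(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_binary <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("phenotype must be 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  y
}

#' Nagelkerke pseudo-R-squared of a score
#'
#' Refits a univariate logistic regression of the phenotype on the score
#' (with intercept), yielding log-likelihood L1; the intercept-only model
#' gives L0. Cox-Snell R2 = 1 - exp((2/n)(L0 - L1)) is rescaled by its
#' maximum 1 - exp((2/n) L0) to give the Nagelkerke value. The refit makes
#' the metric well-defined for any scoring method, linear or not, and
#' invariant under increasing affine transformations of the score.
#'
#' @inheritParams roc_auc
#' @return Nagelkerke R2 in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(y, scores) {
  y <- check_binary(y)
  if (stats::var(scores) == 0) return(0)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, scores), y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  if (!fit$converged && !fit$boundary && fit$deviance > 1e-6) {
    # near-zero deviance means perfect separation: the value is capped at 1
    # below rather than treated as a failure
    stop("logistic refit for Nagelkerke R2 did not converge")
  }
  l1 <- -fit$deviance / 2
  nagelkerke_from_loglik(l1, y)
}

# Nagelkerke R2 from a model log-likelihood and the 0/1 outcome (internal):
# the null model is intercept-only on the same y.
nagelkerke_from_loglik <- function(l1, y) {
  n <- length(y)
  pbar <- mean(y)
  l0 <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  cs <- 1 - exp((2 / n) * (l0 - l1))
  max_cs <- 1 - exp((2 / n) * l0)
  min(1, max(0, cs / max_cs))
}

#' Squared correlation between phenotype and prediction
#'
#' Squared Pearson correlation, the conventional PRS accuracy measure for
#' quantitative traits: affine miscalibration of the score is not
#' penalised.
#'
#' @param y observed phenotype.
#' @param y_hat predicted score.
#' @return R2 in `[0, 1]`.
#' @export
r_squared <- function(y, y_hat) {
  if (stats::var(y) == 0 || stats::var(y_hat) == 0) {
    stop("zero variance in phenotype or prediction")
  }
  stats::cor(y, y_hat)^2
}

#' Evaluate model scores on one partition
#'
#' @param scores score vector for all samples.
#' @param phenotype phenotype vector for all samples.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param idx sample indices of the partition to evaluate (e.g.
#'   `split$test`).
#' @param partition,model labels recorded in the report.
#' @return An `eval_report`: for binary traits `roc_auc`, `nagelkerke_r2`,
#'   `n_cases`, `n_controls`; for quantitative traits `r2`.
#' @export
evaluate <- function(scores, phenotype, trait_type = c("binary", "quantitative"),
                     idx = seq_along(phenotype), partition = "test",
                     model = "model") {
  trait_type <- match.arg(trait_type)
  s <- scores[idx]
  y <- phenotype[idx]
  rep <- if (trait_type == "binary") {
    y <- check_binary(y)
    list(trait_type = trait_type, roc_auc = roc_auc(y, s),
         nagelkerke_r2 = nagelkerke_r2(y, s),
         n_cases = sum(y == 1), n_controls = sum(y == 0))
  } else {
    list(trait_type = trait_type, r2 = r_squared(y, s))
  }
  structure(c(rep, list(partition = partition, model = model, n = length(y))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("evaluation of", x$model, "on", x$partition,
      "(n =", paste0(x$n, ")"), "\n")
  if (x$trait_type == "binary") {
    cat(sprintf("  ROC AUC        %.4f\n  Nagelkerke R2  %.4g\n", x$roc_auc,
                x$nagelkerke_r2))
    cat("  cases/controls", x$n_cases, "/", x$n_controls, "\n")
  } else {
    cat(sprintf("  R2  %.4g\n", x$r2))
  }
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}
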