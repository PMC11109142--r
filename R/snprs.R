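#' Fit a stacked neural-network polygenic risk score
#'
#' Builds the full stacked model H(Z_1..Z_T) = h'(h_1(Z_1), ..., h_T(Z_T)):
#' for every p-value threshold p_t of `thresholds` the variants with
#' training-GWAS p < p_t form an input set Z_t; an architecture grid search
#' trains the best feed-forward network h_t on (train, validation); the
#' base networks' validation-set predictions are concatenated and a linear
#' meta-learner h' (logistic regression for binary traits, ordinary least
#' squares for quantitative) is fitted on them. Because the threshold
#' ladder is decreasing, the input sets are nested, and because every base
#' model is a column of the meta-learner's design, the stacked model's
#' validation metric can never fall below that of any single base model.
#'
#' Summary statistics are computed on the training partition only (or can
#' be supplied); the test partition never reaches any training stage, which
#' the fitted object records for auditing.
#'
#' @param g a [genotype_matrix()].
#' @param phenotype phenotype vector for all samples; defaults to the
#'   phenotype attached to `g`.
#' @param trait_type `"binary"` or `"quantitative"`; defaults to the trait
#'   type attached to `g`.
#' @param thresholds strictly decreasing p-value ladder (default
#'   5e-2, 5e-3, 5e-4, 5e-5, 5e-6, 5e-8). Thresholds selecting no variant
#'   are dropped with a warning; at least two must survive.
#' @param dnn_grid list of [nn_spec()]s searched per threshold.
#' @param split a [make_split()]; built from `seed` when omitted.
#' @param stats training-partition summary statistics; computed by
#'   [assoc_quantitative()] / [assoc_binary()] on `split$train` when
#'   omitted.
#' @param seed integer master seed; stage seeds are derived from it.
#' @param pre_clump clump the input sets on the training partition before
#'   network training (recommended for imputed, LD-dense genotypes).
#' @param clump_r2,clump_window_kb clumping parameters when `pre_clump`.
#' @param trace print per-stage progress.
#' @return An object of class `snprs`; see [predict.snprs()],
#'   [summary.snprs()], [coef.snprs()].
#' @examples
#' g <- sim_genotypes(600, 60, block_size = 5, seed = 7)
#' eff <- true_effects(c("v00001", "v00011", "v00021"), c(1, 0.8, 0.6),
#'                     h2 = 0.4)
#' ph <- sim_phenotype(g, eff, "quantitative", noise_seed = 7)
#' fit <- snprs(g, ph$phenotype, "quantitative",
#'              thresholds = c(0.5, 0.05, 0.005),
#'              dnn_grid = list(nn_spec(depth = 1, divisors = 2,
#'                                      max_epochs = 50)),
#'              seed = 7)
#' summary(fit)
#' @export
snprs <- function(g, phenotype = g$phenotype, trait_type = g$trait_type,
                  thresholds = c(5e-2, 5e-3, 5e-4, 5e-5, 5e-6, 5e-8),
                  dnn_grid = nn_grid(depths = 1:2, divisors = 2),
                  split = NULL, stats = NULL, seed = 1, pre_clump = FALSE,
                  clump_r2 = 0.1, clump_window_kb = 250, trace = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(phenotype)) stop("no phenotype supplied or attached")
  trait_type <- match.arg(trait_type, c("binary", "quantitative"))
  check_threshold_grid(thresholds)
  if (is.null(split)) split <- make_split(phenotype, trait_type, seed = seed)
  say <- function(...) if (trace) message(...)

  if (is.null(stats)) {
    say("GWAS on ", length(split$train), " training samples")
    stats <- if (trait_type == "binary") {
      assoc_binary(g, phenotype, split$train)
    } else {
      assoc_quantitative(g, phenotype, split$train)
    }
  }

  if (pre_clump) {
    cl <- clump(g, stats, split$train, clump_r2, clump_window_kb)
    g <- subset_variants(g, g$variants$vid %in% cl$retained)
    stats <- stats[stats$vid %in% cl$retained, , drop = FALSE]
  }

  sets <- make_threshold_sets(g, stats, thresholds)
  thresholds <- sets$thresholds

  base_models <- vector("list", length(thresholds))
  search_tables <- vector("list", length(thresholds))
  for (t in seq_along(thresholds)) {
    vids <- sets$vids[[t]]
    say("threshold ", format(thresholds[t]), ": ", length(vids),
        " variants, searching ", length(dnn_grid), " spec(s)")
    X <- g$genotypes[, vids, drop = FALSE]
    gs <- nn_grid_search(X, phenotype, split, dnn_grid, trait_type,
                         seed = stage_seed(seed, t))
    bm <- gs$best
    bm$threshold <- thresholds[t]
    bm$vids <- vids
    base_models[[t]] <- bm
    search_tables[[t]] <- gs$table
  }

  feats <- meta_features(base_models, g, split$val)
  meta <- train_meta(feats, phenotype[split$val], trait_type)

  # validation-metric bookkeeping: meta metric from its own fit, base
  # metrics from the corresponding nested single-column model family
  base_val_metric <- vapply(seq_along(base_models), function(t) {
    single_column_metric(feats[, t], phenotype[split$val], trait_type)
  }, 0)
  stacked_val_metric <- meta$train_metric

  fit <- structure(
    list(trait_type = trait_type, thresholds = thresholds,
         base_models = base_models, meta = meta, split = split,
         stats = stats, seed = seed,
         base_val_metric = base_val_metric,
         stacked_val_metric = stacked_val_metric,
         search_tables = search_tables,
         pre_clump = pre_clump,
         n_samples = nrow(g$genotypes)),
    class = "snprs")
  fit$test_scores <- predict(fit, g, idx = split$test)
  fit
}

check_threshold_grid <- function(thresholds) {
  if (length(thresholds) < 2) stop("need at least two thresholds")
  if (anyDuplicated(thresholds)) stop("duplicate thresholds in the ladder")
  if (any(diff(thresholds) >= 0)) stop("thresholds must be strictly decreasing")
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must lie in (0, 1]")
  }
  invisible(thresholds)
}

stage_seed <- function(seed, t) {
  as.integer((as.numeric(seed) * 1009 + t * 9973) %% 2147483647)
}

#' Build the nested threshold input sets
#'
#' @param g a [genotype_matrix()].
#' @param stats summary statistics covering `g`.
#' @param thresholds strictly decreasing p-value ladder.
#' @return List with `thresholds` (those selecting at least one variant)
#'   and `vids` (the variant list per surviving threshold, nested because
#'   the ladder is decreasing).
#' @export
make_threshold_sets <- function(g, stats, thresholds) {
  check_threshold_grid(thresholds)
  vids <- lapply(thresholds, function(p_t) {
    v <- threshold_variants(stats, p_t)
    intersect(v, g$variants$vid)
  })
  empty <- lengths(vids) == 0
  if (any(empty)) {
    warning("dropping threshold(s) selecting no variant: ",
            paste(format(thresholds[empty]), collapse = ", "))
  }
  thresholds <- thresholds[!empty]
  vids <- vids[!empty]
  if (length(thresholds) < 2) {
    stop("fewer than two thresholds select any variant")
  }
  list(thresholds = thresholds, vids = vids)
}

#' Base-model prediction matrix
#'
#' Column t is base model t's prediction for the requested samples on its
#' own variant set; column order follows the threshold ladder.
#'
#' @param base_models list of trained `base_model`s with `vids` attached.
#' @param g a [genotype_matrix()].
#' @param idx sample indices.
#' @return Numeric matrix, `length(idx)` rows, one column per base model.
#' @export
meta_features <- function(base_models, g, idx) {
  cols <- lapply(base_models, function(bm) {
    X <- impute_dosages(g$genotypes[idx, bm$vids, drop = FALSE])
    predict(bm, X)
  })
  do.call(cbind, cols)
}

#' Train the linear meta-learner
#'
#' Logistic regression of the phenotype on the base-model probability
#' columns (binary traits) or ordinary least squares on the base-model
#' scores (quantitative), with intercept and no regularisation, fitted on
#' the validation partition's base predictions. Rank-deficient columns
#' (e.g. a constant base output) receive a zero coefficient.
#'
#' @param feats matrix from [meta_features()] on the validation partition.
#' @param y phenotype of the validation partition.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @return A `meta_learner`: `intercept`, `coef` (one per base model) and
#'   `train_metric`, the meta model's own metric on its training data
#'   (Nagelkerke R2 from its log-likelihood, or squared correlation of its
#'   fitted values).
#' @export
train_meta <- function(feats, y, trait_type = c("binary", "quantitative")) {
  trait_type <- match.arg(trait_type)
  feats <- as.matrix(feats)
  if (nrow(feats) < ncol(feats) + 1) {
    stop("fewer validation samples than meta parameters")
  }
  X <- cbind(1, feats)
  constant <- apply(feats, 2, function(x) stats::var(x) == 0)
  if (all(constant)) {
    warning("all base-model outputs are constant; intercept-only meta fit")
  }
  if (trait_type == "binary") {
    y <- check_binary(y)
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12,
                                                  maxit = 200)))
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    metric <- nagelkerke_from_loglik(-fit$deviance / 2, y)
  } else {
    fit <- stats::lm.fit(X, y)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    fitted <- as.vector(X %*% coefs)
    metric <- if (stats::var(fitted) == 0) 0 else r_squared(y, fitted)
  }
  structure(list(intercept = coefs[1], coef = coefs[-1],
                 trait_type = trait_type, train_metric = metric),
            class = "meta_learner")
}

# Validation metric of the single-column model family nested in the meta
# learner (internal): univariate logistic refit / univariate OLS R2.
single_column_metric <- function(x, y, trait_type) {
  if (stats::var(x) == 0) return(0)
  if (trait_type == "binary") {
    nagelkerke_r2(y, x)
  } else {
    r_squared(y, x)
  }
}

#' Predict from a fitted stacked model
#'
#' Exact composition of the fitted pipeline: each base network scores its
#' own variant set, the meta-learner combines the columns linearly, and for
#' binary traits the logistic link maps the combination to a probability —
#' the reported PRS.
#'
#' @param object a fitted [snprs()] model.
#' @param g a [genotype_matrix()] holding the model's variants.
#' @param idx sample indices to score (default all).
#' @param type `"response"` (probability for binary traits) or `"link"`
#'   (the linear combination).
#' @param ... unused.
#' @return Score vector named by sample id.
#' @export
predict.snprs <- function(object, g, idx = seq_along(g$sample_ids),
                          type = c("response", "link"), ...) {
  type <- match.arg(type)
  feats <- meta_features(object$base_models, g, idx)
  eta <- as.vector(object$meta$intercept + feats %*% object$meta$coef)
  out <- if (object$trait_type == "binary" && type == "response") {
    stats::plogis(eta)
  } else {
    eta
  }
  stats::setNames(out, g$sample_ids[idx])
}

#' @export
print.snprs <- function(x, ...) {
  cat("Stacked neural-network PRS (", x$trait_type, " trait)\n", sep = "")
  cat("  thresholds:", paste(format(x$thresholds), collapse = " "), "\n")
  cat("  base models:", length(x$base_models), " meta coefficients:",
      paste(signif(x$meta$coef, 3), collapse = " "), "\n")
  cat("  validation metric:", signif(x$stacked_val_metric, 4),
      "(best single base:", paste0(signif(max(x$base_val_metric), 4), ")\n"))
  invisible(x)
}

#' Summarise a fitted stacked model
#'
#' @param object a fitted [snprs()] model.
#' @param ... unused.
#' @return A `summary.snprs`: per-threshold table (variants, architecture,
#'   epochs, validation metric, meta coefficient) plus the stacked
#'   validation metric.
#' @export
summary.snprs <- function(object, ...) {
  tab <- data.frame(
    threshold = object$thresholds,
    n_variants = vapply(object$base_models, function(b) length(b$vids), 0L),
    depth = vapply(object$base_models, function(b) b$spec$depth, 0L),
    dropout = vapply(object$base_models, function(b) b$spec$dropout, FALSE),
    batchnorm = vapply(object$base_models, function(b) b$spec$batchnorm, FALSE),
    epochs = vapply(object$base_models, function(b) b$epochs_run, 0L),
    val_metric = object$base_val_metric,
    meta_coef = unname(object$meta$coef))
  structure(list(table = tab, stacked_val_metric = object$stacked_val_metric,
                 trait_type = object$trait_type,
                 intercept = object$meta$intercept,
                 split = object$split),
            class = "summary.snprs")
}

#' @export
print.summary.snprs <- function(x, ...) {
  cat("Stacked neural-network PRS —", x$trait_type, "trait\n")
  cat("samples: train", length(x$split$train), "/ val", length(x$split$val),
      "/ test", length(x$split$test), "\n\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("\nmeta intercept", signif(x$intercept, 4),
      "| stacked validation metric", signif(x$stacked_val_metric, 4), "\n")
  invisible(x)
}

#' @export
coef.snprs <- function(object, ...) {
  stats::setNames(c(object$meta$intercept, object$meta$coef),
                  c("(Intercept)", paste0("p<", format(object$thresholds))))
}

#' Plot base-model and stacked validation performance
#'
#' Validation metric of each base network against its p-value threshold,
#' with the stacked model's validation metric as a horizontal reference.
#'
#' @param x a fitted [snprs()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.snprs <- function(x, ...) {
  graphics::plot(-log10(x$thresholds), x$base_val_metric, type = "b",
                 pch = 19, xlab = expression(-log[10](p~threshold)),
                 ylab = "validation metric",
                 ylim = range(c(x$base_val_metric, x$stacked_val_metric)),
                 ...)
  graphics::abline(h = x$stacked_val_metric, lty = 2, col = "red3")
  graphics::legend("bottomright", legend = c("base models", "stacked"),
                   lty = c(1, 2), pch = c(19, NA),
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}
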