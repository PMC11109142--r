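# shared small simulated study for the stacking tests
snprs_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- sim_genotypes(1500, 120, block_size = 6, within_block_r = 0.6,
                         maf_low = 0.1, maf_high = 0.5, seed = 41)
      set.seed(41)
      eff <- true_effects(g$variants$vid[seq(1, 120, 6)],
                          rnorm(20, 0, 1), h2 = 0.4)
      ph <- sim_phenotype(g, eff, "quantitative", noise_seed = 41)
      cache <<- list(g = g, y = ph$phenotype)
    }
    cache
  }
})

tiny_grid <- function() list(nn_spec(depth = 1, divisors = 2,
                                     max_epochs = 80))

test_that("threshold sets are nested and degenerate ladders are rejected", {
  g <- random_genotypes(30, 4, seed = 2)
  st <- stats_for(g, p = c(0.2, 0.04, 3e-7, 1e-9))
  sets <- make_threshold_sets(g, st, c(0.05, 5e-8))
  expect_equal(lengths(sets$vids), c(3L, 1L))
  expect_true(all(sets$vids[[2]] %in% sets$vids[[1]]))

  st2 <- stats_for(g, p = runif(4))
  grids <- list(c(0.5, 0.05, 0.005), c(1, 0.1))
  for (gr in grids) {
    s <- tryCatch(make_threshold_sets(g, st2, gr), error = function(e) NULL,
                  warning = function(w) NULL)
    if (!is.null(s)) {
      for (t in seq_along(s$vids)[-1]) {
        expect_true(all(s$vids[[t]] %in% s$vids[[t - 1]]))
      }
    }
  }
  expect_error(make_threshold_sets(g, st, c(0.05, 0.05)), "duplicate")
  expect_error(suppressWarnings(make_threshold_sets(g, st, c(1e-12, 1e-13))),
               "fewer than two")
  expect_warning(make_threshold_sets(g, st, c(0.05, 1e-4, 1e-12)),
                 "no variant")
})

test_that("meta features line up with base-model predictions", {
  fx <- snprs_fixture()
  sp <- make_split(fx$y, "quantitative", seed = 41)
  st <- assoc_quantitative(fx$g, fx$y, sp$train)
  vids <- threshold_variants(st, 0.01)
  X <- fx$g$genotypes[, vids, drop = FALSE]
  spec <- nn_spec(depth = 1, divisors = 2, max_epochs = 20, seed = 3)
  bm <- nn_train(spec, X[sp$train, ], fx$y[sp$train], X[sp$val, ],
                 fx$y[sp$val], "quantitative")
  bm$vids <- vids
  feats <- meta_features(list(bm, bm), fx$g, sp$val)
  expect_equal(dim(feats), c(length(sp$val), 2))
  expect_identical(feats[, 1], feats[, 2])
  expect_equal(feats[, 1], unname(predict(bm, X[sp$val, ])))
})

test_that("the meta-learner is exact least squares and degrades gracefully", {
  set.seed(51)
  F <- matrix(rnorm(200 * 3), 200, 3)
  y <- rnorm(200)
  m <- train_meta(F, y, "quantitative")
  o <- qr.solve(cbind(1, F), y)  # normal-equations oracle
  expect_equal(unname(c(m$intercept, m$coef)), unname(o), tolerance = 1e-8)

  # a perfect column is reproduced exactly
  F2 <- cbind(y, rnorm(200))
  m2 <- train_meta(F2, y, "quantitative")
  fitted <- m2$intercept + F2 %*% m2$coef
  expect_lt(sqrt(sum((fitted - y)^2)), 1e-8)

  expect_warning(train_meta(matrix(1, 100, 2), rnorm(100), "quantitative"),
                 "constant")
  expect_error(train_meta(matrix(rnorm(6), 2, 3), rnorm(2), "quantitative"),
               "fewer validation samples")
})

test_that("snprs end-to-end: finite scores, reproducibility, index hygiene", {
  fx <- snprs_fixture()
  fit <- snprs(fx$g, fx$y, "quantitative",
               thresholds = c(0.5, 0.05, 0.005, 5e-4),
               dnn_grid = tiny_grid(), seed = 41)
  expect_s3_class(fit, "snprs")
  expect_true(all(is.finite(fit$test_scores)))
  expect_length(fit$test_scores, length(fit$split$test))

  # the same seed reproduces identical meta coefficients
  fit2 <- snprs(fx$g, fx$y, "quantitative",
                thresholds = c(0.5, 0.05, 0.005, 5e-4),
                dnn_grid = tiny_grid(), seed = 41)
  expect_identical(coef(fit), coef(fit2))

  # index hygiene: no test sample reaches a training stage
  expect_length(intersect(fit$split$test,
                          c(fit$split$train, fit$split$val)), 0)
  expect_true(all(fit$stats$n <= length(fit$split$train)))

  s <- summary(fit)
  expect_equal(nrow(s$table), length(fit$thresholds))
  expect_output(print(s), "Stacked neural-network PRS")
  expect_output(print(fit), "base models")
  expect_equal(length(coef(fit)), length(fit$thresholds) + 1)
  pdf(NULL); plot(fit); dev.off()
})

test_that("stacked validation metric dominates every base model", {
  fx <- snprs_fixture()
  fit <- snprs(fx$g, fx$y, "quantitative",
               thresholds = c(0.5, 0.05, 0.005, 5e-4),
               dnn_grid = tiny_grid(), seed = 41)
  expect_true(all(fit$stacked_val_metric >= fit$base_val_metric - 1e-9))

  # binary trait: dominance via the meta log-likelihood
  set.seed(61)
  g <- sim_genotypes(1500, 60, block_size = 6, within_block_r = 0.5,
                     seed = 61)
  eff <- true_effects(g$variants$vid[seq(1, 60, 6)], rnorm(10, 0, 0.8),
                      h2 = 0.4, prevalence = 0.3)
  ph <- sim_phenotype(g, eff, "binary", noise_seed = 61)
  fitb <- snprs(g, ph$phenotype, "binary",
                thresholds = c(0.5, 0.05, 0.005),
                dnn_grid = tiny_grid(), seed = 61)
  expect_true(all(fitb$stacked_val_metric >= fitb$base_val_metric - 1e-9))
  expect_true(all(fitb$test_scores > 0 & fitb$test_scores < 1))
})

test_that("prediction is the exact meta composition of base outputs", {
  fx <- snprs_fixture()
  fit <- snprs(fx$g, fx$y, "quantitative",
               thresholds = c(0.5, 0.05, 0.005),
               dnn_grid = tiny_grid(), seed = 41)
  idx <- fit$split$test
  feats <- meta_features(fit$base_models, fx$g, idx)
  manual <- fit$meta$intercept + as.vector(feats %*% fit$meta$coef)
  expect_equal(unname(predict(fit, fx$g, idx)), manual)

  # meta coefficients (1, 0, ..., 0) with zero intercept reproduce base 1
  fit3 <- fit
  fit3$meta$intercept <- 0
  fit3$meta$coef <- c(1, rep(0, length(fit$base_models) - 1))
  expect_equal(unname(predict(fit3, fx$g, idx)), unname(feats[, 1]))

  # permuting samples permutes predictions identically
  perm <- sample(seq_along(fx$g$sample_ids))
  gp <- fx$g
  gp$genotypes <- fx$g$genotypes[perm, ]
  gp$sample_ids <- fx$g$sample_ids[perm]
  expect_equal(unname(predict(fit, gp)[order(perm)]),
               unname(predict(fit, fx$g)))
})
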