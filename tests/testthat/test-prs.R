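test_that("linear scoring follows the additive model exactly", {
  g <- toy_genotypes(matrix(c(0, 1, 2), 1))
  st <- stats_for(g, p = rep(0.5, 3), beta = c(0.5, -0.2, 0.1))
  expect_equal(unname(score_prs(g, st, g$variants$vid)), 0)

  g2 <- random_genotypes(40, 10, seed = 3)
  st2 <- stats_for(g2, p = runif(10), beta = rnorm(10))
  vids <- g2$variants$vid
  s_all <- score_prs(g2, st2, vids)
  # additivity over a partition of the variant set
  expect_equal(s_all, score_prs(g2, st2, vids[1:4]) +
                 score_prs(g2, st2, vids[5:10]))
  # linear in the effect sizes
  st3 <- st2; st3$beta <- 2 * st2$beta
  expect_equal(score_prs(g2, st3, vids), 2 * s_all)
  # zero effects give zero scores
  st0 <- st2; st0$beta[] <- 0
  expect_true(all(score_prs(g2, st0, vids) == 0))
  # permuting samples permutes scores identically
  perm <- sample(40)
  gp <- g2; gp$genotypes <- g2$genotypes[perm, ]; gp$sample_ids <- g2$sample_ids[perm]
  expect_equal(unname(score_prs(gp, st2, vids)), unname(s_all[perm]))
})

test_that("allele reconciliation flips effects and rejects mismatches", {
  g <- toy_genotypes(matrix(c(0, 1, 2, 2), ncol = 1))
  st <- stats_for(g, p = 0.5, beta = 0.4)
  base <- score_prs(g, st, "t001")
  # stats report the other allele: the effect sign flips
  st_fl <- st; st_fl$a1 <- "G"; st_fl$a2 <- "A"; st_fl$freq <- 1 - st$freq
  expect_equal(score_prs(g, st_fl, "t001"), -base)
  # strand-complemented alleles are accepted
  st_str <- st; st_str$a1 <- "T"; st_str$a2 <- "C"
  expect_equal(score_prs(g, st_str, "t001"), base)
  st_bad <- st; st_bad$a1 <- "C"; st_bad$a2 <- "A"
  expect_error(score_prs(g, st_bad, "t001"), "t001")
})

test_that("missing dosages contribute the training-mean dosage", {
  g <- toy_genotypes(matrix(c(0, 2, NA, 1), ncol = 1))
  st <- stats_for(g, p = 0.5, beta = 1, freq = 0.25)
  s <- score_prs(g, st, "t001")
  expect_equal(unname(s[3]), 2 * 0.25)
})

test_that("pairwise r2 behaves as squared dosage correlation", {
  g <- random_genotypes(200, 4, seed = 5)
  g$genotypes[, 2] <- g$genotypes[, 1]
  expect_equal(pairwise_r2(g, "t001", "t001"), 1)
  expect_equal(pairwise_r2(g, "t001", "t002"), 1)
  big <- sim_genotypes(5000, 2, block_size = 1, seed = 6)
  expect_lt(pairwise_r2(big, "v00001", "v00002"), 0.01)
})

test_that("greedy clumping keeps the best variant per correlated window", {
  set.seed(8)
  base <- rbinom(300, 2, 0.4)
  flip <- function(x, k) { i <- sample(300, k); x[i] <- 2 - x[i]; x }
  X <- cbind(base, flip(base, 15), flip(base, 20), rbinom(300, 2, 0.4))
  g <- toy_genotypes(X, pos = c(1000L, 2000L, 3000L, 400000L))
  st <- stats_for(g, p = c(1e-10, 1e-9, 1e-12, 0.5))
  cl <- clump(g, st, r2_threshold = 0.1, window_kb = 250)
  expect_identical(cl$retained, c("t003", "t004"))
  expect_setequal(cl$removed$vid, c("t001", "t002"))
  expect_true(all(cl$removed$absorbed_by == "t003"))
  expect_true(all(cl$removed$r2 >= 0.1))

  # two highly correlated variants 400 kb apart both survive
  g2 <- toy_genotypes(cbind(base, base), pos = c(1000L, 401000L))
  st2 <- stats_for(g2, p = c(1e-8, 1e-6))
  expect_identical(clump(g2, st2)$retained, c("t001", "t002"))
})

test_that("clumping equals the brute-force greedy oracle on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- 150
    m <- sample(20:60, 1)
    g <- sim_genotypes(n, m, block_size = sample(3:8, 1),
                       within_block_r = runif(1, 0.3, 0.95), seed = seed)
    st <- stats_for(g, p = runif(m))
    cl <- clump(g, st, r2_threshold = 0.1, window_kb = 250)
    expect_identical(cl$retained,
                     oracle_clump(g, st, seq_len(n), 0.1, 250))
  }
})

test_that("P+T keeps clumped genome-wide-significant variants only", {
  set.seed(12)
  n <- 5000
  g <- sim_genotypes(n, 60, block_size = 10, within_block_r = 0.9,
                     maf_low = 0.2, maf_high = 0.4, seed = 12)
  causal <- g$variants$vid[c(1, 11, 21, 31, 41)]  # one per block
  eff <- true_effects(causal, rep(1, 5), h2 = 0.5)
  ph <- sim_phenotype(g, eff, "quantitative", noise_seed = 12)
  sp <- make_split(ph$phenotype, "quantitative", seed = 12)
  st <- assoc_quantitative(g, ph$phenotype, sp$train)
  res <- pt_prs(g, st, sp)
  # exactly one index SNP per causal block, each tagging the causal variant
  blocks <- (match(res$vids, g$variants$vid) - 1) %/% 10
  expect_setequal(blocks, 0:4)
  expect_true(all(st$p[match(res$vids, st$vid)] < 5e-8))
  ev <- evaluate(res$scores, ph$phenotype, "quantitative", sp$test)
  expect_gt(ev$r2, 0.2)

  # no variant below the threshold: empty model with a warning
  st_null <- stats_for(g, p = runif(60, 0.1, 1))
  expect_warning(res0 <- pt_prs(g, st_null, sp), "all-zero")
  expect_true(all(res0$scores == 0))
})

test_that("threshold search maximises the validation metric over its grid", {
  set.seed(13)
  g <- sim_genotypes(1500, 50, block_size = 5, within_block_r = 0.5,
                     seed = 13)
  eff <- true_effects(g$variants$vid[seq(1, 50, 5)],
                      rnorm(10, 0, 1), h2 = 0.4)
  ph <- sim_phenotype(g, eff, "quantitative", noise_seed = 13)
  sp <- make_split(ph$phenotype, "quantitative", seed = 13)
  st <- assoc_quantitative(g, ph$phenotype, sp$train)

  res <- prsice_search(g, st, sp, ph$phenotype, "quantitative")
  best_row <- which(res$curve$threshold == res$best_threshold)
  expect_equal(res$curve$metric[best_row],
               max(res$curve$metric, na.rm = TRUE))

  # a one-point grid is exactly P+T at that threshold
  res1 <- prsice_search(g, st, sp, ph$phenotype, "quantitative",
                        grid = 5e-8)
  pt <- pt_prs(g, st, sp)
  expect_equal(res1$scores, pt$scores)
  expect_error(prsice_search(g, stats_for(g, p = rep(1, 50)), sp,
                             ph$phenotype, "quantitative", grid = 1e-10),
               "empty")
})
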