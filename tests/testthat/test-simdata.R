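test_that("simulated genotypes are reproducible and block-structured", {
  g1 <- sim_genotypes(200, 40, block_size = 8, within_block_r = 0.7, seed = 9)
  g2 <- sim_genotypes(200, 40, block_size = 8, within_block_r = 0.7, seed = 9)
  expect_identical(g1$genotypes, g2$genotypes)
  g3 <- sim_genotypes(200, 40, block_size = 8, within_block_r = 0.7, seed = 10)
  expect_false(identical(g1$genotypes, g3$genotypes))

  # block starts 1e6 bp apart, 1 kb spacing inside: blocks > 250 kb apart
  pos <- g1$variants$pos
  expect_equal(pos[1:8], 1 + (0:7) * 1000)
  expect_equal(pos[9], 1 + 1e6)
  expect_error(sim_genotypes(10, 5, maf_low = 0), "maf")
  expect_error(sim_genotypes(0, 5), "positive")
})

test_that("within_block_r = 0 gives independent variants", {
  n <- 3000
  g <- sim_genotypes(n, 40, block_size = 10, within_block_r = 0,
                     maf_low = 0.2, maf_high = 0.4, seed = 2)
  pairs <- cbind(sample(1:40, 100, TRUE), sample(1:40, 100, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  r <- apply(pairs, 1, function(p) {
    cor(g$genotypes[, p[1]], g$genotypes[, p[2]])
  })
  expect_lt(mean(abs(r)), 3 / sqrt(n))
})

test_that("adjacent-pair genotype correlation matches a Monte-Carlo oracle", {
  # oracle: the same copula construction at n = 1e6 for one adjacent pair,
  # fixed maf 0.3, latent AR(1) r = 0.9
  set.seed(42)
  nb <- 1e6
  thr <- qnorm(0.3)
  gamete_pair <- function() {
    z1 <- rnorm(nb)
    z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(nb)
    cbind(z1 < thr, z2 < thr)
  }
  d <- gamete_pair() + gamete_pair()
  r2_oracle <- cor(d[, 1], d[, 2])^2

  g <- sim_genotypes(5000, 40, block_size = 10, within_block_r = 0.9,
                     maf_low = 0.3, maf_high = 0.3, seed = 5)
  block <- rep(1:4, each = 10)
  adj <- which(diff(block) == 0)
  r2 <- vapply(adj, function(j) {
    cor(g$genotypes[, j], g$genotypes[, j + 1])^2
  }, 0)
  expect_gt(mean(r2), r2_oracle - 0.05)
  expect_lt(mean(r2), r2_oracle + 0.05)
})

test_that("quantitative heritability is exact by construction", {
  g <- sim_genotypes(5000, 50, block_size = 10, seed = 3)
  vids <- g$variants$vid[seq(1, 50, 5)]
  eff <- true_effects(vids, rnorm(10), h2 = 0.5)
  ph <- sim_phenotype(g, eff, "quantitative", noise_seed = 3)
  expect_equal(var(ph$genetic_score) / var(ph$phenotype), 0.5,
               tolerance = 1e-12)
  # regressing phenotype on the true genetic score recovers R2 = h2
  expect_equal(summary(lm(ph$phenotype ~ ph$genetic_score))$r.squared, 0.5,
               tolerance = 0.05)
})

test_that("null architecture gives pure noise and binary traits hit prevalence", {
  g <- sim_genotypes(10000, 20, block_size = 5, seed = 6)
  eff0 <- true_effects(g$variants$vid[1], 0, h2 = 0.5, prevalence = 0.1)
  ph0 <- sim_phenotype(g, eff0, "quantitative", noise_seed = 6)
  expect_equal(var(ph0$genetic_score), 0)
  expect_equal(mean(ph0$phenotype), 0, tolerance = 0.05)

  eff <- true_effects(g$variants$vid[1:5], rnorm(5), h2 = 0.3,
                      prevalence = 0.1)
  ph <- sim_phenotype(g, eff, "binary", noise_seed = 7)
  expect_true(all(ph$phenotype %in% 0:1))
  expect_equal(mean(ph$phenotype), 0.1, tolerance = 0.01)
  expect_false(is.na(ph$effects$liability_threshold))
})

test_that("interaction terms on centred dosages are invisible to marginal GWAS", {
  g <- sim_genotypes(4000, 30, block_size = 5, within_block_r = 0,
                     maf_low = 0.3, maf_high = 0.5, seed = 8)
  ip <- data.frame(vid1 = g$variants$vid[c(1, 11)],
                   vid2 = g$variants$vid[c(6, 16)], coef = c(1, 1))
  eff <- true_effects(character(), numeric(), interaction_pairs = ip,
                      h2 = 0.4)
  ph <- sim_phenotype(g, eff, "quantitative", noise_seed = 8)
  st <- assoc_quantitative(g, ph$phenotype)
  # the interacting variants carry no marginal signal
  expect_gt(min(st$p[st$vid %in% c(ip$vid1, ip$vid2)]), 1e-4)
})

test_that("a simulated study writes PLINK + truth + config", {
  g <- sim_genotypes(50, 10, block_size = 5, seed = 1)
  eff <- true_effects(g$variants$vid[1:2], c(1, -1),
                      interaction_pairs = data.frame(
                        vid1 = g$variants$vid[3], vid2 = g$variants$vid[4],
                        coef = 0.5))
  ph <- sim_phenotype(g, eff, "quantitative", noise_seed = 1)
  g$phenotype <- ph$phenotype
  g$trait_type <- "quantitative"
  prefix <- tempfile()
  write_sim_study(g, ph$effects, prefix, config = list(seed = 1))
  expect_true(all(file.exists(paste0(prefix, c(".bed", ".bim", ".fam",
                                               ".truth.tsv", ".config")))))
  truth <- read.table(paste0(prefix, ".truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(truth), 3)
})
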