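# Independent reference implementations used as oracles in the tests.
# These deliberately take the most direct route (enumeration, all-pairs,
# direct likelihood maximisation) rather than sharing code with the package.

# Exact HWE p-value by direct enumeration: probabilities from the
# log-factorial multinomial formula, summed over parity-consistent
# heterozygote counts no more probable than the observed one.
oracle_hwe_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na <- 2 * n_hom1 + n_het
  nb <- 2 * n_hom2 + n_het
  hs <- seq(na %% 2, min(na, nb), by = 2)
  logp <- vapply(hs, function(h) {
    h1 <- (na - h) / 2
    h2 <- (nb - h) / 2
    lfactorial(n) - lfactorial(h1) - lfactorial(h) - lfactorial(h2) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, 0)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hs)]
  min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
}

# AUC by brute force over all case-control pairs, ties counted one half.
oracle_auc <- function(y, s) {
  cases <- s[y == 1]
  controls <- s[y == 0]
  total <- 0
  for (a in cases) {
    total <- total + sum(a > controls) + 0.5 * sum(a == controls)
  }
  total / (length(cases) * length(controls))
}

# Nagelkerke R2 by direct likelihood maximisation with optim().
oracle_nagelkerke <- function(y, s) {
  nll <- function(b) {
    eta <- b[1] + b[2] * s
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(c(0, 0), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  l1 <- -fit$value
  n <- length(y)
  pb <- mean(y)
  l0 <- n * (pb * log(pb) + (1 - pb) * log(1 - pb))
  cs <- 1 - exp((2 / n) * (l0 - l1))
  cs / (1 - exp((2 / n) * l0))
}

# Greedy clump reference: re-sorts the remaining variants before every pick
# and removes neighbours by scanning the full table (structurally different
# from the package's single-pass state machine).
oracle_clump <- function(g, stats, idx, r2_threshold = 0.1, window_kb = 250) {
  v <- g$variants
  v$p <- stats$p[match(v$vid, stats$vid)]
  pool <- v[order(v$p, v$chrom, v$pos, v$vid), ]
  X <- g$genotypes[idx, , drop = FALSE]
  retained <- character()
  while (nrow(pool)) {
    top <- pool[1, ]
    retained <- c(retained, top$vid)
    pool <- pool[-1, , drop = FALSE]
    if (!nrow(pool)) break
    drop <- logical(nrow(pool))
    for (k in seq_len(nrow(pool))) {
      if (pool$chrom[k] != top$chrom) next
      if (abs(pool$pos[k] - top$pos) >= window_kb * 1000) next
      a <- X[, top$vid]; b <- X[, pool$vid[k]]
      ok <- !is.na(a) & !is.na(b)
      r2 <- suppressWarnings(cor(a[ok], b[ok]))^2
      drop[k] <- !is.na(r2) && r2 >= r2_threshold
    }
    pool <- pool[!drop, , drop = FALSE]
  }
  retained
}

# Small hand-built genotype_matrix from a dosage matrix.
toy_genotypes <- function(dosages, chrom = "1", pos = NULL, vids = NULL,
                          a1 = "A", a2 = "G", info = NA_real_) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(vids)) vids <- sprintf("t%03d", seq_len(m))
  genotype_matrix(dosages,
                  data.frame(chrom = chrom, pos = pos, vid = vids,
                             a1 = a1, a2 = a2, info = info,
                             stringsAsFactors = FALSE),
                  sprintf("i%03d", seq_len(nrow(dosages))))
}

# Random genotype matrix with optional missingness (independent variants).
random_genotypes <- function(n, m, maf = NULL, miss = 0, seed = 1) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
  X <- sapply(maf, function(f) rbinom(n, 2, f))
  if (miss > 0) X[matrix(runif(n * m) < miss, n, m)] <- NA
  toy_genotypes(X)
}

# Summary-statistics table with given p-values over a genotype matrix.
stats_for <- function(g, p, beta = NULL, freq = NULL) {
  m <- nrow(g$variants)
  if (is.null(beta)) beta <- rep(0.1, m)
  if (is.null(freq)) freq <- colMeans(g$genotypes, na.rm = TRUE) / 2
  data.frame(vid = g$variants$vid, chrom = g$variants$chrom,
             pos = g$variants$pos, a1 = g$variants$a1, a2 = g$variants$a2,
             beta = beta, se = 0.01, p = p, freq = freq,
             n = nrow(g$genotypes), stringsAsFactors = FALSE)
}
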