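---
title: "Stacked neural-network polygenic risk scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked neural-network polygenic risk scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snprs)
```

## The estimator

A linear polygenic risk score commits to a single GWAS p-value threshold
and to additivity. `snprs` relaxes both commitments with a two-level
model. Level one trains, for every threshold $p_t$ in a decreasing ladder
$p_1 > \dots > p_T$, a feed-forward network $\hat h_t$ on the dosage matrix
$Z_t$ of SNPs with training-GWAS $p < p_t$. Level two fits a linear
meta-learner $\hat h'$ on the base networks' predictions for the
*validation* partition, giving

$$\hat H(Z_{1:T}) = \hat h'\big(\hat h_1(Z_1), \dots, \hat h_T(Z_T)\big).$$

For case/control traits the meta-learner is a logistic regression on the
base probabilities and the reported PRS is the meta probability; for
quantitative traits it is ordinary least squares on the base scores. No
regularisation is applied at either meta link: with $T$ of order ten and
hundreds of validation samples, the meta fit is far from its interpolation
regime, and the unpenalised fit yields an exact model-class nesting
argument (below).

Key assumptions: the phenotype depends on genotype only through the SNPs
that survive QC and thresholding; the split is i.i.d., so
validation-fitted stacking weights transfer to the test partition; and the
GWAS used for thresholding is computed on the training partition only, so
SNP selection never sees validation or test labels.

### Why the stacked model cannot lose on validation

The meta model class contains every single base model: putting weight 1 on
column $t$ and 0 elsewhere reproduces the univariate refit of the
phenotype on base $t$'s predictions. Since the package evaluates a score's
Nagelkerke $R^2$ by exactly such a univariate logistic refit, and the meta
logistic fit maximises the likelihood over the larger class, the stacked
model's validation Nagelkerke $R^2$ is $\geq$ every base model's. For
quantitative traits the analogous fact is that OLS fitted values maximise
squared correlation over linear combinations of the columns. The test
suite asserts this dominance at tolerance 1e-9 (the slack covers IRLS
convergence, not the inequality itself). On the *test* partition the
inequality is not guaranteed — that is an empirical claim, checked as a
20-replicate stochastic property instead.

## Base networks

Each hidden layer is affine → batch normalisation (optional) → Leaky ReLU
($\alpha = 0.01$) → dropout (optional, rate 0.5); the output is a single
unit, logistic for binary traits. Hidden widths form an integer-division
chain: layer $l$ has $\lfloor w_{l-1} / d_l \rfloor$ units with divisors
$d_l \in \{1,\dots,4\}$ and depth up to 4. A chain that reaches width 0
makes the spec invalid; grid search skips it rather than clamping, so the
searched family stays well defined. Depth 0 (purely affine) is admitted as
a degenerate case; trained with the binary head it must — and, per the
test suite, does — approach plain logistic regression, which pins the
whole training loop to an independent oracle.

Training minimises binary cross-entropy or mean squared error with Adam
(learning rate 1e-3, $\beta_1 = 0.9$, $\beta_2 = 0.999$). Batches: full
batch below 512 training samples, minibatches of 256 otherwise. Early
stopping watches the validation loss with patience 10 and minimum
improvement 1e-5 over at most 500 epochs, then restores the
best-validation weights; the restored weights also produce the validation
predictions the meta-learner trains on. All constants sit on `nn_spec()`
and are deliberately explicit because reproducibility, not peak accuracy,
is the design goal: a fixed spec seed fixes initialisation (He-scaled
normals), shuffling and dropout masks, making training bit-reproducible.

Inputs are standardised per SNP by training mean and standard deviation
after training-mean imputation of missing dosages; the constants are
stored on the model, so inference never recomputes them. A zero-variance
column gets unit scale rather than NaNs.

## Grid search and the threshold ladder

`nn_grid()` spans depth × divisor × regularisation-on/off;
the per-threshold search scores each candidate on the validation partition
(Nagelkerke $R^2$ or squared correlation) and breaks exact ties toward
fewer parameters, then earlier grid order. The default ladder
`5e-2, 5e-3, 5e-4, 5e-5, 5e-6, 5e-8` spans the range within which
threshold-based scores are usually reported; it is fully configurable, and
thresholds selecting zero variants are dropped with a warning (at least
two must survive). Because the ladder is decreasing the input sets are
nested, which the tests assert.

## GWAS, baselines and evaluation

The split is 10% test, then 20% of the remainder validation (72/18/10
overall), stratified by case status for binary traits. Association is
univariate with intercept: closed-form least squares with $t$ p-values
($n-2$ df) for quantitative traits; logistic regression by Newton
iteration to gradient norm < 1e-8 with Wald p-values for binary ones.
Degenerate fits — zero dosage variance, non-convergence, or a fitted
per-allele log-odds beyond ±10 (taken as quasi-separation) — are flagged
and reported as beta 0, p 1 rather than propagating divergence. Thresholds
apply strictly (`p < p_t`), consistent with the genome-wide convention
that 5e-8 itself is excluded.

Clumping is the standard greedy rule: visit variants by ascending p (ties:
chromosome, position, vid), retain the best, remove unprocessed
same-chromosome variants strictly within 250 kb whose dosage $r^2 \geq
0.1$ computed on the training partition — no external LD panel, since the
score is built and applied in-cohort. P+T applies `p < 5e-8` after
clumping and scores with unaltered GWAS betas. The threshold search clumps
once (not per threshold) and picks the threshold maximising the validation
metric over a default grid of 25 log-spaced points in [5e-8, 1]; a dense
arithmetic grid is supported but adds nothing at these problem sizes.
Missing dosages contribute `2 × freq` (the training mean) times the
effect; allele mismatches between statistics and genotypes flip the effect
sign when the pair is reversed or strand-complemented and are an error
otherwise.

Evaluation: ROC AUC is the rank/Mann–Whitney form with ties counted ½.
Nagelkerke $R^2$ refits a univariate logistic model of outcome on score,
which makes the metric well defined for any scoring method and invariant
to increasing affine transformations; perfect separation caps at 1.
Quantitative $R^2$ is squared Pearson correlation, so affine
miscalibration is not penalised — the PRS convention.

## The simulator

`sim_genotypes()` draws each gamete from a Gaussian copula: latent
liabilities follow an AR(1) process with correlation `within_block_r`
inside contiguous blocks (independent across blocks), thresholded at
`qnorm(maf)`; the dosage is the sum of two independent gametes. Block $k$
starts at $1 + k \cdot 10^6$ bp with 1 kb spacing, so distinct blocks are
> 250 kb apart and the clumping window is meaningful. This emulates the
two features downstream code actually consumes — tunable within-block
$r^2$ and hard-call dosages at chosen allele frequencies — and nothing
else: no realistic human LD maps, no ancestry structure, no imputation
error. Passing tests therefore show the estimator behaves as designed
under its own assumptions, not that it attains any particular accuracy on
real cohorts.

`sim_phenotype()` builds the genetic score from additive terms plus
pairwise products of *centred* dosages, so interaction terms are
near-orthogonal to marginal effects and essentially invisible to marginal
GWAS unless the interacting SNPs also carry additive tags — the
construction needed to study non-linear advantage honestly. Environmental
noise is residualised against the genetic score and rescaled so the
realised variance ratio equals the target $h^2$ exactly on the sample;
binary traits threshold the liability at its empirical $1 -$ prevalence
quantile.

Two packaged benchmark studies fix the regimes of interest once:
`sim_split_signal_study()` (five strong causals at 4% of variance each,
fifty one-per-block weak causals at 0.4% each, $h^2 = 0.4$, so weak-SNP
p-values land around 1e-4–5e-2 at n = 4000) and `sim_epistatic_study()`
(ten cross-block product pairs at 3% each, weak additive tags at 0.5%).
The effect shares were chosen from the power calculation
$\chi^2 \approx n\,\rho^2$ so that each tier lands in its intended
significance band, and are not tuned thereafter.

## Problem sizes and reproducibility

The test suite and acceptance script run at desk scale by choice:
n = 4000 with 150–300 variants for the stochastic stacking properties
(20 replicates each), n = 1000 × 500 variants × 20 replicates for null
GWAS calibration, n = 5000 for heritability recovery, exhaustive sweeps to
50 samples for the Hardy–Weinberg exact test and 200 random instances for
the clumping oracle. One master seed fans out to stage seeds through a
fixed affine-modular scheme (`stage_seed`), keeping every derived seed a
valid 32-bit integer; the command-line layer writes a provenance record
(resolved config plus input digests, no timestamps) so identical runs are
byte-identical.

## Known limitations

* Validation reuse: the same validation partition drives early stopping,
  architecture selection *and* the meta-learner, mirroring the two-level
  design but making the stacked validation metric optimistic; only
  test-partition numbers should be quoted.
* The binary phenotype convention in `.fam` files (1/2 recoded to 0/1, −9
  missing) is inferred from the observed values; a genuinely quantitative
  trait taking only those values would be misread.
* Hard-call genotypes only — no dosage/BGEN input; PLINK-1, not PLINK-2.
* The HWE filter pools cases and controls by default (`controls_only`
  is available); whether the frequency filter should use counted-allele
  rather than minor-allele frequency is resolved in favour of MAF.
* Base learners are all feed-forward networks; heterogeneous ensembles
  and penalised stacking over clumping hyper-parameters are out of scope.
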