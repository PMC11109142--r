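# snprs — stacked neural-network polygenic risk scores

Polygenic risk scores (PRS) summarise an individual's genetic liability to a
trait as a weighted sum of trait-associated allele counts,
`PRS_i = Σ_j X_ij b̂_j`, with weights from GWAS summary statistics. The
weights are taken from SNPs passing a single p-value threshold, so a linear
PRS commits twice: to one significance cutoff, and to additivity. Both
commitments lose information when causal signal is spread across
significance tiers or acts through non-additive (epistatic) combinations.

`snprs` implements a stacked alternative. For a ladder of p-value thresholds
`p_1 > p_2 > … > p_T`, the SNP sets `Z_1 ⊇ Z_2 ⊇ … ⊇ Z_T` passing each
threshold in a training-partition GWAS feed `T` feed-forward neural networks
`ĥ_t` (Leaky-ReLU hidden layers, logistic output for case/control traits,
architecture chosen by grid search). A linear meta-learner `ĥ′`, fitted on
the networks' held-out validation predictions, combines them into the final
score

    Ĥ(Z_1:T) = ĥ′( ĥ_1(Z_1), ĥ_2(Z_2), …, ĥ_T(Z_T) )

so no single threshold has to be right, and the non-linear bases can exploit
variant combinations a linear score cannot. The package is aimed at
statistical-genetics researchers who want to study this estimator end to
end without access to biobank-scale cohorts: a built-in simulator generates
LD-blocked genotypes with additive, epistatic or mixed architectures at
exact target heritability.

The package covers the full workflow:

* **I/O** — PLINK-1 binary genotypes (`read_plink`/`write_plink`) and
  tab-separated GWAS summary statistics (`read_sumstats`/`write_sumstats`).
* **Simulation** — `sim_genotypes`, `sim_phenotype`, `true_effects`, plus
  two ready-made benchmark studies (`sim_split_signal_study`,
  `sim_epistatic_study`).
* **Quality control** — `run_qc`: missing call rate > 0.05, minor allele
  frequency < 0.01, Hardy–Weinberg exact test p < 1e-10 (`hwe_exact_p`),
  strand-ambiguous SNPs, position duplicates, imputation INFO < 0.7.
* **GWAS** — stratified 9:1 then 8:2 train/validation/test split
  (`make_split`), per-SNP linear and logistic association on the training
  partition only (`assoc_quantitative`, `assoc_binary`).
* **Linear baselines** — greedy LD clumping (`clump`, r² ≥ 0.1 within
  250 kb), pruning-and-thresholding at p < 5e-8 (`pt_prs`), and a
  validation-driven threshold search (`prsice_search`).
* **Stacked model** — `snprs()` returns a fitted S3 object with `print`,
  `summary`, `coef`, `predict` and `plot` methods.
* **Evaluation** — ROC AUC, Nagelkerke pseudo-R², squared correlation
  (`roc_auc`, `nagelkerke_r2`, `r_squared`, `evaluate`).
* **Command line** — `inst/exec/snprs` exposes
  `simulate | qc | gwas | score | stack | evaluate` subcommands over the
  same functions, with provenance records for reproducibility.

## Worked example

A simulated quantitative trait (n = 4000, h² = 0.4) whose causal signal is
split between five genome-wide-significant SNPs and fifty sub-threshold
SNPs — the regime stacking is designed for:

```r
library(snprs)
study <- sim_split_signal_study(n_samples = 4000, seed = 1)
fit <- snprs(study$g, study$phenotype, "quantitative",
             thresholds = c(5e-2, 5e-4, 5e-8),
             dnn_grid = list(nn_spec(depth = 1, divisors = 2,
                                     max_epochs = 150)),
             seed = 1)
summary(fit)
#> Stacked neural-network PRS — quantitative trait
#> samples: train 2880 / val 720 / test 400
#>
#>  threshold n_variants depth dropout batchnorm epochs val_metric meta_coef
#>      5e-02         82     1   FALSE     FALSE     30     0.2736    0.5586
#>      5e-04         30     1   FALSE     FALSE    142     0.2126    0.2095
#>      5e-08          7     1   FALSE     FALSE    150     0.1973    0.3940
#>
#> meta intercept -0.01474 | stacked validation metric 0.3088

evaluate(fit$test_scores, study$phenotype[fit$split$test],
         "quantitative", model = "snprs")
#> evaluation of snprs on test (n = 400)
#>   R2  0.4003
```

Reading the summary: the most liberal threshold (p < 0.05) admits 82 SNPs
and gives the strongest single network (validation R² 0.27); the strict
5e-8 set holds only the 7 genome-wide hits. No single threshold reaches the
stacked model's validation R² of 0.31 — the meta-learner spreads weight
over all three tiers — and on the untouched test partition the stacked
score explains 40% of phenotypic variance, matching the simulated
heritability regime.

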