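Package: snprs
Title: Stacked Neural Network Polygenic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Construction and evaluation of polygenic risk scores (PRS) that
    stack feed-forward neural networks trained on SNP sets selected at a
    ladder of GWAS p-value thresholds, combined by a linear meta-learner.
    Includes PLINK-1 binary genotype input/output, an LD-blocked genotype and
    phenotype simulator with additive and epistatic architectures, the
    standard variant-level quality-control cascade (missingness, minor allele
    frequency, Hardy-Weinberg exact test, ambiguous-SNP removal,
    position-level deduplication, imputation INFO score), training-partition
    GWAS with linear and logistic per-SNP association, linear PRS baselines
    (pruning-and-thresholding with LD clumping, and validation-driven
    threshold search), and evaluation by ROC AUC, Nagelkerke pseudo-R2 and
    squared correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
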