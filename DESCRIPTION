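Package: readconn
Title: Gene-Brain-Behavior Analysis of Specific Reading Comprehension
    Difficulty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for imaging-genetic studies of specific
    (unexpected) reading comprehension difficulty. Implements residualized
    comprehension phenotyping with regression-band group classification
    (UPC/EAC/UGC), classification of READ1 (DCDC2 intron-2 tandem repeat)
    alleles into functional groups with microdeletion handling, carrier
    association testing by contingency analysis and multinomial logistic
    regression with chained-equation multiple imputation and Rubin-rule
    pooling, EIGENSTRAT-style genotype principal components with SNP and
    sample quality control and genomic-inflation diagnostics, resting-state
    fMRI motion censoring and nuisance regression, intrinsic connectivity
    distribution (ICD) mapping by stretched-exponential fits to voxelwise
    correlation survival curves with cluster-extent Monte-Carlo correction,
    and seed-based network definition with genotype-connectivity node
    regressions. A synthetic-data module generates cohorts, genotypes, SNP
    matrices, and 4D BOLD runs with planted effects so that the full pipeline
    is testable without access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
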