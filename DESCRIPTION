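Package: paleoimpute
Title: Imputation Accuracy, Runs of Homozygosity and Relatedness for
    Low-Coverage Ancient Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-imputation analysis toolkit for low-coverage ancient
    genomes. Evaluates genotype-imputation accuracy (non-reference
    concordance, heterozygous false-positive and false-negative rates)
    stratified by minor-allele-frequency tranche, genotype-probability
    threshold and substitution class; scans the genome in sliding windows
    for low-concordance outlier regions; calls runs of homozygosity with
    both a window-scan algorithm and a two-state hidden Markov model and
    fuses the two profiles; post-processes identity-by-descent segment
    tables into pairwise relatedness classifications; and computes
    outgroup f3 statistics with a weighted block jackknife. A synthetic
    data generator produces haplotype panels with linkage disequilibrium,
    truth genotypes with planted autozygous and shared segments, imputed
    callsets under a calibrated error model, and pseudohaploid calls, so
    the whole pipeline can be exercised without access to restricted
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
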