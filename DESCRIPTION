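Package: ordherit
Title: Heritability Dissection for Sex-Limited Ordinal Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variance-component dissection of heritability for ordinal traits
    scored on a small number of categories, with an X-chromosome partition for
    male-limited phenotypes. Provides a seeded cohort simulator (genotypes with
    local linkage disequilibrium, pedigree gene dropping, liability-threshold
    ordinal phenotypes, repeated measures, fertility), PLINK and GCTA GRM file
    interchange, genotype quality control and LD-score computation,
    average-information REML for multi-GRM models (pedigree, autosome + X,
    big K small K, MAF/LD-stratified components), observed-to-liability scale
    conversion for ordinal scores, per-SNP heritability enrichment tests,
    mixed-model association with hemizygous X dosage coding, conditional-joint
    SNP selection from summary statistics, LD score regression for heritability
    and genetic correlation with block-jackknife uncertainty, and linear
    selection-gradient estimation from offspring counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
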