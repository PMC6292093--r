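Package: replicheck
Title: Bayesian Verification of Sequencing Replicate Identity from Allelic Depths
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects mislabeled and contaminated samples among k putative
    sequencing replicates of one individual by computing the posterior
    probability of every partition of the replicates into identical-genotype
    groups ("source vectors"), directly from shallow-depth allelic read
    counts at biallelic sites. Genotype likelihoods use a binomial read
    model with a symmetric sequencing error rate; genotype priors come from
    user-supplied population allele frequencies under Hardy-Weinberg
    equilibrium. No genotype calling, imputation, or phasing is required,
    so the method remains usable at mean depths of 1-6x. Includes VCF
    import of per-sample allelic depths, panel-based allele frequency
    estimation, seeded site sampling with minor-allele-frequency and
    inter-site distance filters, a synthetic-data generator with known
    ground truth (Poisson depths, Hardy-Weinberg genotypes, site-level
    contamination), simulation experiment drivers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
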