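Package: gdblup
Title: Genomic BLUP and REML for Additive and Dominance SNP Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction and variance-component estimation of additive
    and dominance effects under the classical quantitative-genetics partition
    of a genotypic value into breeding value and dominance deviation. Builds
    the additive and dominance SNP coding matrices from allele counts, three
    definitions of genomic additive and dominance relationship matrices
    (expected-variance, observed-mean-diagonal, and correlation normalization),
    genomic BLUP with per-individual reliabilities for training and validation
    individuals via two mathematically identical formulations (a conditional
    expectation form for many markers and a mixed-model-equation form on SNP
    effects for many individuals), restricted maximum likelihood estimation of
    additive, dominance and residual variances by inverse-free EM and
    average-information algorithms, SNP-based heritabilities, and a simulator
    (Hardy-Weinberg founders, Mendelian gene dropping, exact-variance effect
    scaling) for validating the whole stack.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coding.R'
    'grm.R'
    'mme-internal.R'
    'gblup.R'
    'greml.R'
    'simulate.R'
    'io.R'
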