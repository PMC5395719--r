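Package: tmbscape
Title: Panel-Based Tumor Mutational Burden, Microsatellite Instability
    Scoring, and Cohort Landscape Analysis
Version: 0.1.0
Authors@R:
    person("tmbscape", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: tmbscape authors [aut, cre]
Maintainer: tmbscape authors <maintainer@example.org>
Description: Tools for estimating tumor mutational burden (TMB) from
    targeted comprehensive genomic profiling panels. Implements the
    somatic filtering cascade used to separate somatic mutations from
    germline polymorphisms without a matched normal, normalization to
    mutations per megabase of coding territory, a binomial downsampling
    simulation of TMB measurement error as a function of megabases
    sequenced, a principal-component microsatellite instability (MSI)
    score computed from homopolymer repeat-length read distributions,
    log-linear models associating gene and mutation status with TMB
    controlling for disease type, logistic co-occurrence tests, and
    cohort-level landscape summaries with Wilson binomial confidence
    intervals. A synthetic-cohort generator with recorded ground truth
    makes every stage testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    BiocGenerics,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
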