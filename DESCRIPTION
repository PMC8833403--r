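Package: twinprs
Title: Polygenic Risk Scores in Biometric Twin Models of Disease Liability
Version: 0.1.0
Authors@R:
    person("STR", "Methods", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for joint analysis of binary disease outcomes in twin
    cohorts with measured polygenic risk. Implements clumping-and-thresholding
    polygenic risk score (PRS) construction with quality-control filters,
    APOE-region handling and within-array standardization; mixed-effects
    probit regression with zygosity-specific pair-level random variances
    fitted by adaptive Gauss-Hermite quadrature; and an extended ACE
    liability-threshold model in which a measured PRS (and APOE epsilon-4
    count) is split out of the total additive genetic variance, with
    unbounded maximum-likelihood estimation, profile-likelihood confidence
    intervals and Monte-Carlo power analysis. A synthetic twin-cohort
    generator with block-LD genotypes and monozygotic/dizygotic sharing
    supports end-to-end testing without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    optparse
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
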