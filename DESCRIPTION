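Package: combSKAT
Title: Combined Genotype and Haplotype Region-Based Association Tests
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Region-based association testing that combines a genotype-based
    and a haplotype-based sequence kernel association test (SKAT) into two
    omnibus tests: the minimum of the two p-values (MinP-val) and the sum of
    their inverse-normal transforms (SumP-val), each with theoretical
    p-values under a correlated bivariate-normal null. Includes rare-variant
    collapsing, rare-haplotype grouping, permutation of residuals under the
    reduced model for correlation estimation and empirical p-values, a
    Shapiro-Wilk normality gate, a theoretical noncentral chi-squared power
    model, a coalescent-style haplotype-pool simulator with genotype- and
    haplotype-based case-control disease models, and VCF-based readers with
    gene-region mapping.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    mvtnorm,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
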