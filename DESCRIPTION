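Package: cnvaccord
Title: Two-Cohort Copy-Number-Variation Association Testing with a
    Cross-Cohort Accordance Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A case-control association pipeline for copy-number variation
    (CNV) measured on SNP genotyping arrays. Probe intensities are quantile
    normalized and transformed to integer copy-number states (0-4) with a
    hidden Markov model; per-SNP association is tested under loss, gain and
    abnormal hypotheses together with Pearson and Cochran-Armitage trend
    tests; window-based testing aggregates evidence across flanking SNPs;
    and a relative factor (Rf) measures the accordance of association
    patterns between a discovery and a validation cohort. Significance is
    controlled with permutation-based false discovery rates, consecutive
    risk loci are summarized into CNV records, and risk loci are related to
    recombination rates and hotspots. A seeded synthetic-cohort generator
    with embedded ground-truth risk regions supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
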