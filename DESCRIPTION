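Package: sigmark
Title: Mutational Signatures as Markers of Drug Sensitivity in Cancer Cell Lines
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers somatic trinucleotide and small-indel mutation spectra from
    unmatched cancer cell line variant calls by subtracting an ancestry-matched
    germline baseline, extracts mutational signatures by bootstrapped
    non-negative matrix factorization with hierarchical re-extraction and
    catalog matching, and screens binarized signature (or any binary marker)
    exposures for drug-sensitivity associations that replicate across
    independent screening data sets using a two-way randomization test.
    Includes a synthetic-data generator with population structure, planted
    signatures and planted pharmacogenomic effects so the whole pipeline can
    be exercised and calibrated without access to restricted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    ranger,
    pracma,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    GenomicRanges,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
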