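Package: credaf
Title: Allele Frequency Thresholds for Mendelian Variant Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical framework for deciding whether a variant is too
    common in a reference population to cause a Mendelian disease. Computes
    disease-specific maximum credible population allele frequencies from
    genetic-architecture parameters (prevalence, inheritance mode, allelic
    and genetic heterogeneity, penetrance), converts them into maximum
    tolerated allele counts in a finite reference sample via a one-sided
    Poisson bound, and inverts the bound into a per-variant filtering allele
    frequency with popmax aggregation across continental populations.
    Includes a VCF annotation and filtering tool, cohort statistics for
    estimating architecture parameters (case-frequency confidence intervals,
    burden odds ratios by frequency bin, penetrance estimation), and a
    seeded multi-population reference-panel simulator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
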