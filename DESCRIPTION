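Package: svecho
Title: Echoed Induction of Somatic SNVs Around Structural Variant Breakpoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify co-localization of somatic single-nucleotide
    variants (SNVs) with chromosomal structural variant (SV) breakpoints in
    whole-genome sequenced tumors. Implements fixed-width genomic binning with
    moving-average smoothing and local-maximum peak calling, observed versus
    expected SV-proximal SNV enrichment with cohort-level tests, kataegis
    (localized hypermutation) calling from inter-SNV distances, rainfall
    statistics comparing SV-high and SV-low regions, flank-superimposed "echo"
    profiles of SNV density around SV peaks, and the classical statistics the
    analyses rest on (Pearson correlation with t test, Fisher r-to-z
    comparison, Welch t test, least-squares slopes, clock-like signature
    normalization). A synthetic tumor-cohort generator with known ground truth
    (hotspot-clustered SVs, breakpoint-proximal SNV enrichment, planted
    kataegis, age-linked clock-like mutations) makes every stage testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
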