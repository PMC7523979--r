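Package: nitroscan
Title: Selection Scans for Low-Nitrogen Tolerance in Inbred Maize Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genomic regions under directional selection between
    groups of inbred maize lines contrasting for low-nitrogen tolerance.
    Implements the low-N agronomic efficiency (LNAE) index from paired
    optimal-N and low-N yield trials, mixed-model adjusted line means,
    Scott-Knott clustering of line means into contrasting phenotypic groups,
    SNP quality control (call rate, minor allele frequency) and sliding-window
    linkage-disequilibrium pruning, identity-by-state genetic distances with
    principal coordinate analysis, the Evanno delta-K summary for external
    structure runs, a per-SNP Weir-Cockerham fixation-index contrast scan with
    outlier calling, and favorable-allele scoring with phenotype association.
    Includes a synthetic-data generator that emulates the statistical
    structure of an inbred diversity panel for testing and tutorials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
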