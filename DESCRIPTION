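Package: pedsift
Title: Family-Based Tiered Variant Prioritization and Case-Control
    Association for Dominant Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing candidate variants in multiplex
    families under an autosomal-dominant model with reduced penetrance.
    Implements a tiered variant-selection pipeline (impact prefilter,
    within-family segregation with zygosity-state matching, MAF/CADD
    filtering, cross-family consistency exclusion, gene-set
    prioritization), exact two-tailed Fisher association on proband
    carrier counts, carrier-fraction and penetrance summaries,
    onset-age comparisons, KING-robust kinship screening, and a
    pedigree gene-drop simulator that generates fully annotated
    synthetic cohorts (VCF, PED, annotation tables, truth records) for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
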