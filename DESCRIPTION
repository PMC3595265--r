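Package: rdnaconcert
Title: Concerted Evolution Dynamics of rDNA Tandem Repeat Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic simulation and statistical analysis of concerted
    evolution in ribosomal RNA tandem repeat arrays. Models unequal crossing
    over (reciprocal and non-reciprocal), gene conversion and copy-number
    viability selection through the mitotic and meiotic life stages of a
    haploid homothallic ascomycete; types cloned ITS amplicons by in-silico
    PCR-RFLP (restriction-site search, fragment sizing, gel-detectability
    filtering); and analyses replicated clone-count series with chi-square
    goodness-of-fit tests and Fisher's combined probability method. Includes a
    synthetic study-design generator, minimum-cell-division calculators for
    composition changes under constrained or unconstrained array size, and a
    reproduction of the reportable statistics of a published ITS clone-typing
    experiment in Ceratocystis manginecans.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
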