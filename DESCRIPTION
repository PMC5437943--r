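Package: oncotally
Title: Cohort-Scale Somatic Mutation Tabulation, Consensus Calling and
    Gene-Centric Visualization Layouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for cancer-genomics cohort analysis:
    capacity-bounded grouping of whole chromosomes for scatter/gather
    parallelization of variant callers, k-of-n ensemble consensus of
    somatic variant calls, tabulation of MAF and segmented copy-number
    data into gene-by-patient matrices, six-class mutation spectra and
    cohort summaries, generation of gene-centric Circos data bundles and
    oncoprint tables with marker-based molecular-subgroup classification,
    plus a seeded synthetic-cohort generator with planted truth so every
    step is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
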