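Package: medicomb
Title: Compartment-Structured Plant-Microbiome Community Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for compartment-structured plant-microbiome
    experiments (rhizosphere, root endosphere, nodule, leaf), built around
    iterative-subsampling diversity estimation, ordination-based variance
    partitioning (a modified PVCA on NMDS axis scores), permutational
    community tests, paired within-plant effect sizes, core-taxon detection,
    Raup-Crick and co-occurrence null-model inference of community assembly,
    sparse compositional correlation (SparCC) networks, and plasmid to
    chromosome read-depth ratio estimation. Includes a synthetic community
    generator emulating a paired two-soil by three-genotype common-garden
    design with nested nodule colonization, so the full pipeline is testable
    without sequence data.
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
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
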