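Package: recessivescan
Title: Recessive-Defect Variant Discovery from Pedigrees, Whole-Genome
    Variants, and Validation Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for mapping rare recessive defects
    in pedigreed populations, built around the workflow used to resolve
    congenital syndromes in livestock: common-ancestor analysis of affected
    individuals' pedigrees, recessive segregation filtering of multi-sample
    whole-genome variant calls, shared-homozygosity mapping across
    affecteds, exclusion of candidates against external population cohorts,
    annotation-based prioritization, and analytics for validation
    genotyping by sequence pileup and droplet digital PCR (Poisson
    occupancy correction, assay power, germline mosaicism assessment).
    A gene-dropping synthetic-cohort generator produces pedigrees, VCFs,
    pileup tables, and droplet counts with known ground truth so the whole
    pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    igraph,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
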