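Package: hybrisect
Title: Dissecting Hybrid Cultivar Ancestry from Transcriptome-Derived SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect the genomic background of hybrid cultivars
    descended from two progenitor species, using multi-sample SNP panels
    called against a progenitor transcriptome. Re-calls genotypes from
    per-allele read depths with threshold rules, classifies every cultivar
    locus into a 12-way progenitor-origin taxonomy, estimates allele-origin
    proportions under allele-counting and two boundary ("pure parents" /
    "exact parents") models, projects progenitor similarity onto a genetic
    linkage map, and detects enrichment and map clustering of outgroup-derived
    ("out") alleles in one phenotype group versus another. Includes a
    synthetic-panel simulator with ground-truth origin tables for
    parameter-recovery validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
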