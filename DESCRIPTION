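Package: cosegr
Title: Cosegregation Region Scanning and Rare-Variant Filtering for
    Dominant Family Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Candidate-gene discovery for a single family segregating an
    autosomal-dominant trait. Provides a dominant-model cosegregation
    region scan over SNP genotype matrices (regions where some allele is
    carried by every affected and by no unaffected member), a multi-stage
    exome variant filter cascade with a complete audit trail (genotype
    quality control, consequence class, population rarity, cosegregation,
    linked-region membership), a seeded pedigree and genotype simulator
    with Haldane recombination, and reporting utilities that integrate
    damage predictions and developmental brain-expression profiles. All
    user-facing functions take and return tibbles so analyses compose
    with the pipe.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
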