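Package: dnamTraits
Title: DNA Methylation Predictors of Mammalian Life-History Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds and evaluates cytosine-methylation-based predictors of
    species-level life-history traits (maximum life span, gestation time and
    age at sexual maturity) across mammals. Provides probe filtering by
    detection p-value, species- and tissue-level aggregation of beta values,
    elastic-net predictors of log-transformed traits with leave-one-species-out
    and leave-one-clade-out cross-validation, a phylogenetic k-nearest-neighbour
    baseline on patristic distances, trait-scale rules (multiplicative
    life-span correction, mean/SD calibration, nearest-neighbour imputation),
    downstream readouts (sex differences, age association, weight adjustment,
    group contrasts, age acceleration, breed-level aggregation), and a
    phylogenetically structured synthetic-data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
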