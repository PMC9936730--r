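Package: karyoCR
Title: Comparative Single-Gene FISH Karyotype Analysis and Chromosomal
    Rearrangement Inference
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative cytogenetics of Triticeae allopolyploids
    from ordered single-gene FISH marker maps. Converts observed marker maps
    into unsigned permutations over a reference collinearity standard,
    enumerates minimal inversion scenarios (pericentric/paracentric, with an
    explicit centromere token), detects reciprocal and one-way translocations
    from foreign-group marker runs, calls duplications and deletions from
    copy-number deviations, classifies rearrangement complexes as
    species-specific or polymorphic across materials, counts chromosome
    variants from repeat-FISH pattern matrices, and quantifies breakpoint
    reuse across lineages. Includes a karyotype simulator with known ground
    truth so every inference stage is testable, and packaged survey tables
    for Elymus sibiricus, Elymus nutans and Hordeum bogdanii.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
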