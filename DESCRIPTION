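Package: ldftopsis
Title: Linear Diophantine Fuzzy Copula Aggregation and Extended TOPSIS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multi-criteria group decision analysis under linear
    Diophantine fuzzy (LDF) information. Provides the LDF number type with its
    reference-parameter validity constraints, five Archimedean copula generator
    families with extended copula/co-copula operational laws, weighted copula
    aggregation operators (LDFWCA and its ordered and hybrid variants),
    generalized distance and entropy measures, and a three-phase extended
    TOPSIS algorithm that derives unknown expert and criterion weights from
    closeness indices and entropy before ranking alternatives. Includes an
    embedded EEG-classifier selection worked example, a seeded random panel
    generator, and JSON/CSV panel interchange.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
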