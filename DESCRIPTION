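Package: barcodegauge
Title: Evaluation of DNA Barcode Markers for Species Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate plastid DNA barcode markers (rbcL, matK,
    trnH-psbA and their combinations) for species-level discrimination:
    curation filters for barcode sequence sets, pairwise genetic distances
    (p, Jukes-Cantor, Kimura 2-parameter) under pairwise deletion, the
    100%-identity best-match identification test with per-species success
    rates, multi-marker supermatrix concatenation, neighbor-joining tree
    estimation with nonparametric bootstrap support, species and genus
    monophyly accounting on rooted trees, and a synthetic barcode-family
    simulator (Yule species trees, Kimura substitution model with
    transition bias, spacer-like indels) so every stage of the analysis
    can be exercised on data generated in code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
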