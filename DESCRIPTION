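Package: delftiMS
Title: Mass Spectrometry Discovery Chain for Acylated Siderophore Analogs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dereplicating acylated lipopeptide siderophore analogs
    from tandem mass spectrometry data, modelled on the delftibactin system of
    Delftia. Provides exact monoisotopic mass and adduct arithmetic over
    elemental formulas, lipid-tail inference from precursor mass differences
    against a peptide scaffold, theoretical b/y fragment-ladder generation and
    spectrum annotation for macrolactam lipopeptides, modified-cosine molecular
    networking, iron-limitation differential feature analysis, metal-adduct
    screening for apo/holo complex formation, and a seeded synthetic LC-MS/MS
    data generator so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
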