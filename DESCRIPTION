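Package: halopha
Title: PHA Synthase Paralog Surveys, RT-qPCR Quantification and PHBV
    Composition in Haloarchaea
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for studying polyhydroxyalkanoate (PHA)
    synthase (PhaC) paralogs in halophilic archaea. Provides a
    comparative-genomics survey that aligns reference PhaC/PhaE proteins
    against proteome collections, classifies homologs by percent identity
    with a strong/weak threshold, measures query coverage and tallies
    paralog occurrence per species; phaE-phaC gene-neighborhood
    colocalization inference by coordinate distance; RT-qPCR relative and
    absolute expression quantification by the Pfaffl method with
    standard-curve amplification efficiencies and single or
    geometric-mean reference-gene normalization; poly(3-hydroxybutyrate-
    co-3-hydroxyvalerate) monomer composition from 1H-NMR methine peak
    integrals, PHA mass content, and medium elemental C/N/P ratios.
    Includes deterministic synthetic-data generators that plant known
    homolog identities, gene distances, fold changes and monomer
    fractions for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
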