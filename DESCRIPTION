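Package: musicodon
Title: Codon-Level DNA Sonification and Music-Theoretic Sequence Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates coding sequences into musical scores (one codon per
    3/4 bar, each codon with a fixed melodic formula and rhythm), and compares
    sonified voices polyphonically through unison, perfect-fourth and
    perfect-fifth consonance statistics, best-offset ensemble search,
    permutation significance, and canon (melodic imitation) detection, as a
    screen for evolutionary conservation and protein-protein interaction.
    Also provides the companion analyses of an interactome study: yeast
    two-hybrid confidence-category (PBS) filtering, selected-interacting-domain
    (SID) alignment identity and protective-epitope coverage, and
    size-exclusion-chromatography calibration with oligomer-state inference.
    Scores export to MusicXML, standard MIDI and a lossless token format.
    Seeded generators supply synthetic coding sequences, paralog pairs,
    canons, interaction tables and calibration standards for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
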