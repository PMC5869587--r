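Package: rhebanchor
Title: Membrane-Attachment Architecture Analysis for Rheb GTPases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects membrane-attachment devices on Ras-family GTPase protein
    sequences (C-terminal CaaX prenylation boxes, N-terminal myristoylation and
    S-palmitoylation candidates scored by deterministic ensemble voters,
    hydropathy-based transmembrane extensions, tryptophan-rich C-terminal
    motifs, and N-terminal PX/FYVE phosphoinositide-binding domains), combines
    them into a twelve-class membrane-anchor architecture taxonomy, and maps
    gains and losses of the resulting protein forms onto rooted species
    phylogenies by Dollo and Fitch parsimony. Ships a seeded synthetic-sequence
    and tip-state generator that plants each architecture with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    phangorn,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
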