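Package: tetraltr
Title: Mining, Classification and Age Dating of LTR Retrotransposons in
    Compact Fish Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for de novo discovery of full-length LTR
    retrotransposons in compact genomes: paired terminal-repeat detection by
    seeded ungapped extension, ORF and retroviral domain annotation
    (Gag/Pol/Env; RT/RH/INT with DDE-triad localisation), greedy identity
    clustering with consensus building and family/superfamily assignment
    against a reference panel, Kimura two-parameter divergence with
    molecular-clock insertion dating (t = K/2r), and per-family insertion-age
    landscapes.  A synthetic-genome generator implants elements of known
    family geometry, copy class and age so that every stage can be verified
    against ground truth at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
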