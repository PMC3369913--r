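Package: hoxrates
Title: Fossil-Calibrated Divergence Rates of Hox Homeobox Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating absolute divergence rates of homeobox
    (Hox) sequence fragments from uncorrected p-distances and fossil
    calibration ages, and for comparing insect against non-insect rate
    samples with a tie-aware Mann-Whitney U test. Includes
    neighbor-joining tree construction with distance-based Hox family
    assignment and explicit Scr/Antp ambiguity diagnostics, in-silico
    validation of degenerate PCR primers (IUPAC matching, degeneracy,
    amplicon prediction, Wallace-rule melting temperatures), and a
    seeded star-phylogeny sequence simulator for parameter-recovery and
    power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
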