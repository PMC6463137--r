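Package: numcodon
Title: Numerical Genetic-Code Tables, Codon-Amino Translation and
    Translation-Machine Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the genetic code in a numerical codon
    notation in which the four RNA bases are written as digits (1 = U, 2 = C,
    3 = A, 4 = G; 1 = T for DNA), so every codon is a three-digit number.
    Builds the universal 64-codon table and its two hypothesized evolutionary
    precursors (the 4-codon GNC code and the 16-codon SNS code), translates
    numerical codon sequences to amino-acid strings (with the stop letters J,
    X, Z for opal, ochre and amber), reverse-translates amino-acid strings
    with exact arbitrary-precision counting and deterministic enumeration of
    all synonymous codon sequences, generates seeded random codon sequences
    (optionally constrained to open-reading-frame structure), and runs a
    discrete-event simulator of the three evolutionary stages of the
    translation machine with charging, codon binding, peptide-bond and
    termination events recorded as traces.  Includes code-robustness
    summaries (synonymous single-substitution profiles per codon position),
    CSV/FASTA/JSONL input and output, and a bundled plain-text corpus of
    worked examples used as regression fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
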