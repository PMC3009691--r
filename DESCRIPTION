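Package: enzpat
Title: Deterministic Enzyme-Specific Sequence Patterns for EC Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives deterministic, enzyme-function-specific sequence
    patterns (PROSITE syntax) from an annotated protein database.
    Enzyme entries are classified, deduplicated, compared all-vs-all with
    a local aligner, clustered by complete linkage on E-value distances,
    and the conserved columns of per-cluster multiple alignments are
    converted into sequence patterns. Patterns are verified against the
    full database with an EC-number-aware true/false-positive calculus,
    filtered into strict and loose pattern sets by specificity, and used
    to annotate query proteomes against a standard-of-truth EC list.
    Includes a synthetic protein-family generator so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
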