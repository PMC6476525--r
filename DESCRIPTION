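Package: apsutr
Title: AU-Rich Proximal UTR Sequence (APS) Classification and Reporter Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies mRNA 3' UTRs for AU-rich proximal sequences (APS): an AU
    base content exceeding fifty percent in the first hundred bases of a 3' UTR
    that is itself at least three hundred bases long, a cis-regulatory feature
    associated with elevated translation in macrophages. Provides transcript and
    UTR coordinate handling (1-based inclusive, mRNA space), sliding-window AU
    composition profiles, in-silico construction of mutant reporter UTRs
    (truncations, insertions, fusions, deletions) with provenance logging, an
    AU-rich element (AUUUA) pentamer scan, Needleman-Wunsch global alignment and
    cross-species conserved-block detection, exact-match in-silico PCR for
    amplicon size prediction, quantification arithmetic for qPCR (2^-ddCt),
    UTR-reporter and plasmid-derived fold changes and western band ratios,
    14-fraction polysome-profile normalization and shift summaries, and seeded
    synthetic-data generators that make every stage testable offline.
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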