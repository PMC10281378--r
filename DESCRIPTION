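Package: ehcastools
Title: Desk-Scale Analysis Pipeline for Characterizing a Compact Cas9 Nuclease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the computational stages used to characterize a compact
    type II-C CRISPR-Cas9 nuclease: PAM-depletion screen statistics (per-variant
    log2 fold-change, threshold selection, sequence-logo matrices), in vitro
    cleavage-screen normalization and consensus calling, double-strand-break
    cut-site inference from adapter-ligated fragment termini, CRISPR
    repeat-spacer array and anti-repeat (tracrRNA candidate) mining with sgRNA
    scaffold assembly and PAM-constrained target enumeration, and amplicon
    INDEL quantification with allele labelling. Every input class is backed by
    a seeded synthetic-data generator carrying ground truth, so each analysis
    stage has an end-to-end recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
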