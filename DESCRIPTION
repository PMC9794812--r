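Package: dna6ma
Title: Single-Base Calling of 6mA DNA Methylation from Nuclease
    Cleavage and Stop Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects N6-methyladenine (6mA) sites at single-base
    resolution from the terminal positions of sequenced DNA fragments
    produced by antibody-guided nuclease digestion. Endonuclease
    cleavage at an antibody-bound 6mA leaves two abutting fragment
    termini flanking the methylated adenine; 5'->3' exonuclease
    digestion stalls at the 6mA so the modified adenine becomes the
    fragment's 5'-terminal base. Per-position terminal-event counts are
    tested against a binomial random-shear null with multiple-testing
    correction and coverage gating. Includes a simulator of the
    enzymatic readouts (random shearing, cleavage, exonuclease stops,
    whole-genome-amplified null, hemi-methylated duplexes, spike-in
    mixtures) so sensitivity and false-discovery control are testable
    without sequencing data, plus downstream annotation: sequence-context
    summaries, full versus hemi-methylation of palindromic motifs,
    TSS-distance periodicity, and interval overlaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
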