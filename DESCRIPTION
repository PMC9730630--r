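Package: rnaeditr
Title: Exome-Wide A-to-I RNA Editing Detection and Profiling from Paired
    DNA/RNA Base Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects putative adenosine-to-inosine (A-to-I) RNA editing
    sites from paired tumor/normal DNA and RNA per-site base counts using a
    multi-stage filter cascade (depth, variant allele frequency, base
    quality, strand bias, germline SNP and somatic SNV subtraction, simple
    repeat exclusion, Alu-stratified thresholds, flanking-sequence
    uniqueness), classifies mismatches strand-aware, annotates recoding
    consequences, and profiles cohorts: recurrence and mismatch spectra,
    per-patient over-/under-editing, sequence-context motifs, and
    associations between editing burden and ADAR expression. Includes a
    fully seeded synthetic cohort generator with known ground truth and a
    chromatogram peak-height quantifier for Sanger-based editing levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
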