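Package: retrobench
Title: Retrotransposon Integrity and Assembly Quality Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structural annotation of full-length LTR retrotransposons and
    solo-LTRs, Kimura 2-parameter insertion dating, target-site-duplication
    accounting, junction-anchored tracking of elements between assembly
    versions with normalized SNP/N divergence profiles, and a panel of
    assembly quality metrics (Nx and gap statistics, stringent transcript
    completeness, in-silico optical label maps with dynamic-programming
    alignment, scaffold retention and gene confidence classification).  A
    transposable-element-aware genome simulator plants elements, solo-LTRs
    and genes of known age and position, and applies short-read-style
    degradation (gaps in LTRs, collapse of near-identical copies,
    substitutions, fragmentation), so that every analysis stage can be
    exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
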