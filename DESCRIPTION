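Package: baitrank
Title: Bait-Centred Co-Expression Ranking of Candidate Transcription-Factor Targets in Developing Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for prioritising candidate target genes of a
    transcription factor ("bait") from developmental expression data, modelled on
    seed-development studies contrasting seeded and seedless grapevine varieties.
    Provides 75th-percentile normalization and negative-signal filtering for
    intensity matrices, per-stage Welch t-test differential expression with
    fold-change thresholds and Venn set algebra, short time-series model-profile
    clustering with exact-permutation profile significance, multi-dataset
    bait-centred co-expression (Pearson and highest-reciprocal-rank measures)
    combined into a composite concordance x intensity x expression score that
    yields a ranked top-K candidate list, CArG-box (MADS-box binding site)
    promoter motif scanning, and a synthetic-data generator with planted ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
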