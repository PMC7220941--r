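Package: refmatch
Title: Reference-Transcriptome Pattern Matching for Tissue Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies which cell types and stimulation conditions explain a
    bulk tissue expression profile by matching it against a compendium of
    reference transcriptomes. Implements pairwise signal-log-ratio
    differential-expression selection between two sample groups, gene
    co-expression pattern discovery across quantile-normalized reference
    arrays, and cumulative-score quantification of how fully each
    stimulated-versus-control reference comparison reproduces a target gene
    signature. A synthetic-data module generates reference compendia and
    mixed-tissue cohorts with known cell-type signatures and stimulus
    response modules so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
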