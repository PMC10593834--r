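Package: tenoscreen
Title: Transcriptional Signature Reversal Screening for Tendon Stem Cell Rejuvenation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico screening of compound libraries against up/down gene
    expression signatures using the unweighted Kolmogorov-Smirnov running-sum
    enrichment statistic and its reversal convention, as used in
    connectivity-map-style drug repurposing. Builds differential-expression
    signatures from two-group expression matrices (genewise Welch test, fold
    change ranking), scores per-compound transcriptional-change profiles on a
    stemness axis and a tendon axis, and selects the intersection of
    top-ranked candidates. Includes per-gene Pearson evaluation of predicted
    versus empirical change profiles, the Achilles functional index and
    normalized grip-strength formulas for rodent tendon repair studies, and a
    fully seeded synthetic-data generator with planted ground truth for
    benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
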