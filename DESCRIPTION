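Package: m6Aarray
Title: Two-Channel MeRIP Epitranscriptomic Microarray Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-channel N6-methyladenosine (m6A)
    epitranscriptomic microarrays in which an immunoprecipitated (IP,
    methylated) and a supernatant (Sup, unmethylated) RNA fraction are
    hybridized as separate dye channels. Provides spike-in based
    normalization, detection-flag probe selection, per-transcript
    quantification of m6A methylation level, m6A quantity and expression,
    fold-change classification of hyper- and hypomethylation between
    groups, directional reversal-intersection analysis across an
    insult/treatment design, hypergeometric over-representation analysis
    of gene sets, and a synthetic-data generator with planted ground
    truth for validating the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
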