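Package: storyload
Title: Structural Complexity Profiling of Narrative Stimuli for
    Story-Retelling Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Rule-based structural profiling of narrative texts used as
    stimuli in discourse-level aphasia therapy. Extracts four transparent
    features from each story (sentence count, average sentence length,
    complex-sentence ratio, and a comma/conjunction proxy for information
    units), z-normalizes them across a corpus, averages the z-scores into a
    composite structural load score, and assigns Low/Medium/High load blocks
    by tertile. Also provides exploratory produced-information-unit gain
    analysis (per-stimulus gains, Pearson correlations with composite load,
    block and condition means), a deterministic generator of narrative-like
    texts with exact target features for calibration and testing, packaged
    reference fixtures, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
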