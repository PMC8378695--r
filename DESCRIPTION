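Package: menzerath
Title: Menzerath-Altmann Law Analysis with a Memoryless-Source Null Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the Menzerath-Altmann law, the statistical
    regularity by which longer linguistic constructs (words, measured in
    syllables) tend to have shorter constituents (syllables, measured in
    graphemes). Provides an exact and simulated three-symbol memoryless
    ("monkey typing") null model with its closed-form mean-syllable-length
    curve a/m + b, a deterministic sonority-sequencing-principle
    syllabifier driven by a seven-class grapheme sonority table, a corpus
    pipeline (tokenization, filtering, per-word measurement, pooled and
    per-document length profiles, Spearman correlation testing), nonlinear
    least-squares fitting of the Menzerath-Altmann curve
    y = alpha * m^beta * exp(-gamma * m) with extremum detection,
    positional syllable-length profiles, and seeded synthetic-corpus
    generators for validating every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
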