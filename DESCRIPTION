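Package: asragree
Title: Transcription-Based Speech Intelligibility Scoring and Listener-ASR Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcription-based assessment of speech intelligibility
    in Hebrew and English, comparing automatic speech recognition (ASR)
    transcripts with panels of three naive listeners. Implements language-aware
    text normalization (niqqud removal, final-letter folding, Unicode
    punctuation stripping), word-correctness scoring under a phonemic-identity
    rule with an auditable equivalence lexicon, majority-vote listener scoring,
    point-by-point listener-ASR agreement for single words, minimum
    edit-distance sentence scoring with ASR-success rates, and the statistical
    layer used in intelligibility studies: Pearson correlations, unbalanced
    two-way ANOVA with partial eta squared, split-plot (mixed) ANOVA,
    estimated-marginal-mean pairwise contrasts with Tukey-Kramer adjustment
    (from raw data or from published cell summaries), subgroup regressions with
    Holm-Bonferroni correction, and a skewness/kurtosis normality screen. A
    synthetic study generator emulates the three-listeners-plus-ASR design so
    the full pipeline runs end to end without confidential recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    purrr,
    rlang,
    stringr,
    jsonlite,
    stats,
    utils,
    car,
    e1071
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse,
    withr
Config/testthat/edition: 3
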