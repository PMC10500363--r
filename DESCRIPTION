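Package: pemread
Title: Readability Assessment of Patient Education Materials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores plain-text patient education materials (PEMs) with four
    traditional readability measures (Flesch-Kincaid grade level, Gunning fog
    index, SMOG, and Dale-Chall), forms per-document composite grade levels,
    quantifies inter-measure agreement with Fleiss kappa under several grade
    binning schemes, and compares readability across document source and topic
    categories with a nonparametric battery (Shapiro-Wilk gate, one-sample
    Wilcoxon against the recommended eighth-grade level, Kruskal-Wallis and
    Bonferroni-corrected pairwise Mann-Whitney tests). Includes a seeded
    synthetic-corpus generator with controllable sentence-length,
    syllable, and hard-word distributions so the full pipeline can be
    exercised and calibrated without access to any crawled collection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
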