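Package: dstsent
Title: Dempster-Shafer Fusion of Sentiment Classifiers with Epidemiological
    Contrasts for Social-Media Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-classifier sentiment analysis of short
    social-media posts and for the epidemiological analysis of the resulting
    labels. Combines the probability outputs of several three-class
    (negative/neutral/positive) sentiment classifiers through
    Dempster-Shafer belief-function theory (basic belief assignments,
    Dempster's orthogonal sum with conflict normalisation, maximum-belief
    decisions), evaluates single and fused classifiers (confusion matrices,
    per-class sensitivity/precision/accuracy/F1, Cohen's kappa, ensemble
    sweeps), and provides the statistical layer of a two-period
    infodemiology study: sentiment-share tables, 2x2 odds ratios with Wald
    intervals, two-proportion chi-square tests, before/after-midnight
    temporal contrasts, and chi-square power and sample-size calculations.
    A seeded simulator generates tweet-like corpora and noisy classifier
    ensembles with known structure so the whole pipeline runs without any
    external data or model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
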