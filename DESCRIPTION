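Package: metalag
Title: Trial-History Decoding of Prospective Metacognitive Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how recent trial history (task correctness,
    stimulus awareness and response confidence on preceding trials) predicts
    prospective metacognitive decisions in psychophysical experiments.
    Provides a calibrated synthetic trial-sequence generator with known
    lagged logistic weights for parameter-recovery testing, validated CSV
    trial-table input/output with participant-exclusion rules, lag-k
    shuffle-split cross-validated logistic decoding scored by ROC AUC with
    independently shuffled permutation nulls and sign-flip group inference,
    odds-ratio attribution of decoder coefficients, phi-coefficient
    diagnostics, conditional-probability univariate summaries, type-1 and
    type-2 (meta-d') signal-detection estimation on the awareness by
    prospective-decision grid, and cross-experiment transfer decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
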