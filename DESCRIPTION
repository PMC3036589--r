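Package: climhull
Title: Rule-Based Climate Envelopes and Audited Maximum-Entropy Climate Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for invasion-risk climate matching built around two
    contrasting approaches: a rule-based monthly climate envelope (a minimum
    convex polygon in temperature by log10-precipitation space with
    hibernation and aestivation exclusion of inactive months) and a compact,
    auditable presence-background maximum-entropy model with L1
    regularization. Includes the audit machinery needed to evaluate either:
    AICc-based regularization selection with parameter counting,
    minimum-training-presence thresholds, rank-based AUC with replicated
    holdout cross-validation, permutation importance, derivation of the 19
    bioclimatic variables with a pairwise collinearity summary, multivariate
    environmental similarity surfaces (MESS) for novel-climate masking, a
    locality-subsampling sensitivity experiment, and a four-screen model
    evaluation framework (native-range inclusion, minimum training presence,
    overfitting, eco-plausibility). A seeded synthetic-world generator
    (monsoonal climate fields, a virtual species with known fundamental
    climate space, coastally biased and contaminated locality sampling)
    makes the whole pipeline testable without external climate data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
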