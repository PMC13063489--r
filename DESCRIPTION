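Package: vbpricer
Title: Shortcut Algorithms for Value-Based Pricing of Pharmaceuticals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for threshold-based value-based pricing (VBP) of drugs from
    trial-period evidence. Implements a multi-endpoint incremental
    cost-effectiveness ratio (ICER) decomposition with severity-weighted
    clinical events, a closed-form solver for the price at which the ICER
    equals a willingness-to-pay threshold, checkers for the algebraic
    cancellation conditions under which downstream savings and survival
    (life-extension) costs drop out of the pricing condition, a post-trial
    extrapolation engine based on proportional scaling factors with
    admissible-deviation analysis, and a decision procedure that reports when
    extrapolation beyond the trial period is unnecessary for the implied
    price. Scenario configurations are read from YAML, per-period profiles
    from CSV, and reports are emitted as tidy tibbles or JSON.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
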