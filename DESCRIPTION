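Package: danpv
Title: Hybrid DEMATEL-ANP-VIKOR Evaluation of Community Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the DANP-V hybrid multi-criteria decision analysis
    pipeline for evaluating community environments: Fuzzy Delphi screening of
    candidate criteria from paired conservative/optimistic expert ratings,
    DEMATEL total-influence analysis with causal profiles and the influential
    network relation map (INRM), DEMATEL-based ANP (DANP) influential weights
    from the limit supermatrix, and a modified VIKOR aspiration-gap evaluation
    that integrates resident and expert satisfaction panels. Ships a community
    case study as a printed-value fixture and synthetic questionnaire
    generators so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
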