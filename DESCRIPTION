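Package: allonurse
Title: Decision Rules of Reciprocal Allonursing from Behavioral Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test the direct reciprocity, generalized reciprocity and
    kin discrimination decision rules of allonursing (a lactating female
    nursing another mother's offspring) from behavioral event logs. Scores
    solicitations into bouts, rejections and attempts; aggregates ordered-dyad
    help counts; computes the reciprocal allonursing frequency index (RAFI)
    for unordered dyads; builds dominance hierarchies with Landau's linearity
    index; fits the mixed-effects count, likelihood-of-allonursing, RAFI and
    latency models with a diagnostic battery (outliers, dfbetas, Cook's d,
    VIF, overdispersion); pools per-group effects by fixed-effect
    inverse-variance meta-analysis with heterogeneity statistics; and
    simulates allonursing event streams under parameterized decision rules so
    that every stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    MASS,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    car,
    withr
Config/testthat/edition: 3
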