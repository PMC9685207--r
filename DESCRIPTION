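Package: pdxpower
Title: Power Analysis and Study Design for Patient-Derived Xenograft
    Drug-Response Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing preclinical drug-response studies in
    patient-derived xenograft (PDX) mouse models, with emphasis on the
    single-mouse ("1x1x1") design.  Implements a log-linear mixed-effects
    model of tumor growth with mouse-level random intercepts and slopes,
    a synthetic-trajectory simulator, model fitting and Wald testing of
    the treatment-by-day interaction, a closed-form power calculator for
    the two-group slope-difference test, Monte-Carlo power estimation,
    sample-size inversion for a target power, retrospective power for
    completed experiments, and condition-grid exploration of effect size,
    inter-mouse variation, measurement frequency and follow-up duration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
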