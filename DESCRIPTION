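Package: medialknee
Title: Medial Tibiofemoral Contact Mechanics and Lifetime Cartilage
    Failure Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Desk-side computational chain for estimating medial knee
    cartilage loading and lifetime failure risk from per-trial gait
    features.  Implements an elastic-foundation (bed-of-springs) contact
    model of the medial tibiofemoral compartment with a nonlinear
    logarithmic spring law, a Weibull cumulative-damage model of cartilage
    fatigue with a competing biological repair process, scalar gait
    feature computations (stance detection from vertical ground reaction
    force, zero-lag Butterworth filtering, foot progression angle from the
    centre-of-pressure path, daily loading cycles, cumulative load), a
    synthetic repeated-measures gait cohort generator, and a
    mixed-effects comparison stage with paired effect sizes for
    between-condition contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    emmeans,
    lme4,
    lmerTest,
    pracma,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
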