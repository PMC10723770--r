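Package: recrin
Title: Recruitment-to-Inflation Ratio Analysis from Decremental PEEP Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes lung recruitability indices from sequential end-expiratory
    lung volume (EELV) measurements acquired during a decremental positive
    end-expiratory pressure (PEEP) trial in mechanically ventilated patients
    with acute respiratory distress syndrome. Implements the recruited-volume
    decomposition (PEEP volume into predicted inflation and recruited volume),
    the recruitment-to-inflation (R/I) ratio both globally and within narrow
    PEEP ranges, functional residual capacity from a single-breath
    derecruitment maneuver, dynamic/static/total lung strain, an
    origin-constrained quadratic model of R/I versus PEEP with chi-square
    goodness-of-fit gating and implausibility flagging, cohort descriptive
    statistics and strain-change correlation endpoints, eligibility screening
    (intrinsic PEEP, airway opening pressure from a low-flow inflation curve),
    and a synthetic-patient generator with analytic ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tibble,
    dplyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
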