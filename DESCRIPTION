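Package: colocea
Title: Cost-Effectiveness of Follow-Up Colonoscopy via a Partially Observed Markov Cohort Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort-level partially observed Markov model of colorectal
    neoplasia for evaluating the cost-effectiveness of follow-up (surveillance)
    colonoscopy. Implements an adenoma/colorectal-cancer natural-history
    transition kernel with age-dependent adenoma appearance, size-dependent
    colonoscopy sensitivity with polypectomy and symptom-triggered diagnosis,
    stage-specific breakpoint (two-piece exponential) cancer survival with
    least-squares fitting, a polynomial all-cause mortality model, discounted
    cost and quality-adjusted life-year accounting, and incremental
    cost-effectiveness optimization of the follow-up interval by screening age
    and screening finding. An individual-level microsimulation oracle and
    synthetic life-table/survival-curve generators support validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
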