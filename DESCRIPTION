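Package: excea
Title: Cost-Utility Modelling of Supervised Exercise After Endometrial Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort cost-utility model comparing a 12-week supervised
    exercise programme with standard care for survivors of early-stage
    endometrial cancer, from the Australian health-system perspective. Six
    mutually exclusive health states (no cardiovascular disease, post-stroke,
    post-coronary heart disease, post-heart failure, post-cancer recurrence,
    death) are simulated over annual cycles with age-dependent background
    mortality, half-cycle correction and 5% discounting. Parameters are loaded
    from a tabulated registry, calibrated to samplable distributions from
    published means and 95% confidence intervals, and propagated through
    deterministic base-case analysis, probabilistic sensitivity analysis,
    cost-effectiveness acceptability curves, one-way (tornado) sensitivity
    analysis, time-horizon sweeps and an extended-supervision scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
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
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
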