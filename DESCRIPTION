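Package: sdtms
Title: Strength-Duration Analysis of Pulse-Width-Controllable TMS Excitability Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cortical axonal excitability from transcranial magnetic
    stimulation (TMS) experiments that vary pulse width. Models the induced
    electric-field pulse and the first-order neural membrane response to obtain
    a depolarization factor, fits Boltzmann sigmoid input-output curves with
    session-fixed asymptotes to motor evoked potential amplitudes, inverts them
    to resting motor thresholds, estimates rheobase and the strength-duration
    time constant by normalized least squares across pulse widths (individual
    and shared-time-constant modes), and analyses drug effects in a crossover
    design with linear mixed-effects models. A trial-level synthetic study
    generator emulating the experimental design supports parameter-recovery
    testing of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmerTest,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
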