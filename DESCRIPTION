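Package: bbisim
Title: Performance Modelling of Closed-Loop Brain-to-Brain Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the information throughput of a closed-loop
    brain-to-brain interface (BBI), the coupling of an EEG brain-computer
    interface (BCI) with a neurostimulation computer-brain interface (CBI).
    Implements the Wolpaw information transfer rate (ITR) in bits per trial
    and bits per minute, a stochastic and closed-form model of the CBI
    stimulation cycle (latency, Bernoulli delivery failure, bounded retries,
    timeout cutoff), effective-ITR computation for the closed loop by
    renewal-reward analysis, full latency x failure-rate x timeout parameter
    sweeps with hypothesis checks, and balanced repeated-measures ANOVA with
    Greenhouse-Geisser, Huynh-Feldt and lower-bound sphericity corrections
    plus Tukey HSD post hoc tests. Includes a command-line interface for
    reproducible batch runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
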