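Package: tanda
Title: Striatal Cholinergic-Dopamine Interaction Model and Pause-Gated
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rate-based model of the striatal tonically active neuron (TAN)
    population and its bidirectional coupling with striatal dopamine release.
    Simulates the thalamically evoked burst-pause response of cholinergic
    interneurons, the reward-prediction-error-dependent phasic dopamine
    excursion that is gated by the TAN pause, and pharmacological
    (sulpiride, cocaine, h-current blockade), dopamine-deficiency and
    levodopa scenarios. Includes the corticostriatal weight-update rule
    driven by the time-integral of phasic dopamine over the pause, and a
    reduced reward-based motor-adaptation task (prism-perturbation
    ball-throwing structure) that links pause duration to learning
    performance in healthy, parkinsonian and levodopa-treated conditions.
License: MIT + file LICENSE
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
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
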