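Package: fearsim
Title: Simulating Extinction and the Return of Fear with Rescorla-Wagner
    Family Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A deterministic trial-level simulator for Pavlovian fear
    conditioning built around the Rescorla-Wagner delta rule and four
    extensions: configural (stimulus-pair) features, asymmetric decay of
    inhibitory associations, familiarity-dependent learning rates, and
    competitive attention with salience learning (a revised CompAct).
    Experiments are written as declarative designs (stimuli, contexts,
    stages, trial sequences, inter-trial intervals, delays) and expanded
    into discrete time-step sequences on which any model variant can be
    run. Builders are included for the classic return-of-fear paradigms
    (ABA/ABC/AAB renewal, occasion-setting renewal, spontaneous recovery,
    reinstatement), conditioned-inhibition phenomena, CS pre-exposure, and
    procedures that reduce the return of fear (deepened extinction,
    unpaired shocks, multi-context extinction, gradual extinction), each
    with the ordinal contrasts the phenomenon is defined by.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
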