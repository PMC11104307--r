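# Small designs shared across tests.

fix_cond_ext <- function(n_cond = 10, n_ext = 30, iti = 5) {
  stages <- list(stage("conditioning", "A", rep("CS+", n_cond), iti))
  if (n_ext > 0)
    stages <- c(stages, list(stage("extinction", "A", rep("CS-", n_ext), iti)))
  design(stimulus_catalog("CS", "A"),
         list(trial_spec("CS+", "CS", 1), trial_spec("CS-", "CS", 0)),
         groups = list(main = stages))
}

fix_delay_only <- function(steps) {
  design(stimulus_catalog("CS", "A"),
         list(trial_spec("CS-", "CS", 0)),
         groups = list(main = list(stage("delay", NA, delay_steps = steps))))
}
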