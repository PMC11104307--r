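# fearsim

Deterministic simulation of Pavlovian fear conditioning, extinction, and the
**return of fear** with Rescorla–Wagner family learning models.

Exposure-based treatments reduce fear by extinction: presenting the feared
stimulus without harmful consequences. The benefit is often temporary — fear
returns with a change of context (*renewal*), the passage of time
(*spontaneous recovery*), or a stray encounter with the aversive event
(*reinstatement*). `fearsim` implements a family of trial-level associative
learning models in which these relapse phenomena all trace back to one
mechanism: during extinction the context becomes a conditioned inhibitor (a
safety signal), which protects part of the threat association from being
unlearned. The package is aimed at learning theorists and computational
psychiatry researchers who want to simulate conditioning protocols and probe
which procedures make extinction durable.

## The models

Time is discrete. On step *n* the learner observes a cue vector *x_n*, maps
it to binary features *f(x_n)* (elemental features per stimulus, optionally
configural features per co-occurring stimulus pair), predicts the
unconditioned stimulus (US) with a positively rectified linear rule

    ŷ(x_n) = max( Σ_i f_i(x_n) w_i , 0 )

and updates association weights by prediction error:

    w_i ← w_i + λ f_i(x_n) (y_n − ŷ(x_n))

Five variants share this skeleton:

| variant       | additions                                                                | key defaults |
|---------------|--------------------------------------------------------------------------|--------------|
| `basic`       | elemental features only                                                  | λ = 0.3 |
| `configural`  | pairwise configural features (occasion setting)                          | λ = 0.2 |
| `decay`       | decay of inhibition: `w_i ← … − I[w_i<0] ρ w_i` on **every** step        | λ = 0.3, ρ = 0.002 |
| `familiarity` | per-feature rate `λ_i = λ_min + 0.5 (n_i+1)^(−p)` (latent inhibition)    | λ_min = 0.1, p = 1.5 |
| `compact`     | revised CompAct: salience η, attention `a = ηf / ‖ηf‖_m` rescales prediction and learning; η follows gradient descent on squared error; plus configural features, familiarity rates, and decay | ρ = 0.01, μ = 1.5, λ_min = 0.15, m = 8, p = 0.5 |

Experiments are declarative: a stimulus catalog, trial types, and per-group
stages (context, trial sequence, inter-trial intervals, delays) expand into
a time-step sequence in which ITIs are context-only steps and delays are
featureless steps — both matter, because the context keeps learning between
trials and inhibition keeps decaying during delays.

## Worked example: ABA renewal

```r
library(fearsim)
p <- build_paradigm("renewal_aba")   # basic model, lambda = 0.3
run <- run_paradigm(p)
run
#> <rw_paradigm_run> renewal_aba (basic)
#>                                                            label left_value
#>  renewal: Different tested outside the extinction context > Same  0.1964836
#>        return of fear: test exceeds end-of-extinction responding  0.1964836
#>   right_value relation margin passed
#>  4.515555e-13  greater   0.01   TRUE
#>  2.771339e-12  greater   0.01   TRUE
renewal_magnitude(run)
#> [1] 0.1964836
```

Both groups are conditioned (10 CS+ trials) and extinguished (30 CS− trials)
until test responding is effectively zero (`right_value ≈ 0`). The group
extinguished in context B and tested back in context A responds at
ŷ ≈ 0.196 — renewal — because testing outside the extinction context strips
away that context's inhibition and exposes the surviving CS→US association
(`run$trajectories$Different$final_state$w` shows w_CS > 0 with w_B < 0).

`list_paradigms()` names fifteen packaged experiments (renewal variants,
spontaneous recovery and its predicted context dependence, reinstatement,
inhibitor non-extinction, forgetting of inhibition, CS pre-exposure,
deepened extinction, unpaired shocks, multi-context and gradual extinction);
`run_battery()` runs them all and evaluates every ordinal contrast. Custom
experiments are composed with `stimulus_catalog()`, `trial_spec()`,
`stage()`, `design()` and simulated with `run_learner()`; designs round-trip
through JSON/YAML files (`write_design()`, `read_design()`). A thin CLI
lives at `inst/cli/fearsim.R` (`list`, `run`, `battery` subcommands).

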