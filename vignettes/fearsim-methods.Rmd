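---
title: "Models and methods behind fearsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fearsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearsim)
```

# The modeling problem

Extinction training reduces a conditioned fear response, but the reduction
is fragile: responding returns with a context switch (renewal), with time
(spontaneous recovery), and after unsignaled aversive events
(reinstatement). `fearsim` implements a family of error-driven associative
models in which all three effects follow from the associative status of the
*context*. Extinction does two things at once: it unlearns part of the
CS→US association, and it turns the extinction context into a conditioned
inhibitor — a safety signal whose negative weight cancels the remainder.
Whatever removes that inhibition (a new context, decay over time,
excitation from stray shocks) uncovers the surviving threat association.

# Learner architecture

On every discrete time step the learner observes a binary cue vector,
featurizes it, predicts the US, and updates. Features are binary:
elemental (one per stimulus, contexts included) and optionally configural
(one per unordered pair of stimuli that can co-occur; context–context pairs
are excluded because exactly one context is present at a time). Configural
features exist from the first step; features that never activate keep a
zero weight and are inert, so generating the full pair set is harmless.

Prediction is a rectified linear sum, `ŷ = max(Σ f_i w_i, 0)`. Rectification
is not cosmetic: with a purely linear prediction a lone inhibitor produces
ŷ < 0, hence a positive prediction error, and wrongly extinguishes when
presented alone. The `rectify` flag exists so this failure mode can be
demonstrated, and the test suite does so.

The five variants differ only in the update step, executed in a fixed
order (attention → prediction → observation counts and rates → salience →
weights), with every within-step quantity taken from the pre-update state:

* **basic / configural** — `w_i += λ f_i (y − ŷ)`.
* **decay** — adds `− I[w_i < 0] ρ w_i` on *every* time step. The decay
  term is not gated by feature activation: a 1000-step delay is simply
  1000 featureless steps during which negative weights contract by
  `(1 − ρ)` each step while positive weights are untouched. The indicator
  uses strict `w_i < 0` with no epsilon; a weight of exactly zero does not
  decay.
* **familiarity** — per-feature rates `λ_i = λ_min + 0.5 (n_i + 1)^(−p)`,
  with `n_i` incremented *before* the rate is computed (so the very first
  observation already uses `n_i = 1`). Counts accumulate for every feature,
  contexts included; contexts therefore become familiar quickly through ITI
  steps, which is intended — it reproduces the fast/slow learning asymmetry
  between discrete cues and backgrounds.
* **compact** (revised CompAct) — each feature has a salience `η_i > 0`;
  attention gain is `g = η ∘ f`, attention weights `a = g / ‖g‖_m`, so `a`
  has unit m-norm over present features and lower `m` means fiercer
  competition. Attention rescales both prediction (`ŷ = max(Σ a_i f_i w_i,
  0)`) and learning (`w_i += λ_i a_i f_i (y − ŷ) − I[w_i<0] ρ w_i`).
  Salience moves by gradient descent on squared prediction error with step
  size μ; the test suite checks the update against a finite-difference
  gradient to 1e−6. On featureless steps the attention normalization is
  undefined; the step is treated as pure delay (ŷ = 0, no learning, decay
  still applies).

Initial conditions are `w = 0`, `n = 0`, `η = 1` for every feature — the
learner starts with no associations and uniform salience. A salience floor
of 1e−4 (applied after each update) keeps the m-norm defined; negative
salience is meaningless in this scheme. States containing NaN/Inf abort the
run immediately.

# Schedules: trials, ITIs, delays

Experiments are declarative designs: a stimulus catalog, a dictionary of
trial types (cues + US), and per-group ordered stages. Expansion is
deterministic and literal. Each trial occupies one step and is preceded by
`iti_steps` context-only steps (default 5); nothing follows a stage's last
trial. It is essential to simulate the ITIs: that is where the context
over-predicts and extinguishes between trials, which is why a context never
becomes as excitatory as the CS it accompanies. Delay stages present *no*
stimuli at all — time in the home cage is not time in any experimental
context, and giving the delay a context would confound decay of inhibition
with context learning. Time is unitless; no mapping from steps to minutes
or days is attempted.

Where a protocol interleaves trial types (conditioned-inhibition training,
mixed test stages), `interleave()` produces a fixed round-robin order. The
models' ordinal predictions are robust to ordering, and a deterministic
order keeps every run reproducible and inspectable.

# Paradigms and their parameters

Fifteen builders (`list_paradigms()`) encode the simulated experiments with
the hand-tuned parameters used throughout: basic model λ = 0.3, configural
λ = 0.2, decay ρ = 0.002 (λ = 0.3), familiarity λ_min = 0.1, p = 1.5, and
for gradual extinction the compact model with ρ = 0.01, μ = 1.5,
λ_min = 0.15, m = 8, p = 0.5. Parameters are per-paradigm defaults, not
fits; the claims being reproduced are ordinal (which group responds more),
so the exact values matter little and `model_params()` accepts overrides.

Trial counts are mostly unstated in the source experiments; the defaults
are conditioning 10, extinction 30, test 4, chosen so each stage approaches
its zero-error fixed point, and all are configurable. Inhibition training
stages use 15 trials per interleaved type for the same reason —
discrimination learning with three trial types needs more passes to
equilibrate. The test suite verifies that contrast directions survive
doubling the extinction counts.

Choices worth flagging because the sources leave them open:

* **Renewal magnitude** across designs is scored within-group as test
  responding minus final-extinction responding, so designs with different
  test contexts compare on a common footing.
* **Spontaneous-recovery context dependence** uses conditioning in A,
  extinction in B, and tests in B (Same) or a novel C (Different). The
  novel test context isolates the prediction — the delay gain in the Same
  group reflects decayed extinction-context inhibition, while a novel
  context has no weight to decay — without mixing in renewal from returning
  to A.
* **Gradual extinction** places the reinforced extinction trials at
  positions 1, 4, 9, 16 of 24 (and mirrored at 9, 16, 21, 24 for the
  reverse condition): increasing gaps realize a contingency that "fades
  out", the mirrored version one that "fades in".
* **Multi-context extinction** splits the same total number of extinction
  trials (10+10+10 vs 30) so the groups differ only in context switches,
  not exposure amount.
* **Reinstatement** uses 4 unsignaled US presentations; the control group
  receives matched context exposure without shocks.
* **Test-stage probes.** Test stages are themselves extinction (or
  acquisition) trials, so later test trials are contaminated by learning
  within the stage. Contrasts that quote a response on a mixed test stage
  (forgetting of inhibition) therefore probe the *first* trial of each
  type; single-type test stages use the stage mean.

# What the simulator does and does not emulate

Runs are deterministic simulations of average behavior: the response
measure is ŷ itself, a monotone stand-in for freezing or suppression, with
no stochastic responding, no individual differences, and no mapping to
response probabilities. "Between-subject" groups are separate deterministic
runs. Consequently a passing contrast shows that the model *mechanism*
produces the ordinal pattern under the stated schedule — it says nothing
about effect sizes in real animals, statistical power, or the many features
of real data (trial-order variability, generalization between similar
contexts, graded stimulus intensities, real-time within-trial dynamics)
that the binary, discrete-step representation omits.

Contrast evaluation guards directions with a margin of 0.01 on ŷ (and
0.02 for approximate-equality claims): large enough to ignore float noise,
an order of magnitude below typical simulated effects.

# Known limitations

* In the forgetting-of-inhibition design, the context itself acquires a
  small negative weight during training (it is ratcheted down on
  compound-nonreinforced trials and protected by rectification during
  ITIs). Under the decay model that context inhibition also decays over the
  delay, so the model predicts a small (≈0.03) delay-induced rise in
  responding to the excitor alone — the same mechanism as spontaneous
  recovery, an order of magnitude below the compound effect (≈0.31), but
  above the 0.02 equality tolerance. The battery reports this contrast as
  failed rather than hiding it; the dissociation contrast (delay affects
  the compound far more than the excitor) passes.
* Decay of *context* inhibition produces between-group spontaneous
  recovery but cannot produce within-subject recovery, which would require
  CS-specific inhibition; that extension is out of scope here.
* The configural model predicts faster extinction after a context change
  and context-dependent conditioning, which empirical data only partially
  support; the builders use configural features only where the phenomenon
  requires them (occasion setting, compact model).
* Excitatory/inhibitory weight decomposition, latent-cause and retrieval
  models, and fitting to empirical data are outside the package's scope.

# Problem sizes and runtime

Every packaged paradigm expands to between ~250 and ~3700 time steps across
its groups (delays of 1000 steps dominate); the full battery simulates
about 18,000 steps and runs in well under a minute on a single core. The
update-rule oracle tests compare all five variants against a naive
pseudocode transcription on 100 random short sequences (≤ 20 steps, ≤ 5
stimuli) to 1e−12.
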