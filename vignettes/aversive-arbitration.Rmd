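---
title: "Arbitrating goal-directed and Pavlovian control of aversive behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arbitrating goal-directed and Pavlovian control of aversive behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aversim)
library(dplyr)
```

## The model

aversim simulates an agent facing a signalled-avoidance task: on each trial
a visual cue appears (optionally signalling a delay to threat), the agent
emits one action, and a high or low auditory tone follows — the high tone
perfectly coupled with an electric shock of value $-1$, the low tone with
safety (value $0$). Two controllers compute an action in parallel on every
trial, and a single arbitration variable decides which of them reaches the
motor output.

**The goal-directed controller** maintains a world model and plans
prospectively. Its components:

* a *transition model*: Hebbian counts $n(c,a,o)$ over (cue, action, outcome)
  triples, giving conditional outcome probabilities
  $\hat P(o \mid c,a) = n(c,a,o) / \sum_{o'} n(c,a,o')$. Counts start at a
  pseudocount (default 1) so probabilities are defined and uniform before
  experience, and only the triple actually experienced on a trial is
  incremented;
* *outcome values* $v(o)$, learned by a single-step temporal-difference rule
  $v(o) \leftarrow v(o) + \alpha_v (r - v(o))$ on the reinforcer $r$ actually
  received. Outcomes are terminal within a trial, so there is no bootstrapped
  successor term and the rule coincides with a Rescorla–Wagner delta rule;
* a *planning sweep* that simulates each action in turn, writing its expected
  value $q(a) = \sum_o \hat P(o \mid c, a)\, v(o)$ into a working-memory
  buffer. The sweep is serial in the underlying theory (simulate an action,
  store its value, inhibit it, move to the next); the implementation computes
  the same buffer as a loop over actions whose result is provably that
  expectation sum — the node-level dynamics carry no additional behavioural
  content, so they are not simulated tick by tick;
* *softmax plan selection* with temperature $\tau$:
  $P(a) \propto \exp(q(a)/\tau)$. The plan node's activation is the buffer's
  *maximum* value, even when the sampled action is not the best one.

**The Pavlovian controller** attaches a value $pv(c)$ to each cue, learned by
the same delta rule on received reinforcers
($\alpha_p$), and triggers a fixed innate response whose activation equals
$pv(c)$ (proportionality constant 1, so the activation is signed and at most
0 under purely aversive reinforcement). In all shipped experiments the innate
response is `no_action`, modelling freezing. Crucially, $pv$ tracks the shock
frequency realised *under the agent's own behaviour*, not under the optimal
policy — this is what allows a freezing agent to keep confirming the value
that sustains freezing.

**Three modulators** shape arbitration:

* *specific controllability* $SC = \max_a q(a) - \min_a q(a)$, the buffer
  spread: large when one action is clearly better, zero when all actions are
  equally (in)effective;
* *generalised controllability* $GC$, a slow stimulus-independent delta rule
  over the $SC$ stream, $GC \leftarrow GC + \alpha_{gc}(SC - GC)$ — an
  exponentially weighted average of the agent's entire controllability
  history. It is the only learned quantity that survives a context switch;
* *threat distance* $TSTD = \kappa \cdot d$, a linear map from the signalled
  seconds-to-threat (an optional saturating form $\kappa d / (1 + \kappa d)$
  is available but off by default). Linearity is the minimal reading of
  "activation corresponds to distance".

**Arbitration.** Instrumental ability is the weighted sum

$$IA = b + w_{gdp}\max_a q(a) + w_{sc} SC + w_{pr} pv(c) + w_{gc} GC + w_{tstd} TSTD$$

and the probability that behaviour follows the goal-directed plan rather than
the innate reaction is $\sigma(IA) = 1/(1+e^{-IA})$. All five weights are
non-negative; the Pavlovian input carries its own (negative) sign, so greater
expected punishment lowers $IA$ through a positive coefficient. A literal
"directly/inversely proportional" coupling would not yield a probability,
hence the logistic.

Within a trial the order is strict: perceive, plan, react, modulate,
arbitrate, act, and only then learn — every update uses the pre-update
state's predictions, verified in the test suite against a two-phase
compute-then-commit oracle.

## Parameters, defaults, and how they were chosen

| parameter | default | meaning |
|---|---|---|
| `alpha_v` | 0.1 | outcome-value learning rate (per trial) |
| `alpha_p` | 0.01 | Pavlovian-value learning rate |
| `alpha_gc` | 0.002 | generalised-controllability learning rate |
| `temperature` | 0.25 | softmax temperature (value units) |
| `gc_prior` | 0.6 | initial generalised-controllability belief |
| `tstd_scale` | 0.05 | threat-distance activation per second |
| `pseudocount` | 1 | initial transition count per triple |
| `w_gdp, w_pr, w_gc, w_tstd` | 1 | arbitration weights |
| `w_sc` | 2.5 | weight on specific controllability |
| `bias` | 2 | arbitration intercept |

The underlying theory specifies the learning rules and the arbitration
structure but no parameter values, so the defaults are this package's own
calibration, chosen once so that all five preset experiments reproduce their
expected qualitative patterns simultaneously under a single configuration
(assessed as sign-consistency over 20 seeds), and then frozen. The choices
that matter:

* **`temperature` 0.25** makes asymptotic choice near-greedy while retaining
  exploration: with action values separated by the task's typical 0.2 value
  units, the best action is chosen roughly half the time, enough to keep
  estimating the inferior actions.
* **`alpha_gc` 0.002**, fifty times slower than value learning. Learned
  helplessness requires the *amount* of uncontrollable training to matter:
  at this rate an agent retains most of its controllability prior after 500
  uncontrollable trials ($0.998^{500} \approx 0.37$) and essentially none
  after 7000 ($0.998^{7000} \approx 10^{-6}$), which is exactly the
  dissociation the helplessness experiment manipulates.
* **`alpha_p` 0.01.** Pavlovian threat values in animals are persistent; a
  slow rate also keeps the late-training value stable instead of chattering
  with each trial, so the gradual decline of goal-directed control under an
  uncontrollable cue is visible over hundreds of trials rather than being
  compressed into the first dozen.
* **`gc_prior` 0.6**, an optimistic prior: a naive agent should attempt
  instrumental control. A zero prior would start every agent helpless. 0.6
  is the scale of the buffer spreads the shipped tasks actually produce
  (between 0.2 for a weakly controllable cue and 1.0 for a fully
  controllable one), so the prior is neutral with respect to the tasks'
  long-run controllability.
* **`w_sc` 2.5 and `bias` 2** are the two deliberate departures from an
  all-unit parameterization, and the reason is instructive. Under unit
  weights the specific-controllability experiment *fails*: an agent that
  freezes under the controllable-but-poor cue is shocked every time (rather
  than 80% of the time), so its Pavlovian value ends up roughly 0.15 lower
  than under the uncontrollable cue, which cancels the 0.14 controllability
  advantage in $IA$. The realized-punishment confound is a genuine property
  of the model, and a larger weight on $SC$ is needed for controllability to
  dominate it. The positive intercept keeps an untrained agent predominantly
  goal-directed (matching the observation that behaviour starts out fully
  goal-directed) and sustains enough instrumental engagement under
  uncontrollable cues for their action values to be estimated precisely.

All parameters are exposed in `agent_config()` / `arbitration_params()` and
recorded in every run's JSON sidecar.

## The simulated task and its presets

The environment is deliberately minimal: per trial, one cue (red or black),
one action (lever press, chain pull, or nothing), one Bernoulli draw deciding
tone and shock together. Blocks either fix the cue or sample it uniformly;
when threat delay is manipulated it is sampled uniformly from the configured
levels and signalled to the agent. The cue-to-tone interval is a label used
by the threat-distance channel, not simulated time.

```{r presets}
task_sim3()
```

Five presets cover the standard designs (see `?task_presets`): goal-directed
acquisition (`sim1`, arbitration disabled), Pavlovian interference (`sim2`),
a specific-controllability contrast with matched best-action shock rates
(`sim3`), a learned-helplessness design with 500- vs 7000-trial
uncontrollable pretraining and a novel-context switch (`sim4`), and a
threat-distance manipulation with 3 s vs 30 s signalled delays (`sim5`).
The published description of the threat-distance contingencies is internally
inconsistent (the prose makes red-cue lever pressing perfectly safe, the
figure legend punishes it 20% of the time); the shipped `sim5` preset follows
the figure legend and the prose variant is provided separately as
`sim5_textvariant` — the two are never merged.

Experiment runners default to 1000 trials per cue (the helplessness design
uses its stated 500/7000 + 500), 20 seeds, and report per-seed summaries;
"asymptotic" always means the mean over the last fifth of a cue's trials.

```{r sim3, eval = FALSE}
s3 <- run_sim3(seeds = 1:20)
tidy(s3) # per-seed asymptotic SC and P(goal-directed) per cue
autoplot(s3) # seed-averaged trajectories, trailing 25-trial average
```

## Randomness, yoking, and reproducibility

Each run draws from two uniform streams — environment (cue, delay, shock) and
agent (plan sampling, controller sampling) — seeded deterministically from
the run's master seed and *re-derived at every block boundary* from
(seed, block). Two consequences:

* a (task, config, seed) triple reproduces a run bit for bit;
* two agents sharing a seed are yoked: they face identical environment draws
  within a block regardless of how many trials they spent in earlier blocks.
  In the helplessness design the uncontrollable block's shock draws are
  action-independent, so the short- and long-trained agents receive exactly
  matched punishment streams, and after a full reset
  (`preserve_gc = FALSE`) their novel-context behaviour coincides exactly —
  demonstrating that generalised controllability is the only state crossing
  the context boundary.

A context switch resets transition counts, outcome values, and Pavlovian
values to initial values. That includes the tone values, although tones are
shared across contexts: the reset is read literally as "all quantities", a
deliberate choice kept for transparency.

## Numerical choices and degenerate inputs

* Softmax uses max-subtraction; results agree with the naive formula to
  1e-12 (tested).
* Argmax ties in the buffer break by action-list order, so runs are
  deterministic under exact value ties (e.g., the very first trial).
* The pseudocount floor keeps every conditional probability defined;
  probabilities renormalise by construction rather than by explicit
  normalisation steps.
* Degenerate tasks are legal: a single cue, a single action, `p_shock` 0 or
  1, or no delay manipulation (the threat-distance channel then contributes
  exactly 0).
* Learning rates outside (0, 1], non-positive temperatures, negative delays,
  negative weights, and unknown identifiers raise immediate errors rather
  than propagating silently.

## What the simulations do and do not show

The synthetic task reproduces the *structure* of the classic avoidance,
controllability, and helplessness designs: contingencies, block structure,
yoked punishment matching, signalled delays. It does not emulate real
behavioural data: there is no within-trial time course, no habituation or
sensitisation, no motor noise, no individual-difference structure, and the
Pavlovian repertoire is a single fixed response per cue. Passing tests
therefore show that the *model* produces the claimed qualitative phenomena
under its stated assumptions — not that it fits any animal's data
quantitatively.

Two honest caveats from the package's own runs. First, with the default
1000-trials-per-cue budget, the asymptotic buffer spread under a fully
uncontrollable cue does not reach zero but an estimation-noise floor of
about 0.04 (the spread of binomial estimates of three identical
probabilities); the collapse to zero is exact only in expectation. Second,
in the helplessness design the long-trained agent is *less* goal-directed in
the novel context than its yoked short-trained partner on essentially every
seed pair, but the effect is a graded reduction, not a categorical failure
to act: with enough exposure to the controllable context both agents
eventually learn the effective action. Stronger, categorical helplessness
would require either a lower arbitration intercept or a longer test horizon
than the preset uses.

## Known limitations

* Single-step planning horizon only: policies over multi-step futures (and
  discounting) are out of scope.
* No habitual (stimulus–response instrumental) controller, and no
  value-level Pavlovian–instrumental transfer; the controllers interact only
  at the motor output.
* Controllability is implemented as the buffer spread; the fuller
  probabilistic definition (probability of avoiding punishment with versus
  without the best action, scaled by the punishment's value) is treated as
  the motivation for that spread, not as a second formula.
* The outcome normalisation divides each input by the total input to the
  outcome layer (standard conditional-probability normalisation); a reading
  that excludes the node's own input from the denominator exists but is not
  implemented.
* Arbitration parameters are calibrated to the preset experiments'
  qualitative patterns, not fitted to empirical datasets; quantitative
  statements about any individual parameter value should not be read off
  these defaults.
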