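---
title: "Simulating and dissecting behaviour on the two-step decision task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and dissecting behaviour on the two-step decision task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(twostepr)
```

## The task and why it is delicate

The two-step task is the standard behavioural assay for separating
model-based from model-free reinforcement learning. On every trial the
subject makes a first-step choice between actions A and B; the choice leads,
through a *common* (probability `p_common`) or *rare* transition, to
second-step state *a* or *b*, where reward is delivered stochastically. In
the **original** variant (`two_step_task("original")`), `p_common = 0.7`,
each second-step state offers two actions, and the four reward probabilities
drift as independent reflecting Gaussian random walks on [0.25, 0.75] with
per-trial step SD 0.025. In the **reduced** variant
(`two_step_task("reduced")`), `p_common = 0.8`, each second-step state has a
single action, and reward probabilities alternate between 0.8/0.2 and
0.2/0.8 in 50-trial blocks.

The reduced variant raises the payoff for exploiting the task structure —
which is exactly why it is dangerous: it strengthens correlations through
which purely model-free strategies can masquerade as model-based ones. This
package exists to simulate those strategies at scale and to run the analyses
that do, and do not, tell them apart.

## The agents

All agents share one interface: first- and second-step choice probabilities
from internal state, and a state update applied at the end of each trial.
Simulation and likelihood evaluation run through a single compiled code
path, so the likelihood an agent assigns to a session it generated is
exactly the sum of its recorded log choice probabilities.

* **Q(λ)** (`q_lambda_agent`): model-free values updated as
  `Q1 <- (1-α)Q1 + α(Q2 + λ(r − Q2))` then `Q2 <- (1-α)Q2 + αr`, applied
  sequentially at trial end with the first-step update using the pre-update
  second-step value. λ = 1 updates the first step directly from the outcome;
  λ = 0 from the second-step value.
* **Model-based** (`model_based_agent`): recomputes
  `Q1(i) = Σ_j P(s_j|i) V(s_j)` each trial from the true transition matrix
  (or one learned online at rate η, initialised at 0.5/0.5), with
  `V(s) = Q(s, a)` on the reduced task and the max of the two action values
  on the original.
* **Reward-as-cue** (`reward_as_cue_agent`): treats the previous trial's
  (outcome, second-step state) pair as the decision state and learns a
  separate pair of first-step action values for each of the four cues,
  updated directly from the outcome. It converges to a fixed
  events-to-choice mapping rather than tracking values across blocks.
* **Latent-state** (`latent_state_agent`): knows the world has two states
  (reward likely in *a*, or in *b*, with believed probabilities
  `p_good`/`p_bad` — 0.8/0.2 on the reduced task, 0.625/0.375 on the
  original, the quartiles of the walk range), performs an exact Bayesian
  update of its posterior from the trial outcome given the reached state,
  mixes in a per-trial reversal probability ω, and maps belief to choice
  with lapse rate ε.
* Utility policies: `det_reward_as_cue_agent()` (the deterministic
  events-to-choice mapping used for performance comparisons),
  `random_agent()` and `random_mf2_agent()` (uniform first step with
  Q-learning at the second step).

A perseveration bias adds a transient bonus to the previously chosen
first-step action inside the softmax only; it never enters value updates.

### Choices the equations leave open

Several details are not pinned down by the update equations; the package
fixes them as follows (all configurable where they are parameters):

* Action values initialise at 0.5 — the chance reward rate, unbiased
  between actions; the latent-state posterior initialises at 0.5 and exact
  ties map to choice probability 0.5.
* Update order within a trial: (original task) the second-step choice uses
  pre-update values; at trial end the first-step value updates first, using
  the pre-update second-step value, then the second-step value updates.
* The latent-state Bayes step precedes the reversal mixing step.
* Reward-as-cue has no cue on trial 1: the choice is uniform and no
  first-step update is made.
* On the original task Q(λ) and model-based agents use a single (α, T) at
  both steps; only reward-as-cue carries separate second-step parameters.
* The learned transition estimate (η variant) initialises uniform.
* Reward probabilities advance at trial end: trial *t*'s outcome uses the
  probabilities in force on trial *t*. The walk reflects by folding
  (`x -> 2·bound − x`, iterated), which is the reflected-process
  construction whose stationary law is uniform on the bounds; walks for
  different second-step actions are mutually independent. The first block's
  good state is chosen at random so sessions are exchangeable.

## Simulating

```{r simulate}
task <- two_step_task("reduced")
agent <- q_lambda_agent(alpha = 0.334, T = 3.22)   # a Q(1) agent
sessions <- run_batch(agent, task, n_sessions = 4, n_trials = 2000, seed = 1)
reward_fraction(sessions)$mean
```

Sessions are data frames carrying, per trial, the choice, transition,
second-step state, outcome, the true reward probabilities in force, the
agent's first-step choice probability, and (for value-based agents) the
pre-choice action values. `write_sessions()`/`read_sessions()` provide a
lossless tab-separated interchange format, so externally recorded data in
the same layout can be analysed and fitted identically.

## The stay-probability confound and its correction

The classic analysis tabulates the probability of repeating the previous
first-step choice by the previous trial's transition and outcome
(`stay_table()`), or regresses stay/switch on the coded previous-trial
events (`fit_choice_regression()`). A model-free Q(1) agent should show an
outcome effect and no transition-outcome interaction — but on the reduced
task it shows a strong spurious interaction:

```{r confound}
fit_choice_regression(sessions)
```

The mechanism is visible in `trial_start_value_table()`: the difference
between chosen and unchosen action values at trial start correlates with
whether the choice was *correct*, which in turn shifts the probabilities of
the four transition-outcome event combinations. Adding a *correct*
predictor (`correct_binary`, or `correct_continuous` when reward
probabilities vary in magnitude, as on random walks) absorbs that variance:

```{r corrected}
fit_choice_regression(sessions, c("outcome", "transition", "interaction",
                                  "correct_binary"))
```

`fit_lagged_regression()` extends the analysis over multiple trials back.
Its encoding is chosen to match the stay-analysis semantics: the response
is the choice identity (A vs B), and the event predictor at lag *k* is the
event's +0.5/0 coding multiplied by the sign of the choice made at trial
*t−k*, with an intercept absorbing side bias — so a positive loading means
"repeat the choice made *k* trials ago". The default of 12 lags covers the
decay of every agent family here; trials without a full lag history are
dropped rather than zero-padded.

Per-session regressions use plain maximum likelihood; a session whose fit
separates perfectly is re-fit with a small ridge (10⁻⁴) and flagged.
Cross-session inference is a two-sided one-sample t-test on per-session
loadings.

## Fitting and comparing models

`session_log_likelihood()` replays an agent on recorded events (both
choices are modelled on the original task; the reduced task has only the
first-step choice). `fit_ml()` maximises it over a transformed
unconstrained space — logistic for rates and probabilities, log for inverse
temperatures — by Nelder–Mead with randomised restarts; each restart first
probes several random points and starts the simplex from the best. The
eligibility trace is fixed per family (Q(0), Q(1), Q(0.25), …), so every
reduced-task family has two free parameters and raw likelihoods are
directly comparable; `cross_fit_matrix()` produces the generator × fitter
likelihood table with SEMs and paired tests, plus BIC
(`k·ln n − 2·logL`) for the original task where parameter counts differ.

The latent-state likelihood needs care: because its policy is a threshold
on the posterior, the likelihood is a step function of ω with narrow
ridges. `fit_ml()` therefore polishes the best restart with dense
coordinate-wise line searches at shrinking spans before a final simplex
pass. Even so, the ω estimate at the 10-session × 10000-trial scale has
sampling spread of roughly ±10% across datasets — a property of the
estimator, worth remembering when interpreting single-dataset fits.

`matched_agent_params()` records the parameter sets that make the agent
families' average behaviour comparable: the model-based agent at
α = 0.5, T = 5, and every other family fitted to it by maximum likelihood —
each value reproducible with `fit_ml()` on simulated model-based data.

## Reward-rate optimisation

`optimise_performance()` asks how well a strategy *can* do: for each
evaluation session it maximises the reward fraction by Nelder–Mead on the
transformed parameter space (rates on [0,1]; inverse temperatures bounded
at 50 by a scaled logistic), holding the random seed fixed across objective
evaluations (common random numbers), restarting from 10 random initial
points, and then re-evaluating the winning parameters on a fresh seed so
that seed-overfitting cannot inflate the report. Nelder–Mead is used
because no Powell implementation is available in the supporting libraries;
both are derivative-free and, with common random numbers and restarts,
agree with brute-force grid search within evaluation noise (this is tested).

Two findings from running this stack are worth recording. On the reduced
task the optimised Q(1) agent reaches a reward fraction of ≈0.594,
reproducing the reference value exactly, while the optimised model-based
agent plateaus at ≈0.635 in this implementation — dense grid search over
(α, T) up to T = 1000, an independent pure-R re-implementation, and
perseveration/forgetting variants all confirm the plateau, and an
ideal-observer bound (Bayesian latent-state inference at the generative
reversal rate) caps reversal-naive strategies near 0.646, so values much
above that appear unattainable for this agent class. On the original task
the optimised ceilings are ≈0.544 for both agents with no significant
difference between them; experiments show these original-task levels are
sensitive to the walk's boundary rule (clipping at the bounds, which makes
extreme probabilities sticky, raises them by ≈0.01), and this package
deliberately implements the stated reflecting process.

## What the simulations do and do not show

The generator reproduces the tasks' generative structure exactly
(transitions, block reversals, reflected walks) and the agents' idealised
strategies. It does not emulate features of real subjects — reaction times,
lapses of engagement, satiety, mixtures of strategies, or parameter drift
within a session. Passing the analyses here therefore demonstrates that the
*pipeline* identifies each pure strategy correctly at scale (10 sessions ×
10000 trials unless stated otherwise); it does not guarantee the same
separability in smaller, messier experimental datasets — the cross-fit
resolution shrinks quickly with session count.

## Problem sizes used in the tests

The test suite runs the 10 × 10000-trial protocol for the performance and
confound-correction checks (with 4 optimisation restarts), and scales the
five-family cross-fit matrix to 6 sessions × 3000 trials with 3 restarts —
sizes at which every qualitative conclusion is stable across seeds while
the whole suite stays quick to run. The acceptance script re-runs
everything at the full scale with 10 restarts.
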