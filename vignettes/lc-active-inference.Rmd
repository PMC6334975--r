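---
title: "Simulating locus coeruleus firing and adaptive model decay with active inference agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating locus coeruleus firing and adaptive model decay with active inference agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coeruleus)
```

## The model

`coeruleus` simulates discrete-state active inference agents and uses one of
their internal quantities — the *state-action prediction error* (SAPE) — as a
model of locus coeruleus (LC) activity and, fed back, as a controller of the
agent's own learning rate.

Each trial is a finite-horizon POMDP with hidden states $s$, observations
$o$, actions $u$ and time steps $\tau = 1..T$ (one second each). The agent's
generative model consists of a likelihood $A$ ($P(o\mid s)$,
observation-by-state, column-stochastic), action-conditioned transitions $B$
($P(s'\mid s, u)$), log-preferences over observations $C$, an initial-state
prior $D$, and an exhaustive policy set (action sequences of length $T-1$).
$A$, $B$ and $D$ are parameterised by Dirichlet concentration counts
$(a, b, d)$; the agent works with their expected distributions (geometric-mean
/ digamma form for inference, Dirichlet mean for outcome prediction).

One update cycle per time step:

1. **State inference.** For every policy still consistent with the actions
   taken, posterior state marginals over *all* trial times (postdiction for
   the past, prediction for the future) are obtained by sum-product message
   passing along the trial chain, iterated to convergence (cap 16 sweeps,
   max-change $10^{-6}$). On a chain, message passing is exact, so the first
   sweep attains the free-energy minimum; the recorded free-energy trace
   (uniform-initialisation bound followed by $-\log$ evidence) is
   non-increasing by construction, and per-policy $F$ equals the negative
   log evidence of the observations so far.
2. **Policy evaluation.** The expected free energy of each policy sums, over
   future steps, a pragmatic term (expected utility $\mathbb{E}[C]$ under
   predicted outcomes), the epistemic state information gain
   ($H[Q(o)] - \mathbb{E}_s H[A(\cdot\mid s)]$), and — when the likelihood is
   being learnt — the Dirichlet novelty bonus
   $\tfrac12(1/a - 1/\mathrm{colsum}\,a)$.
3. **Policy posterior and precision.** $\pi = \mathrm{softmax}(-F - \gamma G)$,
   with the precision $\gamma$ updated by damped fixed-point iteration
   against a Gamma prior (rate $\beta = 1$, initial $\gamma = 1$).
4. **Bayesian model average.**
   $S_\tau = \sum_p \pi_p\, s^p_\tau$ — the agent's overall map of past,
   present and future states.
5. **Prediction error.** From the second step onwards,
   $\mathrm{SAPE}(t) = \sum_\tau D_{KL}\!\left[S^t_\tau \,\|\, S^{t-1}_\tau\right]$
   (nats; probabilities floored at $10^{-16}$). There is no error at
   $t = 1$: no earlier model average exists.
6. **Action.** The policy posterior is marginalised onto the current action.
7. **Learning (end of trial).** Each learnable array accretes the trial's
   evidence through the decay rule
   $\mathrm{new} = \mathrm{counts} + \mathrm{increment} - (\mathrm{counts}-1)/\alpha$:
   $d$ accretes the final model-average belief about the initial state, $a$
   the observed outcome × state-belief outer products, $b$ the
   state-transition coincidences of the actions taken. Counts relax toward
   the flat prior at 1 with time constant $\alpha$ trials; under constant
   increments they converge geometrically (rate $1 - 1/\alpha$) to
   $1 + \alpha\cdot\mathrm{increment}$.

Two printed formulas are implemented with a corrected reading, in both cases
because the published rendering is inconsistent with every figure and stated
interpretation: the spiking logistic is increasing in the prediction error
($p = 1/(1+e^{-k(\mathrm{SAPE}-m)})$ — high surprise must give phasic bursts),
and the decay term divides by $\alpha$ ($-(d-1)/\alpha$ — only division makes
$\alpha = 32$ slow decay and $\alpha = 2$ fast decay).

## The LC unit and the feedback loop

The simulated LC unit converts each step's prediction error into a firing
probability via the increasing logistic ($k = 8$; midpoint $m$), then emits
at most one spike per 0.1 s bin across the 1 s step — a 10 Hz ceiling at
$p = 1$. The same error, through a *decreasing* logistic with the same $k$
and $m$, sets the next decay factor:
$\alpha = \alpha_{\min} + \alpha_{\max}/(1 + e^{k(\mathrm{SAPE}-m)})$ with
$\alpha_{\min} = 2$, $\alpha_{\max} = 32$ (the algebraic range is therefore
$(2, 34)$; the formula is taken as authoritative over the prose "between 2
and 32"). When a trial yields several errors, the maximum is used. Large
surprise → fast forgetting (flexible model); small surprise → stable model.

The midpoint $m$ is calibrated per task as the mean plus one sample standard
deviation of all per-step errors over 100 trials at fixed $\alpha = 16$.
The source text does not say from which agent state those 100 trials start.
`prepare_gonogo_agent()` uses a two-stage scheme: a provisional naive-agent
calibration, 750 flexible-decay training trials, then re-calibration from
the trained counts. A naive-only calibration is dominated by early-learning
transients and places $m$ above every stationary peak, which freezes the
flexible mechanism; re-calibrating on the trained agent puts $m$ inside its
operating range (typically ≈ 0.6–0.8 nats, against go-cue peaks ≈ 1–1.5).

## The two tasks

**Go/No-go** (`gonogo_task()`): six states (location 1 in a go or no-go
context, location 2 hearing the go or no-go cue, location 3 rewarded or
unrewarded), five observations (start, two cues, reward, no reward),
horizon 3. The trial structure forces the move to location 2 (the cue must
be received); the decision at the cue is to approach location 3 (rewarded
only in the go context, $C = +3$; aversive when unrewarded, $C = -3$) or
withdraw to location 1. The go context occurs with probability
`p_go = 0.10`; which cue signals it is the contingency that reversal
schedules flip. The agent learns `a` and `d`; transitions are known.

Two deliberate structural choices:

* **Perception vs contingency.** Only the cue columns of `a` (states 3–4)
  learn and decay; the location/outcome columns are hard-wired perception
  (counts $1 + 128\cdot\text{truth}$, untouched by learning). If the whole
  likelihood decays, the meaning of rarely visited outcomes erodes to its
  decay ceiling within a few dozen trials and learning collapses into a
  wrong-attribution basin (rewards credited to the no-go path). What the
  task trains — and what the reversal reverses — is the cue-context
  contingency, so that is what the Dirichlet machinery models.
* **Initial cue beliefs.** The cue columns start with the true assignment at
  modest confidence (`cue_init = 4`; erased by decay within a few dozen
  trials). Discovering cue semantics from a flat prior is bistable: with a
  9:1 evidence ratio in favour of the no-go context, a run of missed go
  trials teaches the wrong association and extinguishes approach in roughly
  a quarter of simulations, contradicting the premise that training
  reliably yields a well-trained animal. Reversal learning is unaffected as
  a test of relearning: after the flip the initial counts are long gone and
  the agent must genuinely re-learn both cue meanings from disconfirmation.

**Explore/exploit bandit** (`bandit_task()`): seven states (a start state
plus rewarded/unrewarded versions of three arms), identity likelihood,
four actions moving to the start or one of the arms, horizon 2. One arm
pays with probability 0.9, the others 0.1; block schedules move the high
arm. Reward contingencies live in the transition counts `b`, the only
learnable array; exploration needs no extra ingredient — the information
gain term is the outcome entropy, and forgetting re-flattens unvisited
arms' counts ("optimism by forgetting"). The reward preference is $+6$ per
rewarded outcome: the magnitude is not printed in the source and at $+3$
the utility gaps are shallower than the behavioural temperature, so no
agent harvests the high arm reliably.

## Action selection

`select_action()` defaults to the deterministic mode (argmax over the
action marginal, exact ties broken at random from the caller's RNG). The
sampled mode draws from the marginal sharpened by an action precision
($P(u) \propto q(u)^\eta$, default $\eta = 2$; $\eta = \infty$ recovers
argmax).

The protocols use both on purpose. Training and the static session are
exploitation regimes and run deterministically — this is also what makes the
training outcome reproducible across seeds (30/30 well-trained agents with
hit rate ≈ 1 and false-alarm rate ≈ 0 in our checks). The reversal and
bandit paradigms are precisely about renewed exploration; there, actions are
sampled with $\eta = 2$: near-deterministic when the posterior is decisive,
with occasional exploratory choices near indifference. Under pure argmax no
agent (flexible or fixed) ever re-approaches after a reversal — the
extinguished response leaves no gradient to restore it — while raw-marginal
sampling ($\eta = 1$) degrades static behaviour to a ~50% hit rate.

## What the simulations reproduce, and what they do not

With the defaults, the package reproduces: phasic error peaks on rare go
cues (an order of magnitude above the no-go response); suppression of the
peak on consecutive go trials by ≈ 12% (mean 11.6%, seed SD ≈ 5 across our
30-seed check — the estimator rests on only ~20 consecutive-go pairs per
2000-trial session, so single-session values scatter widely); larger go
than no-go responses at equal cue probabilities; peaks decreasing in
`p_go` and increasing in the reward value `c` (with a non-monotone dip at
`c = 2`); post-reversal tonic elevation for the slower (fixed
$\alpha = 16, 32$) agents; conditioned-stimulus transfer after reversal
(feedback-dominant responses first, cue-dominant from ≈ trial 150); fastest
d′ recovery for the flexible agent, with the $\alpha = 2$ agent never
consolidating; and the bandit ordering — fast decay wins under 15-trial
blocks, slow decay under 50-trial blocks, the flexible agent under random
block lengths.

Known deviations, documented rather than patched: the go/no-go asymmetry
reverses already at `p_go = 0.55` (the source reports it persisting up to
55%); the very fast relearning of the flexible and $\alpha = 2$ agents
means their 20-trial post-reversal window shows little *sustained* tonic
elevation; the $\alpha = 32$ agent, aided by sampled exploration, often
does recover within 300 trials (late, after bin ~11), so "flexible beats
every fixed agent in the final bin" does not always hold even though the
flexible agent dominates the recovery window. The learned context prior
under-concentrates relative to the idealised frequency-matching value
(no-go prior ≈ 0.7–0.9 rather than 0.9): soft postdiction leaks go-context
mass into `d` on ambiguous trials.

## Numerical choices and degenerate inputs

Probabilities are floored at $10^{-16}$ before every logarithm and inside
every KL term; $0\log(0/q) = 0$. Belief updating and the precision fixed
point iterate to relative change $10^{-6}$ with a cap of 16 iterations;
non-convergence is flagged on the trial record, never silently dropped.
Dirichlet counts below 1 are rejected at construction ($1$ is the decay
fixed point); $\alpha < 1$ is an error (it would overshoot that fixed
point). d′ uses rates clamped to $[1/2n, 1-1/2n]$ per trial-type count; a
bin with no trials of one type contributes a chance-level rate. Empty
prediction-error sets (e.g. a one-step trial) are an error, as is a
calibration with fewer than two trials. Significance statements use seeded
permutation tests (10 000 draws, label shuffling or paired sign-flips)
throughout, never parametric tests.

## Problem sizes

The shipped protocols use the study sizes throughout: 100 calibration
trials, 750 training trials, 2000 static trials, 300-trial reversals and
150-trial bandit sessions repeated 50 times per agent. A full protocol run
(calibration, training, static session) takes on the order of ten seconds;
the complete repeated-measures batteries run in a few minutes.

## What the generator emulates — and what it does not

All data are self-generated: the environment draws contexts, cues and
rewards from the configured Bernoulli rates, with contingency changes only
at scheduled trial boundaries. This emulates a fully stationary-by-blocks
task world with exact emission probabilities and one-second steps. It does
not emulate motor timing, variable inter-trial intervals, satiety or
motivation drifts, sensory noise within an observation channel, or any
biophysics of LC neurons (the spiking unit is a Bernoulli read-out of the
prediction error, nothing more). Passing tests therefore show that the
belief-updating machinery produces the reported phenomenology under the
stated task statistics — not that real LC recordings would match these
traces quantitatively.
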