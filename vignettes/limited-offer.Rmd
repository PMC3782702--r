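---
title: "Active inference in the limited-offer game: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active inference in the limited-offer game: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinf)
```

## The model

`actinf` implements discrete-state active inference: perception, action
selection and confidence are treated as a single approximate-inference
problem on a Markov decision game. The agent's generative model
(`generative_model()`) has

* hidden states $s_t \in \{1,\dots,J\}$ emitting outcomes through a
  column-stochastic observation matrix $A$;
* control states (beliefs about action) $u_t \in \{1,\dots,K\}$ selecting
  column-stochastic transition kernels $B(u_t)$, optionally one kernel per
  trial for time-dependent contingencies;
* a goal prior $c$ over final states, with the *utility* of a final state
  defined as $\log c$; raw utilities supplied by the user are passed through
  a softmax so that $c$ is always a proper distribution;
* an initial-state prior $d$ and a horizon $T$ in trials;
* a gamma prior $\Gamma(\alpha, \beta)$ over the *precision* $\gamma$ of
  beliefs about policies.

A *policy* is a control sequence from the current trial to the horizon. For
irreversible games with absorbing accepted states the allowable set is
pruned to "choose exactly once" sequences (`enumerate_policies()`), reducing
the count from $K^{T-t+1}$ to $(K-1)(T-t+1)$; an explicit user-supplied
policy list overrides the pruning. The value of policy $i$ from state $j$ is
the negative Kullback–Leibler divergence from the predicted final-state
distribution $T(\pi=i)_j$ (the chronological composition of the policy's
kernels, `compose_transitions()`) to the goal prior:

$$Q_{ij} = \underbrace{H[T(\pi = i)_j]}_{\text{entropy bonus}} +
\underbrace{T(\pi=i)_j^\top \log c}_{\text{expected utility}} \le 0.$$

Both terms are inner products of an elementwise-log vector with a
probability vector; this is the only parse of the value expression under
which the KL decomposes exactly into entropy plus expected utility, and
`compute_value_matrix()`/`decompose_value()` maintain $Q = H + EU$ to
machine precision.

## The variational updates

With a mean-field factorization over past states, future policies and
precision, coordinate-wise variational updates take a fixed-point form
(`iterate_to_convergence()`, per trial, in this order):

1. **Perception** — $\hat s_t = \sigma(\log A^\top o_t +
   \log B(a_{t-1})\,\hat s_{t-1} + \hat\gamma\, Q^\top \hat\pi)$. The last
   term is an optimism bias: high precision pulls perception toward states
   from which valuable policies are available. At the first trial the
   empirical prior is $\log d$.
2. **Action selection** — $\hat\pi = \sigma(\hat\gamma\, Q\, \hat s_t)$, the
   softmax choice rule with the expected precision as inverse temperature.
3. **Evaluation** — $\hat\beta = \beta - \hat\pi^\top Q\, \hat s_t$ and
   $\hat\gamma = \alpha/\hat\beta$. Because $Q \le 0$, precision is bounded
   by $\alpha/\beta$ and attains the bound exactly when the goal
   distribution is fully attainable (zero expected divergence).

Each softmax normalizes over its own support (states for $\hat s$, policies
for $\hat\pi$). Sweeps repeat until the largest absolute change over all
sufficient statistics falls below `tol` or `max_iter` is reached; hitting
the cap flags rather than errors, because the per-sweep precision series is
itself an analysis target (`deconvolve_precision()`).

The closed loop (`run_game()`) alternates inference with action: the
executed control is the argmax of the posterior control marginal by default
(ties to the lowest index, for reproducible traces), or a seeded draw in
`sampled` mode, which is the literal reading of action as sampled from
posterior beliefs about control.

## The free-energy oracle

`free_energy()` evaluates the variational bound by enumerating every
hidden-path/policy configuration, and `enumerate_evidence()` marginalizes
the same measure — both refuse problems above a configuration cap (default
$10^6$), as they exist to audit small models, not to scale. Two conventions
make the audit exact:

* The empirical-prior term in perception is the mean-field expectation
  $E_q[\log B]$ (elementwise $\log B$ times $\hat s_{t-1}$), not
  $\log(B \hat s_{t-1})$; with this reading each sweep is an exact
  coordinate-descent step on the enumerated free energy at fixed precision,
  which the test suite verifies numerically (monotone descent, bound, and
  tightness on models whose posterior factorizes).
* The Boltzmann factor $\exp(\gamma Q)$ coupling policies to the current
  state is normalized by a single global constant over (policy, state)
  pairs. A per-state normalizer would add a state-dependent term the
  fixed-point updates do not carry.

With precision inferred rather than fixed, the gamma factor is handled
within its conjugate family: the energy uses the posterior mean
$\hat\gamma$ and the divergence
$\mathrm{KL}[\Gamma(\alpha,\hat\beta)\,\|\,\Gamma(\alpha,\beta)]$ is added.
The log-normalizer of the Boltzmann factor is evaluated at $\hat\gamma$
rather than integrated over the gamma posterior; this is an approximation,
which is why the oracle tests clamp precision.

## Numerical choices

* **Log floor.** Probabilities inside value and empirical-prior logarithms
  are clamped at $e^{-16}$: absorbing chains produce exact zeros, and the
  floor turns them into bounded penalties rather than infinities.
* **Hard observation evidence.** The observation likelihood is *not*
  clamped: a state that cannot generate the observed outcome receives
  $-\infty$ and is vetoed outright (`softmax()` accepts $-\infty$ entries).
  This matters. With a clamped likelihood, the optimism bias
  $\hat\gamma\,Q^\top\hat\pi$ — which scales with $\alpha$ times the
  utility range — can exceed the finite penalty for contradicting a
  noiseless observation, creating a second, "delusional" fixed point in
  which the agent believes it holds the high offer while observing the low
  one. That bistability makes the marginal-utility surface discontinuous in
  the high-offer utility, and no finite floor removes it for all utilities.
  False perceptual inference belongs to the regime of pathologically high
  precision, not to a calibrated model observing noiselessly; treating
  zero-likelihood states as impossible removes the artifact for every
  utility while leaving genuinely ambiguous (noisy-likelihood) inference
  untouched.
* **Convergence.** `tol = 1e-4` on the max-change norm and `max_iter = 32`
  sweeps; both configurable. The games here converge in 2–8 sweeps per
  trial, so the cap leaves ample room for the deconvolution analysis to see
  dynamics.
* **Deconvolution.** A causal discrete exponential kernel
  $k(i) = e^{-(i-1)/\tau}$ with $\tau = 8$ iterations; the square
  lower-triangular least-squares system is solved by QR, so the round-trip
  residual is numerically zero and is reported as such.

## The limited-offer game

`build_limited_offer()` constructs the worked example: five hidden states
(low offer, high offer, no offer, accepted low, accepted high), two
controls (stay, accept), horizon $T = 16$, identity observation matrix, and
initial state the standing low offer. On leaving trial $t$ under "stay" the
low offer is withdrawn with hazard $r_t = 1 - (1 - 1/16)^t$ and becomes a
high offer with $q_t = (1 - r_t)\,(1 - (1/2)^{1/16})$, calibrated so the
cumulative probability of a high offer over the horizon, conditional on no
withdrawal, is exactly one half. Goal utilities default to
$(1, 1, 1, 2, 4)$, so the agent believes the accepted-high outcome
$e^{2} \approx 7.39$ times more probable than accepted-low, itself
$e \approx 2.72$ times more probable than not accepting. The precision
prior is $\Gamma(8, 1)$.

Decisions the construction had to take where the game description leaves
room:

* **Hazard timing.** Kernels are indexed by the trial being left, so
  $r_1 = 1/16$ is the first withdrawal risk.
* **High-offer persistence.** Once made, the high offer is absorbing under
  "stay": sustained maximal confidence after the offer, as the scripted
  realizations show, is incompatible with a withdrawable high offer, and no
  high-offer hazard is specified.
* **Scripted realizations.** `limited_offer_schedule()` forces the true
  state at a given trial (high offer at 11, or withdrawal at 5); trials off
  the script follow the argmax of the executed action's kernel column, so a
  scripted run is fully deterministic. A scripted transition the kernel
  cannot generate warns but is honored — the script is the experimenter's.
* **Precluding action** (for the sweeps) forces "stay" in the environment
  while inference and choice probabilities run untouched;
  **precluding withdrawal** zeroes $r_t$ in the kernels.

## What the experiments compute

`sweep_low_offer_utility()` re-runs the game over accepted-low utilities
0–8 (the printed range, at unit steps) with withdrawal and action
precluded, once with the full value and once with the entropy term removed,
and reports per-trial acceptance probabilities, latency distributions
(`latency_distribution()`: compounded waiting times acceptance, with the
never-accept residual), and mean latencies with the residual censored one
trial past the horizon.

Because every allowable policy accepts exactly once, the latency
distribution always places some mass before the final trial — at low
utilities simply because low precision flattens the choice distribution.
A "probability of early acceptance exceeds waiting" rule therefore fires
at utility 0 and is non-monotone in the utility, and does not identify the
point at which the low offer becomes worth taking. `crossing_utility()`
instead compares expected utilities directly: the smallest grid utility at
which accepting the standing low offer immediately is at least as good, in
expected utility, as every policy that waits for a high offer. Under the
default goal prior this crossing is at 4, where the accepted-low and
accepted-high utilities coincide; below it every waiting policy strictly
dominates. The entropy bonus, which rewards keeping options open, delays
the mean latency at every grid point; under the censored-mean measure the
delay is largest slightly above the ambiguous point (at utility 5 on the
unit grid, with utility 4 close behind).

`entropy_utility_timecourse()` tracks, per trial of an action-precluded run
in which the low offer stays on the table, the stay/accept marginal and its
entropy, and the entropy and expected-utility components of the value
expected under the converged beliefs. Choice entropy peaks where the
marginal is closest to 50–50; the expected-utility component is lower the
more trials intervene before the horizon — temporal discounting induced
purely by the withdrawal hazard in the prior.

`marginal_utility_curves()` sweeps the accepted-high utility 2–8 (steps of
0.5) with withdrawal and action precluded and evaluates the marginal
(precision-weighted) utility $\hat\gamma \log c$ of accepting either offer
at every trial. As the high-offer utility grows its goal-prior probability
saturates while precision rises ever more slowly, so the magnitude of the
marginal utility is convex decreasing — diminishing returns — approaching
its maximum at zero. The convexity assertion in the tests is on the
magnitude (equivalently, the signed curve has non-positive second
differences); the signed marginal utility is negative and saturates at
zero from below.

## What the generator does and does not emulate

The game is a fully specified synthetic environment: hazards, utilities and
schedules are exact model inputs, observation is noiseless, and scripted
runs are deterministic. Passing tests therefore certify the inference
scheme and the game's analytic structure — precision bounds, value
decompositions, hazard calibration, the free-energy bound — not behavior on
noisy or misspecified worlds: there is no sensory noise (the identity
observation matrix makes perception trivial except for the optimism bias),
no learning of kernels or goal priors, and the true process shares the
agent's kernels unless the user supplies different ones (allowed, but
logged as a modeling mismatch of interest).

## Problem sizes

The default suite and the reproduction script run the 5-state, 16-trial
game (16 policies at most per trial, converging in a handful of sweeps),
9- and 13-point utility grids, and enumeration oracles on 2–3-state,
1–2-trial models — seconds of compute in total, chosen because every
quantity of interest is already exact at this scale.

## Known limitations

* Past-state beliefs are frozen when their trial ends (filtering); there is
  no retrospective smoothing.
* Precision enters other updates only through its posterior mean.
* The free-energy evaluation with inferred precision is approximate (see
  above); exact auditing requires clamped precision.
* No Dirichlet learning of model parameters, no continuous-state variants,
  and no multi-agent play.
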