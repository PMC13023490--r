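---
title: "Queue formation by projective-simulation swarms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Queue formation by projective-simulation swarms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`psnav` simulates a group of `N` identical agents navigating an unbounded
plane toward a distant target at constant speed, steering by discrete
angular increments. Each agent carries the same two-layer
projective-simulation memory: a table of experience weights `h[s, a]` over
9 percept states and `m` steering actions. Decisions are a one-step random
walk over this table,

$$P(a \mid s) = \frac{h_{s,a}}{\sum_k h_{s,k}},$$

so the policy is directly readable at any time: `policy_table()` is the
policy, and `extract_rules()` turns its rows into if-then steering rules.
That transparency — not raw task performance — is the point of the model:
once the swarm self-organizes into a travelling queue, one can open the
table and see which microscopic arbitration rules produced it.

### Percepts

Each agent senses two angles from the time-`t` snapshot of the world:

* `theta_neighbor` — the signed angle from its own heading to the
  normalized mean heading of its `k = 6` topologically nearest neighbors
  (metric-free interaction: the neighborhood has fixed size regardless of
  density);
* `theta_target` — the signed angle from its heading to the target
  bearing.

Both use the same convention (positive = counter-clockwise = the cue lies
to the agent's left) and both are discretized into three cues — 0 (right,
`theta < -pi/6`), 1 (aligned, `|theta| <= pi/6`), 2 (left,
`theta > pi/6`) — giving the percept index `3 * s_n + s_t` in 0..8.
States 2 (neighbors right, target left) and 6 (neighbors left, target
right) are the *conflict states*, where social alignment and navigation
disagree; the learned resolution of that conflict is the scientific
readout of the model.

Two degenerate cases are fixed by convention: a vanishing neighbor
average (norm below 1e-9) is treated as "aligned" (cue 1, no directional
information), and exactly antiparallel vectors take the angle `+pi`
(cue 2). Both are measure-zero and the choice only has to be
deterministic.

### Actions and kinematics

The action set is `m` symmetric angles `a_k = (k - (m-1)/2) * delta_theta`
(default `m = 15`, `delta_theta = 2` degrees, so turns span ±14°; the
middle action is exactly straight). All agents move synchronously: every
percept is computed from the same snapshot, then all agents rotate and
advance one step of length `speed = 1`. Synchrony removes any dependence
on agent iteration order.

### Reward

Each agent receives, every step,

$$R = \lambda_d\,(d_{t-1} - d_t) + \lambda_r \max(0,\ \hat v \cdot \hat T),$$

with `lambda_d = lambda_r = 0.5` by default: progress toward the target
(bounded by the step length) plus clipped heading-target alignment,
evaluated at the post-move position. There is no formation term of any
kind — elongation and alignment are never rewarded — so any queue that
appears is an emergent consequence of navigation-only incentives.

### Learning: glow and forgetting

Each agent keeps a private eligibility ("glow") matrix `g` the same shape
as the policy. Every step all glow entries decay by `1 - eta`
(`eta = 0.1`) and the edge the agent just used gains `+1`; an edge used
every step therefore saturates at `1/eta = 10`. The shared memory then
absorbs the summed, reward-weighted glow of all agents:

$$h \leftarrow h - \gamma\,(h - 1) + \textstyle\sum_i R_i\, g_i,$$

floored elementwise at `h_min = 0.01` so rows always normalize. The glow
is reset to zero at each episode start; the memory persists across
episodes.

The `gamma` term needs justification, because the bare additive rule
(`gamma = 0`, the default of the low-level `update_experience()`) cannot
converge to deterministic rules: with purely additive updates the row
sums grow linearly in time while each visit deposits a bounded amount, so
the selection probabilities change ever more slowly — an urn process
whose drift decays as `1/t`. We verified this directly: training the
default task for 3000 episodes at `gamma = 0` leaves the average policy
entropy at ~2.1 bits with an argmax pattern frozen since episode 300.
Deterministic per-state decisions, which this family of models reports
and which the interpretability analysis relies on, require the memory to
stay bounded so that reinforcement remains competitive; the standard
projective-simulation literature does this with exactly this forgetting
term, which relaxes unused weights toward their initial value 1. The
package default `gamma = 1e-4` sets the forgetting timescale to ~10,000
learning steps — several episodes — slow enough to retain navigation
skill across episodes, fast enough that within-row competition resolves.
With it, the default training protocol converges to 6-7 of 9 states
deterministic (max probability ≥ 0.9), average certainty ~0.85, average
entropy ~0.6 bits, and the two conflict states resolve to a left turn
(state 2) and a right turn (state 6): strict target priority. These
figures were stable across every training seed we ran.

## Order parameters

* **Polarization** `O_p`: norm of the mean unit heading; 1 = common
  heading, ~`1/sqrt(N)` for random headings.
* **Elongation** `O_e = L / max(W, 1)`: aspect ratio of the bounding
  rectangle aligned with the centroid's motion direction (finite-difference
  estimate; when the centroid barely moves the last valid direction is
  reused). The width floor of one body length keeps the ratio finite for
  perfectly collinear queues. Values well above 1 mean a file stretched
  along the travel direction.
* **Success**: the centroid enters a 100-unit radius of the target.
* The steady navigation window used for time-averaged metrics runs from
  the first step with `O_p >= 0.9` to the first target hit.

## Why a queue forms at all

Three ingredients interact. First, the *target-priority* conflict rules
constantly bleed agents off pure mutual alignment toward the goal, which
breaks the rotational symmetry of a Vicsek-style flock. Second, the
discretization of steering introduces an effective inertia: an agent
whose cues sit inside the ±30° "aligned" bands takes no corrective
action, so the group carries a persistent, spontaneously chiral drift
(the trained policies pick a slightly turning action, ±2°, in the
fully-aligned state — left or right depending on the run's symmetry
breaking). The resulting gently curved pursuit path shears the group
along its direction of travel. Third, as the swarm closes on a point
target the bearing cone narrows, compressing the group laterally. Queue
strength therefore grows with transit length — a group that reaches the
target after a few hundred steps never has time to string out, which is
why scaled-down protocols must not shorten the journey too aggressively
(see below). The weighted Vicsek baseline, which blends alignment and
attraction with fixed weights every step, produces none of these effects
and travels as a compact cluster (time-averaged `O_e` ≈ 2).

## Protocols and problem sizes

`navigation_protocol()` bundles two scales:

* `"full"` — the reference protocol: target (3000, 3000) (distance
  ≈ 4243 from the initial disk), 5000 training episodes of up to 10,000
  steps. On one CPU core this takes on the order of an hour with the
  compiled engine; it is the protocol behind the headline full-scale
  numbers (steady-state peak elongation ≈ 8, certainty ≈ 0.9).
* `"desk"` — the package's working scale, used by the test suite and the
  acceptance script: target (3000, 3000) kept at the reference geometry,
  episodes shortened to 6,000 steps (transit ≈ 4300 steps plus a
  post-arrival phase), and 1,200 training episodes. Training takes a few
  minutes. We deliberately do *not* shrink the target distance: the queue
  needs the transit to develop, and pilot runs with a target at ~850
  units peaked at `O_e` ≈ 3 no matter how converged the policy was. The
  episode count is set where the learning curve plateaus (certainty
  flattens near 0.87 after ~1,500 desk episodes); the post-arrival phase
  is retained in training episodes because the sharp near-target reward
  differentials are a strong teacher of the conflict rules.

Evaluation always runs fixed-length episodes (no early stop, matching
how the reference experiments are scored), freezes the memory, and
reports per-episode summaries plus aggregates. Sensory noise, when used,
is Gaussian on both perceived angles (SD in degrees), applied before
discretization, at evaluation time only.

## Numerical choices

* Probability rows are validated to sum to 1 within 1e-9.
* Argmax readouts break ties toward the smaller action index.
* `h_min = 0.01` floors the memory after every update; without it a run
  of negative rewards could zero a row and break normalization.
* Distance ties in the k-nearest-neighbor search go to the smaller agent
  index (and the compiled and interpreted engines implement the same
  rule, verified bit-for-bit).
* The compiled episode engine draws from R's global RNG stream in the
  same order as the reference R loop, so seeded runs are identical across
  engines and across platforms with the same RNG.

## What the simulations do and do not show

Everything here is simulation of an idealized point-agent swarm: no
collisions or body exclusion, no metric interaction radius, no obstacle
fields, no speed variation, and a shared policy (population-level
learning rather than individual cognition). Passing tests show that the
learning rule, percept geometry and order parameters interact as
described under these idealizations — they say nothing about sensor
physics or embodiment of real animals or robots. The sensitivity sweeps
(action granularity, reward weights) and the robustness suites (sensory
noise, moving target, rotated targets, larger groups) probe the model's
own parameter space, not field data.

Known limitations worth keeping in mind:

* The rapid-alignment claim (`O_p` ≈ 0.99 within 100 steps) is only
  approximately reproduced at desk scale (~0.98): the ±30° aligned band
  caps how tightly uncorrelated headings can align, and the collective
  chirality lock that beats the cap takes longer than 100 steps to
  establish at moderate training budgets.
* Noiseless peak elongation at desk scale sits near the bottom of the
  full-scale range and fluctuates strongly between episodes; moderate
  sensory noise actually *strengthens* the queue by breaking the wide
  front, so the noise robustness results are not a degradation story at
  this scale.
* With `gamma > 0` the memory slowly forgets unvisited states; very long
  evaluation-only deployments are unaffected (evaluation never updates
  the memory), but resumed training after a long pause re-learns rare
  states.
* The often-cited non-monotonic effect of action granularity (moderate
  `m` best, coarse and fine both worse) does *not* reproduce at desk
  scale under the bounded-memory update: at 400 and at 1000 desk
  episodes, `m = 5`, `15` and `29` all evaluate at average polarization
  ~0.95. This is consistent with the granularity effect being largely a
  *learnability* phenomenon of the purely additive update — under
  frozen-urn dynamics a 5-action table converges orders of magnitude
  faster than a 29-action one, so at a fixed episode budget coarse
  policies look crisp and fine ones look random. Once the memory is
  bounded and every granularity converges, the macroscopic differences
  at this scale are within noise. `sweep_granularity()` reports whatever
  the simulation produces; the package makes no attempt to steer the
  ordering.
```
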