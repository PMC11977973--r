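---
title: "Exact stochastic simulation with delayed reactions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact stochastic simulation with delayed reactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaysim)
```

## The model class

`delaysim` samples exact realisations of well-mixed chemical systems. A
network is a set of species with counts $n \in \mathbb{N}^d$ and reactions
$r$ with propensities $f_r(n)$: $f_r(n)\,dt$ is the probability that
reaction $r$ fires in $[t, t+dt)$. Three matrices describe the system, each
with one row per species and one column per reaction: the *reactant matrix*
$\nu$ (stoichiometric orders, used by mass-action propensities), the
*immediate change matrix* $S$ applied when a reaction fires, and the
*delayed change matrix* $S^{delay}$ applied when the reaction's delay
$\tau_r$ elapses.

Mass-action propensities use the combinatorial convention
$f_r(n) = c_r \prod_i \binom{n_i}{\nu_{ri}}$ — e.g. $c\,n(n-1)/2$ for a
homodimerisation, not $c\,n^2$ — because that is the convention under which
the simulation is exact for the chemical master equation (CME). States with
$n_i < \nu_{ri}$ have propensity exactly zero. Propensities may also be
arbitrary nonnegative functions of the state. This extension is required in
practice: regulatory-network models are usually written with Hill terms,
which are not mass-action. The AST network below is the motivating case.

## Delayed reactions

Two delay classes are supported, following the standard taxonomy:

* **consuming** — the state is adjusted twice: $S_{\cdot r}$ at initiation
  (typically removal of reactants), $S^{delay}_{\cdot r}$ at completion
  $t + \tau_r$ (typically appearance of products);
* **completion-only** — nothing changes at initiation; the whole net change
  is applied at $t + \tau_r$.

$\tau_r$ is either a constant (model time units) or drawn afresh from a
user-supplied sampler at every firing. Scheduled completions are kept in a
time-ordered pending-event queue — the memory that makes the process
non-Markovian. Ties in completion time pop first-in-first-out, and a
completion that coincides exactly with a sampled firing executes first:
completions were committed in the past, and the deterministic ordering keeps
runs bit-reproducible.

A subtlety of completion-only reactions is that their reactants remain
visible to the propensity during the delay, so a reaction such as delayed
degradation can initiate more removals than there are molecules. We chose
*not* to check reactant availability at initiation (the class is defined by
"no change at the start of the delay"); infeasibilities are instead handled
by conflict resolution, below. The practical consequence — worth knowing
when building models — is that a completion-only conversion $X \to Y$ of a
*conserved* reactant keeps re-initiating until a completion wins the race;
for delayed degradation (the common use) the dynamics are the intended
ones.

### Conflict resolution

Non-delayed reactions can invalidate scheduled changes: if fast degradation
consumes a molecule whose delayed removal is already scheduled, executing
that removal later would drive the count negative. The rule implemented is
to *randomly remove one of the conflicting pending events*, repeatedly,
until the update is feasible; removed events never execute.

Concretely, the queue maintains, per species, the total *committed pending
decrement*. An update is feasible iff it leaves every species with at least
its committed decrement. Under this invariant a completion can never drive
a count negative (if $n_s \ge C_s$ before popping an event that removes
$k$ from $s$, then $n_s - k \ge C_s - k \ge 0$), so every conflict
surfaces at firing/scheduling time, where it is repaired by removing one
uniformly chosen pending event that decrements a deficit species. The
uniform choice is our reading of "randomly"; the removal is one event at a
time with feasibility rechecked. If no removable event exists the model is
inconsistent and the simulation errors rather than clamping.

## The six engines

Non-delay engines: the Gillespie **direct** method; the **first-reaction**
method; and Anderson's **modified next reaction** (MNR) method with
per-reaction internal clocks $T_k$ and unit-exponential thresholds $P_k$.
We implement MNR (rather than the Gibson–Bruck next-reaction variant)
because its delay extension is the natural third delay engine.

Delay engines share the queue and differ in how the next firing is drawn:

* **delay_rejection** — draw a tentative $\Delta t \sim \mathrm{Exp}(a_0)$;
  if a completion intervenes, advance to it, apply it and redraw (exact by
  memorylessness);
* **delay_direct** — solve for the waiting time by integrating the
  piecewise-constant total propensity across completion times, applying
  each completion and re-evaluating propensities exactly (no
  interpolation);
* **delay_mnr** — MNR clocks, next event is the earlier of the earliest
  internal firing and the earliest completion.

All six are distributionally equivalent on networks they both support; the
suite checks this by pairwise Kolmogorov–Smirnov tests and, on truncatable
networks, against the CME solved by matrix exponentiation of the truncated
generator.

Output is the state sampled onto a user grid (piecewise-constant: the state
at grid time $t$ is the state after all events with time $\le t$), which
bounds memory on long runs; raw event logs are not retained. Two design
points are deliberate: an exhausted system ($a_0 = 0$, empty queue) freezes
silently to the horizon, because absorbing states are legitimate model
behaviour; and no automatic "steady state reached" stopping rule is
offered, because such a rule is ill-defined for a fluctuating jump process
— only `t_final` terminates a run. Ensembles derive replicate $i$'s seed as
`seed + i - 1`, so individual trajectories can be reproduced in isolation.

## Worked models and their oracles

**Bursty transcription.** Bursts arrive at frequency $\alpha$ with
geometric size ($k \ge 1$, mean $b$); every molecule of a burst is removed
exactly $\tau$ later. The burst-size law is encoded as a truncated family
of reactions $\varnothing \to k M$ with rates
$\alpha b^k/(1+b)^{k+1}$, truncated where the residual tail mass drops
below $10^{-6}$ (configurable); this preserves the matrix formalism, and a
single firing schedules one $-k$ completion. The paper source states only
the mean burst size; geometric is the standard choice for bursty
expression. Oracles: the truncated total rate equals
$\alpha(1 - 1/(1+b))$, the production rate $\alpha b$, and by Little's law
the stationary mean is $\alpha b \tau$ ($= 11.709$ at the printed
$\alpha = 0.0282$, $b = 3.46$, $\tau = 120$).

**Refractory promoter.** The unidirectional cycle
$G_0 \to G_1 \to G_2 \to G_0$ (rates $k_1, k_2, k_3$) is the standard
refractory construction — three printed rate constants force exactly three
transitions. Transcription $G_2 \to G_2 + M$ at rate $k_4$; each $M$ lives
exactly $\tau$. Renewal-cycle occupancy gives
$P(G_2) = (1/k_3)/(1/k_1 + 1/k_2 + 1/k_3) = 0.5455$ at the printed rates,
hence a stationary mean $k_4 \tau P(G_2) = 5.455$, with a bimodal marginal
whose global mode is zero (long silent $G_0/G_1$ periods).

**RNA velocity.** $\varnothing \to U$ at $\alpha$, $U \to S$ at $\beta$,
$S \to \varnothing$ at $\gamma$ (optionally completion-only delayed by
$\tau$). Phase 1 runs to `t_switch`, then $\alpha$ is set to zero with the
state *and the pending queue* carried across the switch. Defaults
$\alpha = 20$, $\beta = 1$, $\gamma = 0.5$, `t_switch` $= 50$ are our
choices (the figure caption of the source is garbled beyond the switch
time); only the qualitative claims — phase-1 means $\alpha/\beta$,
$\alpha/\gamma$, decay to the origin, and the two-arc U–S loop — are
asserted quantitatively in the suite.

**AST network.** The four-gene FOXA2/NKX2-1/P63/SOX2 circuit is published
as concentration ODEs. With $B = V N_A$ (molecules per concentration unit;
$B = 6023$ at $V = 10^{-20}$ L with the conventional rounded
$N_A = 6.023 \times 10^{23}$), the exact rescaling $X = xB$ turns
$\dot x = f(x)$ into $\dot X = B f(X/B)$; `convert_concentration_model()`
implements precisely this, and with $B = 1$ it is the identity. The
stochastic model has one production reaction per species whose custom
propensity is the molecule-based Hill term (SOX2's self-activation and
basal production combined into one), plus linear degradations. Bistability
is assessed two ways: deterministically, by integrating the molecule-based
ODEs from random starts and clustering endpoints (`count_attractors`), and
stochastically, via the quasi-potential landscape. The SOX2 degrader is a
completion-only reaction with propensity $k_{deg} S$ and delay
$\tau_S = 1$ (printed). $k_{deg}$ is not printed; we set the default
$k_{deg} = 1$ from the deterministic skeleton — an added effective SOX2
degradation of $1$ (total $1.4$) removes the squamous attractor at
$\alpha_S = 0.8$ with a wide margin (any value $\gtrsim 0.3$ suffices), so
the choice is not delicate.

## Landscape estimation

Pooled late-time ensemble states of two chosen species are binned on a 2-D
grid; the normalised occupancy $P$ yields the quasi-potential approximation
$U = -\ln(P + \varepsilon)$. The pseudo-frequency
$\varepsilon = 1/(2n)$ (half the weight of one sample) keeps $U$ finite on
empty bins with bias vanishing in $n$. Minima are bins strictly below all
8 neighbours, with boundary bins excluded (sparse-histogram edge
artifacts). Because $U$ is a monotone relabeling of $P$, bin rankings by
$U$ and by $-P$ coincide exactly — a property the suite asserts.

`count_attractors` integrates with `deSolve::lsoda` at relative tolerance
$10^{-8}$ to $t = 200$ by default, excludes starts still moving over the
last 10% of the horizon, and merges endpoints within a radius of $0.05 B$
molecule units; all configurable. Attractor sets are stable across seeds
for the AST parameterisations; only basin counts fluctuate.

## What the synthetic conditions do and do not show

The generators above reproduce the study conditions exactly where printed
(Bursty and Refractory parameters, AST parameters and $B$, $\tau_S$) and
otherwise use the defaults stated here. They emulate well-mixed, constant-
volume kinetics with deterministic or sampled delays. They do not emulate
extrinsic noise, cell growth/division, or measurement noise in real
single-cell data — so passing tests demonstrate correctness of the
samplers and faithfulness to the stated models, not fit to any dataset.

## Problem sizes and numerical choices

The suite and the acceptance script use: $10^5$ pooled stationary samples
for the Bursty mean (20 trajectories, snapshots every 40 time units after a
burn-in of 1000 — snapshot spacing is set against the correlation time
$\tau = 120$); $10^4$ samples for the Refractory mean (spacing 10) and for
the delayed-Poisson law (spacing 2 $= \tau$, giving effectively independent
draws); $10^4$ endpoint samples per engine for the CME total-variation
check (truncation at 60 states, where the neglected mass is
$< 10^{-10}$); $2 \times 10^3$ trajectories per RNA-velocity variant; 100
random starts per $\alpha_S$ for attractor counting; and 10 trajectories
from the squamous state, snapshots on $t \in [6, 10]$, for the degrader
landscape (collapse of S is fast, time scale $\approx 1/1.4$). The
law-of-large-numbers comparison of AST ensemble means against the
molecule-based ODE runs at $B = 600$ with 40 trajectories — the $B$-scaling
itself is exact algebra and is tested separately at $B = 6023$.

Engine internals are pure R. Two implementation choices matter for
throughput and are invisible to results: RNG draws are consumed from
buffered blocks, and the pending queue is a time-sorted array with
tombstone deletion, making constant-delay scheduling, popping and
conflict cancellation O(1) amortised; cancellation candidates are drawn by
rejection sampling, which is O(1) exactly in the conflict-heavy regime
where most queued events decrement the deficit species.

## Known limitations

* No approximate accelerations (tau-leaping, hybrid ODE–SSA) — exact
  sampling only.
* Completion-only reactions over-initiate against conserved reactants (see
  above); model conversions of that shape as consuming.
* Landscapes are 2-D only, and the quasi-potential is the histogram
  surrogate $-\ln P$, not a minimum-action potential.
* `count_attractors` sees only attractors reachable from its initial box
  and can merge attractors closer than `merge_radius`.
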