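---
title: "Co-evolution of classical and quantum prisoner's dilemmas on coupled scale-free networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-evolution of classical and quantum prisoner's dilemmas on coupled scale-free networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpdnet)
```

## The model

`qpdnet` simulates two populations of imitating agents that play different
games on different networks but are tied together economically.

**Layer 1 (classical PD).** Each node plays the weak prisoner's dilemma with
every network neighbour: mutual cooperation pays $R = 1$, defecting on a
cooperator pays the temptation $T = b \in [1, 2]$, and both the sucker's
payoff and the punishment are zero ($S = P = 0$). Defection is the strict
Nash equilibrium for $b > 1$.

**Layer 2 (simplified QPD).** The quantum extension adds a third strategy,
super cooperation $Q$, whose payoffs depend on the entanglement degree
$\gamma \in [0, \pi/2]$:

$$A(b, \gamma) \;=\; \begin{pmatrix}
 & C & D & Q \\
C & 1 & 0 & \cos^2\gamma \\
D & b & 0 & b\cos^2\gamma \\
Q & \cos^2\gamma & b\sin^2\gamma & 1
\end{pmatrix}$$

Four structural features drive everything below: (i) at $\gamma = 0$, $Q$ is
payoff-identical to $C$ and the game is a plain PD; (ii) $C$ and $Q$ have
equal status against each other (both earn $\cos^2\gamma$); (iii) against
$D$, $Q$ earns $b\sin^2\gamma$ while $D$ earns $b\cos^2\gamma$, so
entanglement progressively starves defectors; (iv) $Q$ is a strict Nash
equilibrium — hence an ESS — exactly when $b\cos^2\gamma < 1$, i.e. for
$\gamma > \arccos(b^{-1/2})$ (`q_equilibrium_analysis()`; the boundary
$b\cos^2\gamma = 1$ is classified as not strict, because strictness is what
guarantees evolutionary stability).

**Topology and coupling.** Both layers are Barabási–Albert graphs of $N$
nodes grown from a complete core of $m$ nodes, each arrival attaching $m$
edges preferentially by degree (`generate_ba()`). Layer 2 is by default a
structural copy of layer 1 ("identical networks"); an `independent` mode
redraws it. A uniformly random bijection matches each node to one partner in
the other layer (`couple_layers()`). Partners never play games with each
other; they only share utility:

$$U_x = P_x + \alpha P_{x'}$$

where $P_x$ is the node's accumulated payoff against its own-layer
neighbours, $P_{x'}$ the matched partner's, and $\alpha \in [0, 1]$ the
coupling factor. At $\alpha = 0$ the layers are completely independent.

**Dynamics.** Asynchronous Fermi imitation: an elementary event picks a
focal node uniformly on one layer, one of its neighbours uniformly, and the
focal node adopts the neighbour's strategy with probability
$W = 1/(1 + \exp((U_x - U_y)/K))$, $K = 0.1$. One Monte Carlo step (MCS)
interleaves $N$ such events on each layer (layer 1, layer 2, layer 1, ...),
so every player is updated once per MCS on average. Strategy fractions are
recorded each MCS; the stationary value is the mean over the trailing
window (1000 MCS by default).

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `b` | temptation of defection | — | dimensionless, $[1, 2]$; both endpoints simulated |
| `gamma` | entanglement degree | 0 | radians, $[0, \pi/2]$ |
| `alpha` | inter-layer coupling | 0 | $[0,1]$; 0 = independent layers |
| `k_noise` | Fermi selection noise $K$ | 0.1 | outcomes are qualitatively insensitive to it |
| `n`, `m` | BA size / attachment | 5000, 2 | $\langle k\rangle \approx 2m$ |
| `mcs_total`, `window` | horizon / stationary window | 5e4, 1000 | fixed horizon, no convergence testing |
| `realizations` | ensemble size | 100 | each redraws topology, matching, init |

The defaults are the full study conditions; `scale_profile(cfg, "desk")`
switches to the reduced scale used throughout the test suite
(N = 1000, 1e4 MCS, 10 realizations).

## Design choices where the design was open

**Utility convention.** The published description of the model states only
that utilities correlate a node's payoff with its partner's and that
$\alpha = 0$ decouples the layers. Two standard forms from the
interdependent-network literature satisfy this: additive
($P_x + \alpha P_{x'}$) and convex ($(1-\alpha)P_x + \alpha P_{x'}$). Both
are implemented (`utility_convention`). The additive form is the default
because it reproduces the three benchmark stationary fractions
($\rho_Q = 0.8270$, $0.8879$, $0.8095$; see the acceptance script), whereas
the convex form degenerates at $\alpha = 1$: utility then equals the
partner's payoff alone, a node's utility no longer depends on its own
strategy, and the dynamics collapses to neutral drift
(desk-scale $\rho_Q \approx 0.24$ instead of $\approx 0.89$).

**Payoff freshness.** The sequential wording of the update protocol is
ambiguous about whether payoffs are recomputed at every imitation event or
once per MCS. The default recomputes fresh at every event (the standard
asynchronous convention, implemented exactly via incrementally maintained
payoff arrays); a `frozen` mode recomputes once per MCS for sensitivity
analysis. At desk scale the two agree on direction everywhere we measured,
with frozen values shifted up by 0.03–0.05 at maximum entanglement.

**Interleaving.** Strict alternation of layers within an MCS is the
default; a `shuffled` mode randomizes the order of the $2N$ events as a
robustness check.

**Mean degree.** The source description leaves $\langle k\rangle$
unstated; $m = 2$ ($\langle k\rangle \approx 4$), the standard choice in
this literature, is the default. Sensitivity was measured rather than
assumed away: with $m = 3$ or $m = 4$ the benchmark points collapse
($\rho_Q \approx 0.19$–$0.25$ at the $\alpha = 1$ points), confirming
$m = 2$.

**RNG streams.** One master seed spawns seven named streams (two topology,
matching, two initializations, one dynamics stream per layer). Because the
layers draw from separate dynamics streams, with $\alpha = 0$ the layer-1
trajectory is *bit-identical* across runs that differ only in $\gamma$ —
the strong, exactly testable form of layer independence.

## What the generated data emulate — and what they do not

All inputs are synthetic by design: BA topologies, a random matching and
uniform initial strategies are the study conditions themselves, not a stand-in
for field data. The desk profile reproduces the full-scale model at reduced
$N$ and horizon, which preserves every qualitative effect we test (the $b$-,
$\alpha$- and $\gamma$-monotonicities, defector extinction and C–Q
coexistence at $\gamma = \pi/2$) but shifts one class of quantitative
results, as follows.

At $\gamma = \pi/2$ the QPD layer, once defectors die out, is a
coordination game between $C$ and $Q$ on a heterogeneous graph: whichever
strategy holds the hubs takes over, and single realizations fixate at
all-$Q$ or (rarely) all-$C$. Ensemble-mean fractions such as
$\rho_Q = 0.8270$ are therefore averages over a bistable outcome, and
carry binomial noise $\sqrt{p(1-p)/R}$ across $R$ realizations. The
probability of $C$-fixation falls with network size (measured
$\approx 0.27$ at $N = 1000$ against $\approx 0.10$ at $N = 5000$), so the
desk-scale mean at $b = 1$, $\alpha = 1$ sits near 0.74–0.79, below the
full-scale value: a finite-size effect, not a dynamical difference. A
20-realization run at the full scale ($N = 5000$, $5 \times 10^4$ MCS)
gives $0.888 \pm 0.067$ for that point, consistent with the benchmark.
The corresponding desk-scale assertion in the test suite is deliberately
left failing at its $\pm 0.06$ band rather than widened.

## Numerical choices

* Payoff matrices are evaluated from the trig formulas in double precision;
  no rounding anywhere.
* The Fermi probability saturates cleanly ($\exp$ overflow yields 0/1,
  never NaN).
* The engine maintains accumulated payoffs incrementally: flipping one node
  updates its own and its neighbours' payoffs in $O(\deg)$, which is exact,
  so each imitation event costs $O(1)$ utility evaluations.
* Degenerate inputs: isolated focal nodes (possible only in user-supplied
  graphs) skip their update and are counted in the trajectory's `skips`
  attribute; monomorphic layers are absorbing, which the engine preserves
  exactly.
* Replicator dynamics (`replicator_trajectory()`, the well-mixed baseline)
  uses fixed-step RK4 with step-halving validation; approach to the pure-D
  vertex of the PD is algebraic ($\sim 1/t$, since $S = P = 0$), so
  attractor tests there use wider tolerances than at exponentially stable
  strict equilibria.
* Exact one-step enumeration (`enumerate_step_distribution()`) refuses
  layers above 8 nodes; it is an oracle, not a solver.

## Worked example

```{r example, eval = FALSE}
cfg <- scale_profile(simulation_config(b = 1.5, gamma = pi / 2, alpha = 0.8,
                                       seed = 1), "desk")
traj <- simulate_coupled(cfg)
stationary_fractions(traj, cfg$window)
ens <- simulate_ensemble(cfg)
ens
whole_network_cooperation(ens$mean)
```

Sweeps reproducing the published figure layouts are one call away
(`run_sweep(figure_preset("fig2"))`), and `inst/cli/qpdnet` exposes the
same operations from a shell.

## Known limitations

* Only imitation dynamics: no mutation, so absorbing states are forever;
  stationary values at high $\gamma$ are fixation statistics, not mixing
  averages.
* Only BA presets; other topologies enter via edge-list files.
* No pair-approximation or mean-field closure beyond the replicator
  baseline; no spatial cluster statistics.
* The continuous-strategy quantum game (unitary strategy operators) is out
  of scope; only the three-strategy simplification is implemented.
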