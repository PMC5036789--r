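---
title: "Steady-state sensitivity analysis of signed signalling networks"
author: "netsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state sensitivity analysis of signed signalling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsens)
```

## The model

`netsens` studies how the basal ("independent") activity of each protein
in a signed signalling network controls downstream readouts. A network is
a directed graph whose edges are activating (`->`) or inhibiting (`-|`);
each node `i` carries a basal activity `beta_i` (arbitrary relative
units) and evolves by

```
dx_i/dt = beta_i * A_i(x) * I_i(x) - gamma * x_i
```

where `A_i` aggregates Hill-type transfer terms
`w_e * x_s^h / (K^h + x_s^h)` over the node's activators (the mean by
default, so redundant activators saturate rather than add; `sum` is
available) and `I_i` is the product of complementary terms
`1 - w_e * hill(x_s)` over its inhibitors (AND-NOT logic: any strong
inhibitor can shut production down). A node without activators has
`A_i = 1`, so a *source* node settles at `beta_i / gamma`: `beta` is
exactly the activity the node would sustain on its own, which is what
makes it the natural perturbation parameter. Endpoint nodes
(the readouts — in the shipped NPM-ALK model, *Proliferation* and *Cell
Survival*) carry a fixed production scale `endpointBeta = 1`, so their
steady state purely reflects upstream input; they are never enumerated
as control nodes.

This phenomenological form integrates qualitative
activation/inhibition knowledge into a quantitative, bounded, smooth
model without requiring kinetic measurements. It is one concrete choice
among the family of Hill-type network formalisms: whether activators
combine additively or multiplicatively, and whether `beta` enters as a
production scale or a saturation ceiling, are genuinely open modelling
decisions; ours (mean aggregation, `beta` as production scale) keeps
every steady state inside `[0, beta_i/gamma]` and makes source nodes
interpretable, and is documented rather than claimed canonical.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `hillCoef` (h) | 2 | — | cooperativity of each link; `h = 2` gives mild sigmoidality without switch-like bistability at the activity scales used |
| `halfSat` (K) | 0.5 | activity | input level at which a link half-saturates |
| `degradation` (gamma) | 1 | 1/time | sets the time unit; source steady state is `beta/gamma` |
| `endpointBeta` | 1 | activity | production scale of readout nodes |
| `beta` low / high | 0.001 / 0.1 | activity | the two coarse-grained basal levels (a 100-fold change) |

With these defaults the network operates well below `K`, where the Hill
kernel is nearly quadratic. Signals therefore *attenuate* as they hop
across nodes, which reproduces two qualitative features of the
coarse-grained analysis: most nodes sit in a negligible-sensitivity
plateau, and the few influential nodes are those adjacent to strong
sources or to the readouts. It also means absolute activities deep in a
cascade can be extremely small; all solvers in the package work to an
absolute rate tolerance, so quantities derived from activities far below
~1e-8 are treated as numerically degenerate (see *Numerical choices*).

## The coarse-grained scan and the sensitivity statistic

Each of the `n` control nodes is assigned `beta` *low* or *high*,
giving `s^n` states (`countStates`); for `n = 20` binary nodes that is
1 048 576 conditions. Every unordered pair of states differing in
exactly one node — `s^n * n * (s-1) / 2` pairs, 10 485 760 for
`n = 20` (`countSensitivityPairs`) — yields, for each observed node
`N_i`, the log–log gain

```
S(N_i, beta(N_j)) = ln[ SS(N_i)_high / SS(N_i)_low ] /
                    ln[ beta(N_j)_high / beta(N_j)_low ]
```

a dimensionless sensitivity: positive when raising `N_j`'s basal
activity raises `N_i`, negative when it lowers it, and ~0 when
intermediate nodes buffer the signal. The statistic is symmetric under
relabelling the two states, and exactly zero when `N_i` is unreachable
from `N_j`.

`rankProfile` sorts one endpoint's values and profiles the extreme
regions: the top and bottom `floor(q*N)` records (default `q = 0.02`,
so 209 715 of the full 10 485 760), per-node frequencies within them,
per-node extreme values, and the fraction of each node's records inside
the negligible band `|S| <= 0.005`.

Full enumeration of the shipped 19-control-node model (524 288 ODE
solves) is supported but deliberately not the test-suite default; the
suite exercises the exhaustive path on a 12-control-node subnetwork
(4 096 states) and the full model through a seeded sample of 10 000
single-node-difference pairs. Both members of a sampled pair are solved
in the same vectorised batch, which makes the *sign* of their steady
state difference exact (see below).

## Signal flow

For a chosen control node `j` (e.g. NPM-ALK raised 100-fold,
`beta` 0.001 to 0.1), two per-node metrics summarise how the
perturbation propagates:

* **involvement** — among states whose endpoint steady state is at or
  above the 0.75 quantile of the scan ("endpoint highly active"), the
  fraction of states in which each node sat at `beta` high. An
  uncorrelated node shows ~50%; the deviation from 0.5 measures
  involvement. "Highly active" has no intrinsic absolute threshold in
  this model; a scan-relative quantile keeps the selection nonempty and
  scale-free, and is configurable. Tallies use the node's *input* basal
  level (the quantity that defines a coarse-grained state), not its
  output activity.
* **amplification ratio** — the mean steady state of each node over all
  states on the `beta_j = high` face of the hypercube divided by the
  mean over the `beta_j = low` face.

`flowAttributes` maps involvement deviations linearly to node widths in
`[30, 120]` and ratios linearly to grey levels `[255, 50]` (darker =
stronger transduced signal), with the control node black (0) — the
conventions of Cytoscape-style network diagrams. Endpoints have no basal
level to tally, so they take the midpoint width; when a metric is
constant across nodes every node maps to the midpoint of its range.

On the exhaustively enumerated subnetwork the ratios are exact
hypercube-face averages, and the VAV1/CDC42 arm of the model amplifies
an NPM-ALK perturbation at least as strongly as the
p85/PI3K/p110-PIP3-pAKT arm, which is additionally damped by the lipid
phosphatases. On *sampled* scans this ordering is not asserted: each
node's own basal level is then imperfectly balanced across the two
faces, and that sampling noise can exceed the cascade signal.

## Fine-grained surfaces

`gridScan` varies 1–3 control nodes over log-spaced grids (default 25
points across `[1e-3, 1e2]`) with every other control node at `beta`
low, and `localSensitivity` applies the same two-level log-gain between
adjacent grid points, assigning each value to the geometric midpoint of
its cell (forward differences, consistent with the two-level coarse
statistic; central differences are available). The default study varies
JAK3/STAT3 and SHP1 at NPM-ALK levels `{0.001, 0.1, 10, 100}`; the grid
resolution and ranges are this package's documented choice (there is no
canonical grid for such surfaces). Surfaces with respect to
JAK3/STAT3 are non-negative everywhere (it reaches the endpoints through
activation only) and surfaces with respect to SHP1 — which touches the
rest of the network only through inhibiting links — are non-positive, at
every NPM-ALK level.

## Numerical choices

* **Two steady-state backends.** `steadyState` defaults to adaptive
  integration (deSolve's `lsoda`, integrated in chunks until
  `max |dx/dt| <= rateTol`, default 1e-9, cap `tMax = 1e4`). The
  scanning functions use a damped fixed-point iteration vectorised
  across states (`X <- X + dt (beta A I - gamma X)`, with `dt = 1/L`
  for a Lipschitz bound `L` of the right-hand side), which shares its
  fixed point with the ODE exactly; the two backends are required to
  agree to 1e-6 relative in the test suite. Initial condition is
  `x = beta` by default; feedback loops are handled by iteration, never
  by algebraic elimination.
* **Exact sign structure.** Within one batch, every state is advanced
  with the same step and iteration count, and each update is composed of
  IEEE-monotone operations. For two states differing only in one basal
  activity whose influence propagates through a fixed sign structure,
  the computed steady states are therefore ordered *exactly*, and the
  derived sensitivity carries the correct sign even when its magnitude
  is near rounding level. The sign assertions in the test suite hold
  with zero tolerance for this reason.
* **Degenerate values.** Sensitivities from non-converged or
  non-positive steady states are flagged invalid, excluded from ranking,
  and counted — never silently dropped. Activities below ~1e-8 are at
  the rounding floor of doubly-saturating Hill chains; solver-agreement
  tests use a relative criterion with that absolute floor.
* **Ties and determinism.** States are enumerated in lexicographic order
  of the control tuple (first declared node most significant, low before
  high); ranking sorts are stable with ties broken by perturbed node
  name then state index; all sampling is governed by an explicit seed
  and restores the caller's RNG state. Grid and full-enumeration
  pipelines contain no randomness and are bitwise reproducible.
* **Exact combinatorics.** `countStates`/`countSensitivityPairs` use
  integer-exact double arithmetic and refuse (rather than round) beyond
  2^53.

## The synthetic generator

`randomNetwork` draws sparse Erdős–Rényi-style directed networks shaped
like the curated model: a topological layout with forward-edge
probability 0.15 by default, ~10% inhibiting edges, optional back edges
(a quarter of the forward probability) for feedback, and sink endpoints
that are guaranteed an incoming edge. Defaults give a 21-node network a
density comparable to the curated model's 28 edges. `motifNetwork`
supplies closed-form oracles — explicit Hill compositions for cascades,
fan-ins and inhibitor pairs, and a bisection-solved scalar fixed point
for a driven positive-feedback loop — against which the numerical
solvers are validated to 1e-8.

What the generator does *not* emulate: realistic degree distributions,
edge-weight heterogeneity, multistability (at the basal ranges used the
feedback loops are weakly coupled and the fixed point is unique), or
time-resolved behaviour. Passing tests on synthetic networks therefore
validate the machinery — solvers, enumeration, statistics — not the
biological fidelity of any particular curated model.

## Problem sizes in the test suite

The suite validates solver agreement on 50 seeded 8-node networks,
exhaustive scanning on the 12-control subnetwork (4 096 states; 49 152
endpoint sensitivities), the full 19-control model through 10 000
sampled pairs (20 000 ODE solves, batched), and 15x15 fine grids at four
NPM-ALK levels. These sizes were chosen so the entire suite completes in
about a minute while still exercising every code path at meaningful
scale; the full 2^19 enumeration remains available through
`runCoarse(runConfig())`.

## Known limitations

* The Hill-type right-hand side is one documented member of a family of
  phenomenological network formalisms; absolute sensitivity magnitudes,
  extreme values and top/bottom-2% node counts depend on that choice and
  on the kinetic defaults, and should be read as sign and ordering
  structure rather than as universal numbers.
* The shipped curated model has 19 control nodes plus 2 endpoints; all
  combinatorial functions take `n` explicitly, so formula checks (e.g.
  at `n = 20`) are independent of the fixture's size.
* Involvement and amplification metrics are exact only under full
  enumeration; sampled scans estimate them with hypercube-face
  imbalance noise.
* No stochastic dynamics, no parameter fitting, no bifurcation analysis;
  steep-sensitivity regions are reported, not classified.
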