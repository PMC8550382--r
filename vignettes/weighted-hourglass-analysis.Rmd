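---
title: "Weighted hourglass analysis of directed source-target networks"
author: "hourglassNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted hourglass analysis of directed source-target networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hourglassNet)
```

## The question the package answers

Many directed dependency networks are organised like an hourglass: a large
set of source nodes and a large set of target nodes communicate almost
entirely through a small "waist" of intermediate nodes.  The prototypical
case is a nervous system viewed as an information-processing network:
sensory neurons (sources) feed inter-neurons (intermediates) which drive
motor neurons (targets), and the interesting biology sits in the handful of
inter-neurons that almost every sensorimotor pathway crosses.  With modern
connectomes the connections also carry weights — the number of chemical
synapses per connection — and the question becomes: *does the placement of
weight, not just the wiring, concentrate the traffic on a small waist?*

`hourglassNet` answers this in four steps, each exposed as an exported
function and each reusable on any directed network whose nodes can be
labelled source / intermediate / target.

## Model and procedure

**1. Preprocessing.**  A `RoleNetwork` holds a simple directed graph
(duplicate edge rows are summed at load — synapse counts are additive —
and self-loops are dropped, since simple paths cannot use them) with
exactly one role per node.  Edges that run against the
source→intermediate→target direction (intermediate→source, target→source,
target→intermediate) are *feedback* edges; `removeFeedbackEdges()` deletes
them before path enumeration, which keeps the path set finite and focused
on feed-forward traffic.  Within-class edges (source→source and so on) are
kept.  `pruneIsolated()` drops nodes left without any incident edge.

**2. Bounded path enumeration.**  `enumerateStPaths()` collects every
*simple* directed path from a source to a target of at most `maxHops`
edges (default 4, the bound under which a nervous system plausibly relays
a signal without requiring global shortest-path routing).  Interior nodes
may hold any role, and a direct source→target edge is a 1-hop path; the
`strictInterior` flag restricts interiors to intermediates for sensitivity
analysis.  Paths are returned in lexicographic (byte) order of their node
sequences, so every downstream result is deterministic.

**3. Path weights and centrality.**  A weighting scheme maps the edge
weights along a path to one path weight $w_p = f(w_{e_1},\dots,w_{e_n})$:

| scheme    | $w_p$                         | reading                           |
|-----------|-------------------------------|-----------------------------------|
| `unit`    | $1$                           | unweighted analysis (UNW)         |
| `product` | $\prod_e w_e$                 | multi-edge transformation (MET)   |
| `min`     | $\min_e w_e$                  | max-flow capacity                 |
| `invsum`  | $(\sum_e 1/w_e)^{-1}$         | communication efficiency          |

The MET view treats an edge of integer weight $w$ as $w$ parallel unit
edges, so a path is counted once per distinct combination of parallel
edges — hence the product — and reduces exactly to the unweighted analysis
when every weight is 1.  The *path centrality* of a node $v$ is
$P(v)=\sum_{p \ni v} w_p$, the weighted number of source-target pathways
the node participates in.

**4. τ-core and H-score.**  The *τ-core* is the smallest node set whose
paths carry at least a fraction τ of the total path weight.  Exact
minimisation is a set-cover problem (NP-complete), so `computeTauCore()`
uses the standard greedy heuristic: repeatedly add the node with the
highest centrality over the still-uncovered paths and remove the paths it
covers, stopping as soon as the covered weight reaches $\tau \cdot
\text{total}$ (test uses $\geq$).  Only covered paths are removed —
surviving paths keep all their nodes and edges — and argmax ties are
broken by lexicographic node id.  Core size alone is meaningless without
a reference, so `buildFlatNetwork()` constructs the *flat dependency
network* $G_f$: sources and targets only, one edge per ordered
(source, target) pair weighted by the pair's aggregated path weight.
$G_f$ preserves every source-target dependency but has no intermediates,
so it cannot have an hourglass, and its exact core can never be smaller
than the network's.  The H-score is

$$H(\tau) = 1 - \frac{C(\tau)}{C_f(\tau)} \in [0, 1],$$

with values near 1 meaning the real network covers its traffic with far
fewer nodes than any source/target cover could.

## A worked example

```{r fixture}
net <- tinyHourglass()
ps <- assignPathWeights(enumerateStPaths(net), net, "product")
pathCentrality(ps)
computeTauCore(ps, 0.9)
hScore(ps, 0.9)
```

The four paths have MET weights 2, 8, 3 and 12 (total 25); the hub `x`
lies on all of them, so a single node covers 100% of the weight while the
flat network needs two endpoints for 90% — hence $H(0.9) = 1 - 1/2 = 0.5$.

## Null models

Two randomizations put an observed H-score in context:

* `permuteEdgeWeights()` — the weighted null: the topology is kept intact
  and the multiset of weights is permuted uniformly over the edges.  Any
  H-score drop relative to the observed network isolates the contribution
  of *weight placement*; with all weights equal the permutation is a
  no-op and the p-value is exactly 1.  This is the minimal randomization
  for weighted networks, and `nullHDistribution()` exploits it by
  enumerating paths once and recomputing only path weights per replicate.
* `shuffleEdges()` — the unweighted null: every edge keeps its head (so
  in-degrees, node and edge counts are preserved) and draws a new tail
  uniformly from the nodes earlier in a fixed precedence order.  The
  "partial ordering" this preserves is not fully specified in the
  unweighted-analysis literature the procedure descends from; we
  operationalise it as the topological level of each node's strongly
  connected component in the condensation of the feed-forward network
  (members of one component share a level), with role and node-id
  tie-breaks, and flag this as an interpretation (`orderConstraint =
  FALSE` disables it).

The p-value is the add-one permutation estimator
$(1 + \#\{H_\text{null} \ge H_\text{obs}\}) / (n_\text{reps} + 1)$, never
exactly 0.  The headline analyses use 500 replicates; replicate seeds are
spawned deterministically from one master seed.

## The synthetic generator and what it does (not) show

`layeredHourglass()` generates the study conditions for all power and
calibration checks: `nSource = 8` sources and `nTarget = 8` targets joined
through a waist of `nWaist = 2` intermediates (each source-waist and
waist-target pair connected with probability `pWaist = 0.8`, topped up so
every source reaches the waist and the waist reaches a target), plus
`extraIntermediates = 8` bypass intermediates wired with probability
`pBypass = 0.3` per source-extra and extra-target pair.  Weights are
uniform integers in `weightLow:weightHigh = 1:3` — small synapse-count-like
values — and waist-incident edges are multiplied by `waistWeightBoost`
(boost 10 in the "weighted waist" condition, i.e. roughly an order of
magnitude more synapses on waist connections, the regime the weighted
analysis is designed to detect).  These sizes keep path counts in the
low hundreds, which is deliberate: the exhaustive set-cover oracle and
seed sweeps stay cheap while every structural feature of the full-scale
analysis (bypass routes, within-class edges, feedback edges via
`pWithinClass`/`pFeedback`) is representable.

What the generator does *not* emulate: heavy-tailed degree and weight
distributions, reciprocal connections, correlated weights, or the sheer
path multiplicity of a real connectome (millions of 4-hop paths).  Tests
passing on these networks show the machinery is correct and the nulls are
calibrated; they do not by themselves certify effect sizes on real data.

## Numerical and design choices

* **Determinism.**  All node orderings and argmax tie-breaks use
  byte-order (`radix`) sorting; enumeration order is fixed; every
  stochastic function takes a seed and restores the caller's RNG state.
* **Stopping and tolerances.**  Greedy stopping compares covered weight
  against $\tau \cdot \text{total}$ with a $10^{-9}$ relative guard;
  argmax ties use a $10^{-12}$ relative band (weights are exact for
  integer inputs, so this only matters for `invsum`-style schemes).
* **Flat core is greedy by default.**  $H$ compares like with like when
  both cores come from the same heuristic; `flatCore = "exact"` switches
  to the exhaustive oracle for small networks.  Because the greedy core
  of the network can occasionally exceed the greedy flat core, $H$ is
  clamped at 0 with a warning and a `clamped` flag rather than reported
  negative.
* **Flat weights aggregate by summation** — the unique choice that keeps
  the flat network's total weight equal to the path set's, so τ means the
  same fraction on both sides of the H-score ratio.
* **Weights are positive reals.**  The MET story presumes integer synapse
  counts, but the product formula is well-defined for any positive
  weights, so the loader validates positivity only.
* **Degenerate inputs.**  A network with no source-target paths is an
  error for core computation (there is nothing to cover); a shuffled
  null replicate that loses all its paths scores $H = 0$ (no hourglass).
* **τ grid.**  H-score curves default to τ from 0.05 to 1.00 in steps of
  0.05, with τ = 0.9 as the single reporting threshold.

## Limitations

The greedy core has no approximation guarantee here beyond the classical
set-cover bound; on adversarial instances it can exceed the optimum (the
test-only `exactMinCore()` oracle quantifies this on small networks).
The edge-shuffling null's precedence constraint is one reading of an
under-specified procedure; conclusions about *weights* should rest on the
weight-permutation null, which is exact about what it holds fixed.  Path
enumeration is exponential in `maxHops` on dense networks — the bound,
not the implementation, is what keeps the analysis tractable.
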