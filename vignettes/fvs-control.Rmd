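---
title: "Structural control of regulatory-network dynamics via feedback vertex sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural control of regulatory-network dynamics via feedback vertex sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvscontrol)
```

## The problem and the theory

A gene regulatory network (GRN) is a directed graph $\Gamma = (V, E)$ whose
nodes are genes (or signaling activities) and whose edges are regulatory
linkages; the in-neighborhood $I_n = \{i : (i \to n) \in E\}$ of a node is
its input set. The activity $x_n$ of each node is assumed to follow an
ordinary differential equation

$$\dot x_n = F_n(x_n, x_{I_n}),$$

subject only to the *decay condition*

$$\partial_1 F_n(x_n, x_{I_n}) < 0 :$$

holding a molecule's inputs fixed, its activity decays. No functional form,
parameter values or initial states are assumed beyond this. Under the decay
condition, structural-control theory for nonlinear networks identifies the
key nodes for controlling the dynamics from topology alone: they are the
members of a **feedback vertex set (FVS)** — a set of vertices whose removal
leaves the directed graph without directed cycles (a self-loop counts as a
cycle of length one). Clamping every FVS node at its value in a steady
state of the intact system removes all feedback from the remaining
dynamics; an acyclic decay-condition system converges on a unique, globally
stable equilibrium, which must coincide with the chosen steady state. Hence:

* clamping a full FVS at the values of attractor $S$ steers the system to
  $S$ from **any** initial state;
* clamping a *proper subset* of an FVS leaves residual feedback and, in
  general, residual multistability — control genuinely requires the whole
  set;
* clamping the FVS at arbitrary (e.g. binary) value combinations
  enumerates *all* steady states the system can reach: with $k$ FVS nodes,
  $2^k$ low/high assignments suffice under a binarization assumption.

This package implements the computational side of that program end to end:
exact enumeration of all minimum FVSs, decay-condition dynamics with exact
clamping, control verification, and the exhaustive binary scan, together
with seeded generators that make every claim testable on synthetic ground
truth.

## Exact enumeration of all minimum FVSs

Minimum-FVS computation is NP-hard in general, but regulatory networks are
sparse and their feedback is localized. The enumerator exploits this:

1. **SCC decomposition.** Every directed cycle lives inside one strongly
   connected component, so the problem decomposes: the global minimum size
   is the sum of per-SCC minima, and the global family is the Cartesian
   product of per-SCC families.
2. **Branch and bound on shortest cycles.** Within an SCC, every FVS must
   contain at least one vertex of any directed cycle — in particular of a
   *shortest* one, found by BFS. Branching over the (few) vertices of a
   shortest cycle with the current best size as bound yields the exact
   minimum.
3. **Complete co-optimal enumeration.** The branching is rerun at the
   exact optimum, collecting every FVS of that size. Dominance rules that
   can discard co-optimal solutions are deliberately not used: completeness
   of the family is part of the contract (and of the tests). Output order
   is lexicographic on sorted node ids, so results are byte-stable.
4. **Alternative-choice factorization.** Families frequently form a
   Cartesian product of interchangeable "alternative groups". Two nodes are
   assigned to one group iff they never co-occur in a set and swapping them
   everywhere maps the family onto itself; the grouping is reported only
   after verifying that one-choice-per-group reconstruction reproduces the
   family exactly, otherwise `groups` is `NULL`. (The never-co-occur
   refinement matters: nodes present in *every* set are trivially
   swap-invariant with each other but form separate singleton groups.)

`brute_force_minimum_fvs()` provides the independent oracle — exhaustive
subset search in increasing cardinality, with igraph's DAG test as a second
acyclicity route — and the test suite checks exact agreement of the whole
family on hundreds of seeded random digraphs with up to 12 nodes.

On the packaged ascidian-network fixture (92 nodes, 328 edges; see below)
the enumerator returns 12 minimum FVSs of size 5 factorizing as
{Foxa.a|Nodal|Snail} × {Foxd|Twist-r.a/b} × {Neurog|Delta.b} × {Zic-r.b} ×
{Erk signaling} in well under a second.

## The dynamics model

The theory needs no functional form, but simulation does. The default drift
is a logistic-of-weighted-sum:

$$\dot x_n = -d_n x_n + c_n + b_n\,
  \sigma\!\big(\beta_n (u_n - \theta_n)\big), \qquad
  u_n = \sum_{i \in I_n} s_{in} w_{in}\, x_i,$$

with $\sigma$ the standard logistic, $s_{in} = \pm 1$ the edge sign and
$w_{in} \ge 0$ the edge weight; top nodes (empty $I_n$) reduce to
$\dot x_n = -d_n x_n + c_n$ with the unique equilibrium $c_n / d_n$. An
AND-like product-of-regulators variant is selectable
(`regulation = "product"`). Both forms satisfy the decay condition by
construction — the self-part derivative is exactly $-d_n$ — and keep each
coordinate in the forward-invariant box $[0, (b_n + c_n)/d_n]$.

Defaults (units: activities are dimensionless, rates per unit time):

| parameter | default | meaning |
|---|---|---|
| $d_n$ | 1 | decay rate; sets the time scale |
| $b_n$ | 1 | maximal regulated synthesis rate |
| $c_n$ | 0 (regulated), 0.5 (top) | basal supply; top nodes idle at 0.5 |
| $w_{in}$ | 1 | edge weight |
| $\beta_n$ | 10 | logistic steepness; sharp enough for multistability |
| $\theta_n$ | $\tfrac12 \sum_i s_{in} w_{in}$ | threshold at half the signed input range |

The threshold choice deserves a note, because it was a genuinely open
design point. Centering $\theta_n$ at half the *signed* input range (rather
than at half the count of activating inputs) is what makes the canonical
motifs behave correctly across sign patterns: a mutual-repression toggle
($\theta = -\tfrac12$, so a node switches on exactly when its repressor
falls below mid-activity) is bistable, positive feedback loops are
bistable, and a target with only repressors can still be expressed when its
repressors are off. With a count-based threshold a pure-repression toggle
collapses to a single low state, which would contradict the package's own
toggle fixture.

Numerical choices: stiff-capable `lsoda` integration (deSolve) at
`rtol = 1e-9`, `atol = 1e-10`; steady-state residual tolerance
`tol_ss = 1e-8` in max norm; attractor-identity tolerance `1e-3` per
coordinate; horizon 200 time units, doubling to 1600 before declaring
non-convergence. After integration the root is polished by a damped Newton
iteration on the unclamped subsystem (numeric Jacobian) — but only when the
integration residual is already below `1e-4`. Polishing from farther away
is refused deliberately: on a limit cycle Newton could jump to an unstable
equilibrium that the flow never reaches, and a non-stationary or
oscillatory outcome must be reported as `converged = FALSE`, never
silently as a steady state. If the integrator itself gives up (oscillatory
models occasionally exhaust the step budget), the last good state is kept
and the result is flagged non-converged.

Clamping is implemented by subsystem reduction — clamped coordinates are
removed from the ODE state and pinned exactly — not by stiff penalty
terms. Exactness of clamped coordinates is a tested contract.

## Control verification and the binary scan

`verify_fvs_control()` checks the headline property directly: it requires
`is_fvs()` of the candidate set and a converged target attractor (the
theorem's hypotheses; both are errors when violated), clamps the set at the
target's values, and integrates from seeded random initial states drawn
uniformly in the invariant box. Success means every run lands on the target
(non-FVS coordinates within the attractor tolerance).
`demonstrate_subset_failure()` shows the necessity side: clamping a proper
non-FVS subset and counting the attractors that remain — two or more
demonstrates non-control.

`binary_scan()` evaluates all $2^k$ low/high clamp assignments over a
$k$-node FVS (defaults low = 0, high = 1, the binary abstraction of
inactive/active on normalized activities), ordered by binary counting with
the first node as the most significant bit. Conditions are labelled by
letter codes — upper case = high, lower case = low — derived from display
names, or supplied explicitly; the ascidian fixture carries the
conventional A/D/N/Z/E letters, so its 32 conditions read `adnze` through
`ADNZE`. Each condition is integrated from several random starts; if the
endpoints disagree the record is marked `ambiguous` (they are never
averaged), and integration failures are marked `nonconverged`.

Steady states are labelled by `classify_readout()`: a tissue qualifies when
all of its markers exceed a threshold `tau` (default 0.5) times the
marker's maximum attainable activity; among multiple qualifying tissues, a
tissue whose marker set is a proper subset of another qualifying tissue's
defers to the superset (so a brain-plus-pan-neural pattern reads as brain);
anything else is `multiple` or `none`. This deterministic threshold rule
replaces the sign test used on embryo replicates in the experimental
setting — biological replicates have no analogue in a deterministic
simulation, so a statistical test would be theater; the substitution is
intentional and visible.

## The ascidian fixture and what it is not

The package ships `ciona_grn_synthetic.tsv`, a stand-in for the cell-fate
specification GRN of the ascidian *Ciona intestinalis* (type A). The word
*synthetic* in the name is load-bearing. The file reproduces the published
summary topology of that network — 92 nodes, 328 signed edges, minimum FVS
size 5, exactly 12 minimum FVSs with alternative groups of sizes
3 × 2 × 2 × 1 × 1 over the genes named above, tissue markers wired as
terminal targets of their canonical regulators, Erk signaling as a single
ordinary node — but every edge outside that engineered feedback structure
and the curated marker inputs is randomly generated (strictly
rank-increasing, so the designed cycles are the only directed cycles). It
exists so that the full pipeline (load → enumerate → scan) runs at the real
problem size with verifiable structural answers. It must not be used for
biological inference; the fixture file's header says the same.

For the same reason, the 32-condition scan's *readouts* on this fixture are
exploratory output, not a claim: which tissue lights up under which binary
condition depends on kinetic parameters that no published source provides.
The structural facts (32 complete, duplicate-free conditions; exact
clamps; convergence) are asserted; the condition-to-tissue map is merely
reported.

## The synthetic-data generator

`synth_spec()` / `generate_network()` produce seeded random signed
digraphs: the requested number of mutual-repression toggle pairs is
embedded first (nodes 1–2, 3–4, ...), then the remaining edges are drawn
uniformly without duplicates, repressing with probability
`repression_fraction` (default 0.3). `generate_multistable_model()` builds
default dynamics on such a network and *verifies* multistability by a
seeded attractor sweep, regenerating with a derived seed (up to a retry
cap) when feedback happens to be washed out — the theorem-testing ensemble
contains only models with confirmed ≥ 2 attractors. Everything is
byte-reproducible from the spec and seeds.

What the generator emulates: sparse signed regulatory wiring, localized
feedback through bistable motifs, activities normalized to order one. What
it does not emulate: transcriptional noise, time-varying inputs, spatial or
intercellular coupling, realistic kinetic constants, and the heavy-tailed
degree structure of curated GRNs. Passing the ensemble tests therefore
shows that the *algorithms* honor the theory's guarantees under the decay
condition; it does not show that any particular biological network is
controllable in practice — that depends on the fidelity of the network map
itself.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run, by the package's own
choice of scale: oracle-equivalence sweeps over 200 seeded digraphs with
3–12 nodes; a control ensemble of 50 verified-multistable models (6 nodes,
10 edges, 2 toggles) with 30 verification starts per attractor and an
equal-size non-FVS contrast subset per model; 50 random acyclic models
probed from 20 starts each; and the full 92-node fixture for enumeration
and the 32-condition scan. On one CPU the whole suite completes in a few
minutes.

## Known limitations

* FVS enumeration is exponential in the worst case; the branch-and-bound
  is exact and fast on sparse regulatory networks (and refuses, with a
  resource error, families larger than its budget) but is not meant for
  dense graphs with enormous co-optimal families.
* Cycle counting is capped (default $10^6$) because simple-cycle counts
  grow exponentially; the capped flag is carried on the result.
* The dynamics layer is deterministic ODE only — no stochastic, delay or
  spatial dynamics.
* Attractor discovery is sampling-based: an attractor with a tiny basin
  can be missed at small `n_inits`; seeds and counts are recorded so runs
  are reproducible and extensible.
* The condition-code default (first letter of display names, indexed on
  collision) is cosmetic; pass explicit letters where a conventional code
  exists.
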