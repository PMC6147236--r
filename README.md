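# fvscontrol

Structural control of gene regulatory network (GRN) dynamics via feedback
vertex sets, in R.

## What problem this solves, and for whom

Cell types correspond to distinct steady states of a regulatory network's
dynamics, but the kinetic details of those dynamics — functional forms,
parameters, initial states — are almost never known. Structural-control
theory sidesteps them: model each gene's activity as
`dx_n/dt = F_n(x_n, x_{I_n})` with only the *decay condition*
`∂F_n/∂x_n < 0` (inputs held fixed, activity decays), and the key nodes
for controlling the dynamics can be read off the wiring diagram alone.
They are the members of a **feedback vertex set (FVS)**: a set of vertices
whose removal leaves the directed graph without directed cycles. Clamping
a full FVS at the values it takes in any steady state forces the whole
system onto that steady state from any initial condition; clamping a
proper subset does not; and scanning all `2^k` binary (low/high) clamp
combinations of a `k`-node FVS enumerates every steady state the system
can reach. In the ascidian embryo this program — five FVS factors
controlling a 92-gene fate-specification network — reproduced the gene
expression programs of six of seven larval tissues.

This package is for systems biologists and network scientists who want to
run that pipeline on their own networks: find *all* minimum FVSs exactly,
simulate decay-condition dynamics with exact clamping, verify
controllability, and perform exhaustive binary scans with tissue-marker
readouts.

What it deliberately does not do: infer networks from expression data, fit
kinetic parameters, or simulate stochastic/spatial dynamics.

## Worked example

Load the packaged ascidian-network fixture (a synthetic stand-in that
reproduces the published topology of the *Ciona* fate-specification GRN —
see `?get_fixture` and the fixture file header for exactly what is and is
not faithful), and enumerate its minimum FVSs:

```r
library(fvscontrol)
fx <- get_fixture("ciona")
fx$network
#> <regulatory_network> ciona: 92 nodes, 328 edges (247 activating, 81 repressing, 0 unknown)

enumerate_minimum_fvs(fx$network)
#> <fvs_family> minimum size 5, 12 minimum FVS(s)
#> alternative-choice factorization: {Delta.b|Neurog} x {Erk_signaling} x
#>   {Foxa.a|Nodal|Snail} x {Foxd|Twist-r.a.b} x {Zic-r.b}  (2 x 1 x 3 x 2 x 1 = 12)
#>   { Delta.b, Erk_signaling, Foxa.a, Foxd, Zic-r.b }
#>   ...
```

Twelve co-optimal FVSs of five genes each, presented as a product of
alternative groups: pick one gene per group. Now clamp the conventional
five — Foxa.a, Foxd, Neurog, Zic-r.b, Erk signaling — in every one of the
2^5 = 32 binary combinations and read out tissue markers at each steady
state (letter codes: upper = high clamp, lower = low):

```r
model <- build_dynamics(fx$network)
scan <- binary_scan(model, fx$fvs_nodes, fx$panel, n_inits = 3, seed = 11,
                    letters = fx$letters)
head(scan$table[, c("condition_code", "readout", "residual")])
#>   condition_code  readout     residual
#> 1          adnze   muscle 2.109424e-15
#> 2          adnzE     none 1.443290e-15
#> 3          adnZe multiple 1.609823e-15
#> 4          adnZE    brain 1.276756e-15
#> 5          adNze   muscle 2.731149e-14
#> 6          adNzE     none 7.771561e-16
```

Each row is one clamping condition: its five-letter code, the tissue whose
markers are predominantly on at the converged steady state (`multiple` /
`none` when several / no tissue qualifies), and the residual max-norm
drift (≈ 1e-15: these are genuine equilibria). On this fixture the
condition→tissue map is exploratory — it depends on generated wiring and
default kinetics — but the scan structure (all 32 conditions, exact
clamps, convergence) is asserted by the test suite.

The control theorem itself, on the canonical toggle switch:

```r
tog <- build_dynamics(get_fixture("toggle")$network)
at <- enumerate_attractors(tog, 50, seed = 3)
at
#> <attractor_set> 2 attractor(s), basins 28/22, 0 nonconverged (seed 3)
round(at$attractors[[1]]$state, 4)
#>      u      v
#> 0.0072 0.9928

v <- verify_fvs_control(tog, "u", at$attractors[[1]], n_inits = 30, seed = 5)
v$success; max(v$deviations)
#> TRUE
#> 2.22e-15
```

Clamping the single FVS node `u` at its value in either attractor drags
all 30 random initial states onto that attractor to machine precision.

A shell entry point wrapping the same functions lives at
`inst/cli/fvsctl.R` (subcommands `fvs`, `cycles`, `simulate`, `scan`,
`verify`, `synth`; exit codes 0/2/3/4/5 for success/usage/validation/
resource/check-failure).

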