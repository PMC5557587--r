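---
title: "Reverse engineering signalling logic with logic-based ODEs and cooperative scatter search"
author: "logicess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse engineering signalling logic with logic-based ODEs and cooperative scatter search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logicess)
```

## The modelling problem

Cell-signalling measurements are typically perturbation time series: a cell
line is exposed to combinations of ligands (stimuli) and kinase inhibitors,
and the phosphorylation state of a handful of proteins is sampled at a few
time points on a normalized $[0,1]$ scale.  Prior knowledge about the
pathway usually exists only as a signed directed graph — "A activates B",
"C inhibits D" — with no kinetics and no certainty that every edge is
functional in the cell type at hand.

`logicess` turns such a prior graph into a *candidate hypergraph* of logic
gates and fits, simultaneously,

* **which gates are real** — one binary selector $w_i$ per candidate
  hyperedge, and
* **how they transmit signal** — continuous kinetic parameters per gate
  input and per protein,

by minimizing the squared mismatch to the data over both blocks at once.
This is a mixed-integer dynamic optimization problem: the outer search
handles a mixed continuous/binary decision vector, and every objective
evaluation solves an inner initial-value problem.

## From Boolean logic to continuous dynamics

Each regulator set of a protein is a candidate AND gate (a hyperedge);
alternative hyperedges targeting the same protein combine through an
implicit OR; inhibitory edges act as NOT.  A Boolean update function
$B(x_1,\dots,x_N)$ is made continuous by multilinear interpolation over the
vertices of the unit hypercube:

$$\bar B(\bar x) \;=\; \sum_{x\in\{0,1\}^N} B(x)\,
  \prod_{i=1}^{N}\bigl[x_i\bar x_i + (1-x_i)(1-\bar x_i)\bigr],$$

which is exact at every Boolean vertex and affine in each coordinate
(`boolcube_eval`).  To obtain the sigmoidal, switch-like responses typical
of phosphorylation cascades, each input is first passed through a Hill
function $f_H(x) = x^n/(x^n + k^n)$, normalized as $f_{Hn}(x) =
f_H(x)/f_H(1)$ so that the unit interval maps onto itself with fixed
endpoints (`hill`, `normalized_hill`, `hillcube_eval`).  Inhibitory inputs
enter as $1 - f_{Hn}(x)$; composing NOT with the Hill transform this way is
the standard convention, which we adopt because it preserves vertex
exactness of the normalized transform.

The dynamics of each non-input state are first-order relaxation towards its
gate value,

$$\dot{\bar x}_i \;=\; \frac{1}{\tau_i}\,\bigl(\bar B_i(\bar x) - \bar
x_i\bigr),$$

with $\tau_i > 0$ a life-time.  $\bar B_i$ is the OR (multilinear:
$1-\prod_e(1-z_e)$) over the state's *selected* hyperedges, each hyperedge
value $z_e$ the product of its transformed inputs.  Because every
hyperedge-input occurrence carries its own $(n,k)$ pair, occurrences of the
same species in different gates are formally distinct variables, and the
product form coincides with the exact multilinear interpolation.  States
whose every candidate gate is deselected decay exponentially to zero;
species with no incoming edges are experimental inputs, clamped at their
stimulus level (zero when unstimulated).  Inhibitors force the target's
activation $\bar B_i$ to zero while leaving the state in the system —
signal blocking rather than state deletion, matching how a kinase inhibitor
suppresses catalytic activity without removing the protein.  Full block is
the default; partial block can be emulated through the stimulus interface.

## The estimation problem

For experiments $\epsilon$, observed species $o$ and sampling times $s$, the
fit minimizes

$$F(n,k,\tau,w) \;=\; \sum_{\epsilon}\sum_{o}\sum_{s}
\bigl(\tilde y_{s}^{\epsilon,o} - y_{s}^{\epsilon,o}\bigr)^2$$

subject to the ODE system induced by the selected sub-hypergraph
$E_{sub}=\{e_i \mid w_i = 1\}$ and box bounds on all continuous parameters.
Missing measurements are skipped.  Time starts at $t_0=0$ and measurements
at $t=0$ compare against the initial state.  The default bounds are
$n\in[1,10]$ (near-linear to switch-like), $k\in[0.01,1]$ (half-saturation
within the state range), $\tau\in[0.1,10]$ and $\bar x_0\in[0,1]$; the data
are normalized, so these cover the scientifically meaningful range.

For model reduction the same search minimizes the Akaike information
criterion in the form

$$\mathrm{AIC} = 2K + 2n\ln(F/n),$$

where $K$ counts the active parameters: two per input of each selected
hyperedge ($n$ and $k$), one $\tau$ per state with at least one selected
incoming gate, each estimated initial condition, and each selected $w_i$.
A `standard_aic` variant ($n\ln(F/n) + 2K$) is provided but is not the
default.  On noiseless data $F$ can collapse towards machine precision,
where $\ln F$ is dominated by integrator round-off rather than by model
structure; `reduce` therefore floors $F$ at `aic_f_floor` (default `1e-8`,
configurable).  With the floor, all structures that fit essentially
perfectly tie on the likelihood term and the parameter count decides — the
reduction behaviour the criterion is meant to deliver.

### Numerical choices

The inner IVP is integrated with `deSolve::lsoda` (stiff-capable,
variable-step) at `rtol = 1e-6`, `atol = 1e-8`; the right-hand side is
compiled C for speed, with a pure-R mirror (`build_rhs`) cross-checked in
the tests.  State values are clamped into $[0,1]$ inside the gate
evaluation so that tiny integrator overshoots cannot feed negative numbers
to fractional powers.  Each integration has a step budget (`maxsteps`,
default 2000 per output interval); decision vectors whose dynamics exceed
it are treated as integration failures.  Failures never raise errors inside
the objective: they map to a finite penalty ($10^{10}$ plus the number of
failed experiments) so the solver can still rank them.

## The solver

The mixed-integer search is an enhanced scatter search: a small
diversified population (latin-hypercube continuous coordinates, fair-coin
binaries) seeds a reference set of about ten members, half elite and half
maximally diverse under a scaled Euclidean + Hamming distance.  All RefSet
pairs are combined each iteration — continuous coordinates sampled in
biased hyper-rectangles along the parent difference (extending beyond both
parents, with more mass towards the better one), binary coordinates by
uniform crossover with a $1/\max(1,n_{bin})$ per-bit flip.  An offspring
that beats its parent triggers the *go-beyond* intensification: repeated,
doubling steps along the improving direction with the binary block frozen.
Stagnant members are aged out and replaced by fresh diversification, and a
memory of visited optima suppresses re-insertion of near-duplicates
(threshold $10^{-3}$ of the scaled box diagonal).

Local refinement (`local_refine_mixed`) alternates bounded quasi-Newton
descent (L-BFGS-B, finite differences at a relative step of $10^{-6}$) on
the continuous block with best-improvement 1-flip — then 2-flip — search on
the integer block.  The integer coordinates are only ever evaluated at
integral values; there is no relaxation anywhere in the solver, and an
auditing evaluation wrapper enforces this (and counts every objective
call).  This refinement honours the published contract of trust-region
mixed-integer SQP solvers (smoothness assumed, convexity not required,
integers never relaxed) and is implemented as a named strategy so a true
MISQP backend could be slotted in.  Because the fitting objective is
exactly invariant to parameters of deselected hyperedges, the descent skips
their finite-difference columns (`active_coords_fn`) — a measurable saving
at zero approximation cost.

### Cooperation

`run_cooperative` runs several eSS islands with deliberately different
settings (RefSet size 8/10/14, aggressive or conservative local search,
quality-vs-diversity balance), coordinated by a master process:

* a slave offers its local best when it improves the shared best-known
  solution by more than $\epsilon_{slave}$ (relative improvement, default
  1%);
* the master re-broadcasts only improvements beyond its own adaptive
  $\epsilon$ (initial 10%), halving $\epsilon$ after every 10 consecutive
  refusals down to the slave level — so cooperation is selective early and
  permissive late;
* each accepted solution scores a point for its island on a scoreboard;
* a slave that has spent more than $N_{par}\times 500$ evaluations since
  its last cooperation *and* received more than $4\times\mathrm{sent}+10$
  solutions declares stagnation (both printed criteria are required — a
  conjunction, to avoid reconfiguration storms; exposed as configuration)
  and requests reconfiguration: it receives the settings of the
  top-scoring island and re-diversifies its RefSet except for two retained
  members — its local best and the cooperative best.

All message passing goes through an in-process, deterministic transport
with per-link ordered delivery and seeded island interleaving, so a fixed
seed reproduces a cooperative run exactly — including on one CPU, where
"parallel" islands are interleaved iterations.  The relative-improvement
form of $\epsilon$ (with a tiny-denominator guard) was chosen because the
protocol must behave identically across objective scales; the numeric
defaults (0.1 initial, 0.01 floor and slave threshold, halving every 10
refusals) realize the intended qualitative behaviour.

## The synthetic benchmark generator

`generate_network` draws a DAG-biased signed digraph with the stimuli as
sources (80% activating edges), expands it with AND order 2 — the order cap
default follows standard practice of adding AND gates from pairs of inputs;
higher orders are available but off by default — and samples a true
sub-hypergraph in which every non-input protein keeps at least one gate.
True parameters are drawn well inside the bounds ($n\in[2,4]$,
$k\in[0.3,0.7]$, $\tau\in[0.5,2]$): sigmoidal but not degenerate switches,
the regime the Hill formalism is meant to capture.  `design_experiments`
builds either a full factorial or the classic ligand/inhibitor panel: every
non-zero stimulus combination crossed with (no inhibitor + each single
inhibitor) plus an unperturbed control, which yields the canonical 10
combinations for two ligands and two inhibitors.  Every stimulus must be
perturbed at least once (asserted at generation).  `generate_pseudodata`
simulates the truth, samples at `times = c(0, 3, 15)` by default (one
early-transient and one near-steady-state point for life-times up to 2),
adds zero-mean additive Gaussian noise with sd `noise_rel` (default 0.05 on
the normalized scale — "5% noise" read as additive on $[0,1]$) and clamps
into $[0,1]$, keeping the noiseless copy.

Two aspects of real data are deliberately *not* emulated: systematic
(non-Gaussian, correlated) measurement error, and model mismatch — the data
really are generated by a logic-ODE.  Passing the recovery tests therefore
demonstrates that the optimizer solves the mixed-integer inverse problem,
not that the logic-ODE formalism is adequate for any particular biology.

### Identifiability screening

Noiseless structure recovery is only a meaningful test when the true
selector is the *unique* structure reproducing the data: an extra gate that
can be parameterized to near-inertness fits perfectly and makes "exact
recovery" ill-posed.  `screen_identifiability` refines the continuous
parameters for every single-bit flip of the true selector (structure
frozen) and requires each flip to stay above an objective threshold.  The
canonical CI-scale benchmark (`ci_benchmark`: 6 species, 2 stimuli, 1
inhibitable node, about a dozen candidate hyperedges) is the first
generator seed of that size passing this screen
(`select_ci_benchmark`); single-bit flips are a necessary, not sufficient,
condition, which is the screen's known limitation.  Problem sizes
throughout the tests (a 6-species network, budgets of $10^4$–$2\times10^4$
evaluations, 10 seeds) were chosen so the whole recovery study runs in
minutes on a single core while the mixed-integer structure of the problem
— coupled continuous/binary decisions, multimodality, penalty regions —
remains intact.

## Known limitations

* Path constraints, terminal costs and free final time are outside the
  problem class handled here; controls are limited to piecewise-constant
  parameterizations (`control_parameterization`) of input clamps.
* Gradients are finite-difference; no forward sensitivity system is
  integrated.
* The transport is in-process and deterministic.  It implements the full
  asynchronous protocol (buffered per-link ordered delivery), but wall-time
  parallel speedups are out of scope for this implementation.
* The AND-gate expansion is combinatorial in the in-degree; the default
  order cap of 2 keeps candidate sets manageable, as is standard.
* The identifiability screen checks single-bit flips only; higher-order
  degeneracies (for instance a singleton traded for a compensating pair)
  are not excluded, though none occur in the canonical benchmark.
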