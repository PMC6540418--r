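---
title: "Methods: feedback-vertex-set unions and attractor control in multilayer networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feedback-vertex-set unions and attractor control in multilayer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multifvs)
```

## The model

A multiplex networked system has `N` nodes shared by `S` directed layers, one
interaction type per layer, each layer running its own nonlinear dynamics

$$\dot x(t) = F(x) + B\,u(t),$$

with layer-wise state $x = [x^{(1)},\dots,x^{(S)}]$ and a block-diagonal 0/1
control matrix $B$ selecting driver nodes. For decay-type nonlinearities,
controllability of one layer reduces to its **feedback vertex set**: clamp an
FVS to its values in a target attractor and the remaining network, now free of
feedback loops, relaxes onto that attractor. Assuming a node is a driver in
every layer or in none — the natural reading of a multiplex, where a node is
one physical entity — the multilayer driver-node problem is the **minimum
FVS-union problem**:

$$\min\ |F_1 \cup F_2 \cup \dots \cup F_S|,\qquad F_i \text{ an FVS of layer } i.$$

Both the objective and the per-layer feasibility are purely topological, which
is why the package parses but discards edge weights.

## Algorithms

### SG: exact single-layer minimum FVS

`sg_mfvs()` composes two stages.

1. **Reductions to fixpoint** (`simplify()`): R1 — a self-looped node is in
   every FVS (forced); R2 — a source, sink or isolated node is on no cycle
   (discarded); R3 — a node with in-degree 1 (resp. out-degree 1) and no
   self-loop is contracted into its sole predecessor (successor). All three
   preserve minimum FVS size; contraction may create self-loops that R1 then
   forces. Contracted nodes never need to enter the solution: the surviving
   endpoint covers the same cycles, so solutions of the residual are solutions
   of the original.
2. **Branch-and-bound** per strongly connected component of the residual:
   branch over the vertices of a shortest cycle (every FVS must hit it),
   pruning with the incumbent and a greedy vertex-disjoint-cycle lower bound,
   with a greedy FVS as the initial incumbent. Components are capped at
   `node_budget = 40` nodes; on the reduced residuals of sparse biological
   networks components are far smaller, and the cap turns a potential
   exponential blow-up into an explicit error suggesting the greedy path.

The suite validates SG against an independent subset-enumeration oracle
(`brute_force_mfvs()`) on 200 random digraphs with up to 12 nodes and edge
densities 0.1–0.5 — sizes chosen so the oracle itself stays exhaustive.

### ISG: the blind union

`isg()` solves every layer exactly and unites the results. It is always valid,
and it is the baseline the greedy method must beat: each layer's optimum is
chosen with no knowledge of the other layers, so the union is typically larger
than necessary. (The method's historical name speaks of an "intersection", but
an intersection of per-layer FVSs is generally not an FVS of any layer; the
union is what the optimisation model demands, and what is implemented.)

### IISG: greedy reuse of the reference FVS

`iisg()` designates a reference layer (the first, by default), solves it
exactly (`F_r`), and processes each remaining study layer in two phases,
maintaining that layer's FVS `F_i`:

* **Reference phase.** While some node of `F_r` still lies on a cycle of the
  study layer minus `F_i`: enumerate those passing loops (`L_i`), rank their
  nodes, and move the single top-ranked *dominated node* into `F_i`.
* **Residual phase.** While the study layer minus `F_i` still has cycles:
  enumerate them (`L_i'`), rank, move the top node into `F_i`.

The driver set is `F_r ∪ (∪_i F_i)`. With more than two layers the running
union plays the reference role for each subsequent study layer, so reference
nodes are reused everywhere.

**Dominated-node order.** The three dominance criteria are composed
lexicographically: membership in the reference FVS, then the count of
enumerated cycles through the node, then the function weight, then node id.
This order is fixed by the worked example: nodes 2 and 5 are picked first
*because* they are reference-FVS members, even though their loop counts (3
each) tie with nothing else distinguishing them, and function information is
explicitly the tie-breaker of last resort. One node is moved per iteration and
loop counts are recomputed, which guards against over-selection when one
removal breaks several counted loops at once.

**Exact residual option.** `exact_residual = TRUE` replaces the residual
phase's greedy picks with an exact FVS of the remaining study graph. It never
enlarges the result and often shrinks it; it is off by default because the
plain greedy procedure is the documented method, and the option exists as the
package's own refinement.

IISG is a heuristic: it is always valid (termination conditions are exact
acyclicity checks, not enumeration emptiness), always bounded below by the
exhaustive `min_union_oracle()`, but carries no optimality guarantee. On the
suite's 200 random duplexes it was no larger than ISG in 199 cases and once
larger by one node; those observed figures are frozen in the tests as
regression baselines, not claimed as theorems.

## Cycle enumeration

`enumerate_cycles()` lists directed simple cycles by backtracking from each
start vertex `s` in ascending node order, extending only to vertices ordered
after `s` within the same strongly connected component, and closing at `s`.
Each cycle appears exactly once, canonically rotated to start at its smallest
node; self-loops are length-1 cycles. Enumeration is exponential in general,
so a `cap` (default 100 000 cycles) sets a `truncated` flag; the greedy solver
then warns and re-ranks using cycles of length ≤ 12 (`fallback_len`).
Dominated-node ranking needs *relative* counts, so a length-bounded census
preserves the ranking's intent while keeping the cost polynomial for fixed
bound; FVS validity is never decided from a truncated enumeration.

## Dynamics and control validation

The control theory the union objective rests on is testable only once a
concrete vector field is fixed; the network data alone do not determine one.
`build_dynamics()` therefore instantiates the standard decay-plus-saturating
coupling form, layer by layer:

$$\dot x_i^{(\alpha)} = -d\, x_i^{(\alpha)} + \sum_{j \to i \in E_\alpha} w_{ij}\,\tanh\!\big(g\, x_j^{(\alpha)}\big),$$

the class for which FVS clamping is an established control principle. Defaults
(chosen once, before any validation was run): decay `d = 1` per unit time,
gain `g = 2`, weight magnitudes uniform in `[0.5, 1.5]`, sign positive with
probability 0.8. A positive 2-cycle with `w g > d` is already bistable, and
the positive-sign bias makes multistability — the regime where steering
between attractors is a non-trivial claim — common in random topologies.
Clamping is a hard state override of every driver coordinate in every layer
(the control-matrix form `B u(t)` is represented via `control_matrix()` for
completeness, but validation uses overrides, as the FVS control principle
prescribes).

Numerical choices: `deSolve::ode` (lsoda) integration; fixed-point residual
tolerance `1e-6`; attractor identity and control-success tolerance `1e-3` in
max norm; horizon `t_max = 200` time units; divergence declared beyond state
magnitude `1e6`. Trajectories of this bounded-coupling form cannot actually
diverge, but the guard keeps the integrator honest on user-supplied
parameters; non-convergence within the horizon (e.g. a limit cycle) is
reported as `converged = FALSE` rather than an error.

The control acceptance check uses 20 multistable models (random 6-node
duplexes × dynamics seeds, screened for ≥ 2 attractors by relaxation from 8
random states), 5 random initial states each: clamping the IISG driver set
must reach the target in ≥ 95% of the 100 trials, while the free system
started deep in a wrong basin must fail. These problem sizes keep the default
test run fast while leaving no slack for a silent regression: at these sizes
the observed success rate is 100%, against ~50% for equal-sized non-FVS sets.

## Synthetic data

`random_multilayer()` draws correlated Erdős–Rényi-style directed layers on a
shared universe: a base edge set is drawn once and each layer copies each
potential edge's base indicator with probability `layer_correlation`
(default 0.3, mimicking partially overlapping interaction layers), redrawing
it otherwise; an exact per-layer edge-count mode reproduces published network
shapes (e.g. a 14-node duplex with 38- and 42-edge layers). It emulates what
the algorithms are sensitive to — shared node universe, partially correlated
cycle structure, self-loops — and deliberately not what they are blind to:
degree heterogeneity, motif enrichment, edge signs and weights. Green tests on
these instances therefore certify algorithmic correctness, not biological
fidelity of any particular network.

`fig8_fixture()` reconstructs the worked two-layer example from its published
cycle inventory, since the edge list itself is not printed: FVS structure
depends only on cycle structure, so any realisation with exactly those simple
cycles reproduces the example. The published account lists four circles yet
also states that one circle on {3,4} remains after deleting nodes 2 and 5,
which a four-cycle inventory cannot produce; the fixture includes the 3⇄4
2-cycle, because the example's final answer (three drivers: {2,5} plus one of
{3,4}) requires it. One acyclic edge attaches node 6, which the example
describes as present but cycle-free. The constructor re-verifies the full
cycle inventory and the reference-layer optimum {2,5} on every call and errors
on any mismatch.

## Degenerate inputs and determinism

Acyclic layers yield empty FVSs and contribute no drivers; empty edge files
parse to edgeless layers with a warning; a single-layer network makes IISG
coincide with SG. All solvers are deterministic: node order is numeric-aware
and locale-independent, dominated ties break by node id, the branch-and-bound
explores a fixed order, and only the synthetic generator and the dynamics
module consume seeds. Equally sized optimal FVSs are genuinely ambiguous —
the contract is validity and size, and the reported membership is simply the
deterministic first optimum found.

## Known limitations

* IISG has no approximation guarantee; the oracle bound is only computable on
  small instances (`N ≤ 14` by default).
* Exact search is exponential in the worst case; the per-component budget
  makes that explicit rather than open-ended.
* Cycle enumeration under truncation ranks by bounded-length counts, which can
  reorder near-tied candidates on very dense graphs.
* The dynamics module validates the control principle on the decay-type class
  it instantiates; it does not claim to model any specific biological
  kinetics, and undirected or weighted notions of feedback are out of scope.
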