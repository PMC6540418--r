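# multifvs

Driver-node identification for nonlinear multilayer networks via minimum
feedback-vertex-set unions.

## The problem

Many biological systems — signalling networks, host–virus interactomes,
cancer–immune cell interaction networks — are naturally *multilayer*: a fixed
set of molecular or cellular players connected by several distinct types of
directed interaction, one layer per type, each layer running nonlinear
dynamics. A practical control question is: **which minimal set of nodes must
be externally overridden (clamped) so the whole system can be steered from any
initial state into any desired attractor, e.g. a healthy steady state?**

For a single layer with decay-type nonlinear dynamics, this control problem
maps onto the **feedback vertex set (FVS)**: a node set whose removal leaves
the directed graph acyclic. Clamping an FVS to its values in a target
attractor forces the remaining (now feedback-free) network to relax onto that
attractor. Under the standard multiplex assumption that a node is either a
driver in every layer or in none, the multilayer problem becomes a **minimum
FVS-union problem**: with `F_i` an FVS of layer `i`,

```
minimise |F_1 ∪ F_2 ∪ … ∪ F_S|
```

`multifvs` implements three solvers for this problem on directed multiplex
networks, plus the machinery to validate the control claim dynamically:

* **SG** — exact single-layer minimum FVS: FVS-preserving reductions
  (self-loop forcing, source/sink deletion, degree-1 contraction) followed by
  branch-and-bound over strongly connected components.
* **ISG** — the baseline union: solve every layer exactly with SG,
  independently, and take the union.
* **IISG** — the greedy improvement: solve a *reference layer* exactly, then
  process each *study layer* by repeatedly selecting *dominated nodes* —
  ranked by membership in the reference FVS, then by the number of simple
  cycles ("passing loops") through the node, then by a user-supplied function
  weight — until the study layer is acyclic. Reusing reference nodes first is
  what shrinks the union.
* an exhaustive **minimum-union oracle** for small instances, and an ODE
  simulator (`build_dynamics()`, `find_attractor()`, `clamp_and_simulate()`)
  that verifies clamping the identified drivers really steers a multistable
  nonlinear system into a chosen attractor.

## Worked example

The package ships the classic two-layer worked example as a generated
fixture: a 7-node duplex whose reference layer has minimum FVS {2, 5} and
whose study layer contains exactly the simple cycles {2} (a self-loop),
{1,2,5}, {2,5,4,3}, {1,5,7} and {3,4}.

```r
library(multifvs)

fx <- fig8_fixture()
sg_mfvs(fx$reference)
#> <fvs_result [SG] layer 'reference': size 2, valid>
#>   {2, 5}

iisg_duplex(fx$reference, fx$study)
#> <union_result [IISG]: 3 driver node(s), valid on 2/2 layers>
#>   {2, 3, 5}

compare_methods(multilayer(list(fx$reference, fx$study)))
#> # A tibble: 5 × 5
#>   method scope     size valid drivers
#>   <chr>  <chr>    <int> <lgl> <chr>
#> 1 SG     reference    2 TRUE  2,5
#> 2 SG     study        3 TRUE  2,4,7
#> 3 ISG    union        4 TRUE  2,4,5,7
#> 4 IISG   union        3 TRUE  2,3,5
#> 5 oracle union        3 TRUE  2,3,5
```

Reading the table: solving each layer blindly and uniting the results (ISG)
needs 4 drivers, because the study layer's exact solver is free to return an
optimum ({2,4,7}) that shares only one node with the reference FVS. IISG reuses the reference FVS {2, 5} — both
nodes lie on the most study-layer cycles (3 each) — and then only needs node 3
for the one remaining cycle on {3, 4}: 3 drivers, which the exhaustive oracle
confirms is optimal. Clamping those 3 nodes provably steers both layers'
decay-type dynamics to any attractor; `clamp_and_simulate()` demonstrates it
numerically.

A thin command-line wrapper is installed with the package (see
`exec/multifvs`):

```sh
multifvs synth --preset fig8 --out demo/
multifvs iisg --multiplex demo/fig8.multiplex
multifvs compare --multiplex demo/fig8.multiplex
```

## Running on real multiplex data

`read_multiplex()` parses the 4-column extended edge list
(`layer source target weight`) used by public multiplex repositories, and
`read_edge_list()` parses plain per-layer `src dst [weight]` files, so
published regulatory or host–virus multiplexes can be analysed once their
files are supplied:

```r
net <- read_multiplex("HIV1_gpi.edges")   # user-supplied file
validate_network(net)
res <- iisg(net, reference = 1, w = read_node_weights("functions.tsv"))
tidy(res)
```

Those network files are distributed by their original databases and are not
bundled here; all bundled and generated instances are synthetic.

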