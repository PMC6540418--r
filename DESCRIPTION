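Package: multifvs
Title: Driver-Node Identification in Nonlinear Multilayer Networks via
    Minimum Feedback Vertex Set Unions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the minimal set of driver nodes able to steer a
    nonlinear multilayer (multiplex) networked system to any of its
    attractors, by solving the minimum feedback-vertex-set (FVS) union
    problem across layers. Implements an exact single-layer solver built
    on FVS-preserving graph reductions and branch-and-bound (the SG
    algorithm), the per-layer union baseline (ISG), and a greedy
    improvement that reuses the reference layer's FVS and per-node cycle
    counts to shrink the union (IISG). Includes capped simple-cycle
    enumeration, readers for per-layer edge lists and multiplex extended
    edge lists, a synthetic-network generator, and an ODE simulator that
    validates FVS-based control by clamping driver nodes and checking
    convergence to a target attractor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
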