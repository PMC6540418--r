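# Synthetic networks and fixtures: the worked duplex example reconstructed
# from its printed cycle inventory, random correlated multilayer generators,
# and a writer that materialises a small oracle-verified fixture suite.

#' The worked duplex example
#'
#' Reconstructs the two-layer example used to illustrate the greedy algorithm.
#' Only the cycle structure is published, so the edge set is derived from it:
#' the study layer's simple cycles are exactly a self-loop at node 2, cycles
#' on node sets \{1,2,5\}, \{2,5,4,3\} and \{1,5,7\}, plus the 2-cycle on
#' \{3,4\} that remains after deleting nodes 2 and 5; node 6 is attached by a
#' single acyclic edge. The reference layer is four 2-cycles arranged so its
#' unique minimum FVS is \{2,5\}. Both claims are re-verified at construction
#' time (cycle inventory by enumeration, reference FVS by the exact solver);
#' any mismatch is an internal error.
#'
#' @return List with elements `reference` and `study`, both [layer()] objects
#'   on nodes 1..7.
#' @examples
#' fx <- fig8_fixture()
#' sg_mfvs(fx$reference)$fvs
#' @export
fig8_fixture <- function() {
  study <- layer(
    data.frame(
      from = c("2", "1", "2", "5", "5", "4", "3", "1", "7", "3", "2"),
      to   = c("2", "2", "5", "1", "4", "3", "2", "7", "5", "4", "6")
    ),
    nodes = as.character(1:7), layer_id = "study"
  )
  reference <- layer(
    data.frame(
      from = c("2", "1", "2", "6", "5", "4", "5", "7"),
      to   = c("1", "2", "6", "2", "4", "5", "7", "5")
    ),
    nodes = as.character(1:7), layer_id = "reference"
  )
  expected <- list("2", c("1", "2", "5"), c("1", "5", "7"), c("2", "5", "4", "3"),
                   c("3", "4"))
  got <- enumerate_cycles(study)$cycles
  key <- function(cys) sort(map_chr(cys, function(cy) paste(sort(cy), collapse = ",")))
  if (!identical(key(got), key(expected))) {
    abort("fig8_fixture: study-layer cycle inventory failed its consistency check.")
  }
  if (!identical(sg_mfvs(reference)$fvs, c("2", "5"))) {
    abort("fig8_fixture: reference-layer minimum FVS is not {2, 5}.")
  }
  list(reference = reference, study = study)
}

#' Generate a random multilayer network
#'
#' Draws `S` directed Erdos-Renyi-style layers on a shared `n`-node universe.
#' A base edge set is drawn first; each layer copies the base indicator for
#' every possible edge with probability `layer_correlation` and redraws it
#' otherwise, so layers share roughly that fraction of structure — mimicking
#' partially overlapping biological interaction layers. Alternatively,
#' `n_edges` fixes exact per-layer edge counts, with about
#' `layer_correlation` of the smaller count shared across layers.
#'
#' @param n Number of nodes (ids `"1" .. "n"`).
#' @param S Number of layers.
#' @param edge_prob Probability of each ordered non-self pair (ignored when
#'   `n_edges` is given).
#' @param n_edges Optional integer vector (length `S`) of exact per-layer edge
#'   counts.
#' @param layer_correlation Fraction of structure shared between layers, in
#'   `[0, 1]`.
#' @param self_loop_prob Per-node self-loop probability.
#' @param seed Integer seed; fixed seed implies fixed output.
#' @return A [multilayer()] network with layer ids `"1" .. "S"`.
#' @export
random_multilayer <- function(n, S = 2, edge_prob = 0.15, n_edges = NULL,
                              layer_correlation = 0.3, self_loop_prob = 0,
                              seed = 1) {
  stopifnot(n >= 1, S >= 1,
            layer_correlation >= 0, layer_correlation <= 1,
            self_loop_prob >= 0, self_loop_prob <= 1)
  nodes <- as.character(seq_len(n))
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  m_all <- nrow(pairs)
  layers <- withr::with_seed(seed, {
    if (is.null(n_edges)) {
      base <- runif(m_all) < edge_prob
      map(seq_len(S), function(a) {
        keep_base <- runif(m_all) < layer_correlation
        ind <- ifelse(keep_base, base, runif(m_all) < edge_prob)
        sl <- nodes[runif(n) < self_loop_prob]
        ed <- data.frame(from = c(nodes[pairs$from[ind]], sl),
                         to = c(nodes[pairs$to[ind]], sl))
        layer(ed, nodes = nodes, layer_id = as.character(a))
      })
    } else {
      if (length(n_edges) != S) abort("`n_edges` must have one count per layer.")
      if (any(n_edges > m_all)) {
        abort(sprintf("Requested edge count exceeds the %d possible edges.", m_all))
      }
      n_shared <- round(layer_correlation * min(n_edges))
      base_idx <- sample.int(m_all, n_shared)
      map(seq_len(S), function(a) {
        extra <- sample(setdiff(seq_len(m_all), base_idx), n_edges[a] - n_shared)
        ind <- c(base_idx, extra)
        sl <- nodes[runif(n) < self_loop_prob]
        ed <- data.frame(from = c(nodes[pairs$from[ind]], sl),
                         to = c(nodes[pairs$to[ind]], sl))
        layer(ed, nodes = nodes, layer_id = as.character(a))
      })
    }
  })
  multilayer(layers, node_universe = nodes)
}

#' Write a suite of plain-text network fixtures
#'
#' Materialises, under `dir`: the worked duplex example (per-layer edge lists
#' and a multiplex file), two small random duplexes whose minimum-union sizes
#' are computed by the exhaustive oracle at write time, and a duplex shaped
#' like a 14-node cancer-immune cell-cell network (38- and 42-edge layers).
#' A `manifest.tsv` records every file with its format and machine-readable
#' expected values. Re-running overwrites byte-identically.
#'
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly written as `manifest.tsv`.
#' @export
write_fixture_suite <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  add <- function(instance, file, format, expected) {
    rows[[length(rows) + 1]] <<- tibble(instance = instance, file = file,
                                        format = format, expected = expected)
  }

  fx <- fig8_fixture()
  write_edge_list(fx$reference, file.path(dir, "fig8_reference.tsv"))
  write_edge_list(fx$study, file.path(dir, "fig8_study.tsv"))
  write_multiplex(multilayer(list(fx$reference, fx$study)),
                  file.path(dir, "fig8.multiplex"))
  add("fig8", "fig8_reference.tsv", "edge_list", "sg_mfvs_size=2")
  add("fig8", "fig8_study.tsv", "edge_list", "sg_mfvs_size=3")
  add("fig8", "fig8.multiplex", "multiplex", "iisg_size=3")

  for (sd in c(101L, 202L)) {
    net <- random_multilayer(n = 8, S = 2, edge_prob = 0.2, seed = sd)
    f <- sprintf("duplex_n8_seed%d.multiplex", sd)
    write_multiplex(net, file.path(dir, f))
    opt <- min_union_oracle(net)
    add(sprintf("duplex_seed%d", sd), f, "multiplex",
        sprintf("min_union_size=%d", opt$size))
  }

  cicc <- random_multilayer(n = 14, S = 2, n_edges = c(38L, 42L), seed = 303L)
  write_multiplex(cicc, file.path(dir, "cicc_shaped.multiplex"))
  add("cicc_shaped", "cicc_shaped.multiplex", "multiplex",
      "layer_edges=38,42")

  manifest <- bind_rows(rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
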