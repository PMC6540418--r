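#' Assemble layers into a multilayer (multiplex) network
#'
#' A multilayer network is an ordered list of directed layers sharing one node
#' universe. Every layer is expanded to the full universe (isolated nodes are
#' permitted), mirroring the multiplex model in which a fixed node set is
#' connected by several interaction types.
#'
#' @param layers A list of [layer()] objects (or a single layer).
#' @param node_universe Optional character vector forcing extra nodes into the
#'   shared universe; defaults to the union of all layers' node sets.
#'
#' @return An object of class `multilayer_network` with fields `layers`
#'   (named list, each expanded to the universe), `node_universe`, `S` (layer
#'   count) and `N` (node count). Each stored layer keeps its pre-expansion
#'   node set in the `raw_nodes` attribute for reporting.
#' @examples
#' l1 <- layer(data.frame(from = "a", to = "b"), layer_id = "ppi")
#' l2 <- layer(data.frame(from = "b", to = "a"), layer_id = "reg")
#' net <- multilayer(list(l1, l2))
#' net$S
#' @export
multilayer <- function(layers, node_universe = NULL) {
  if (inherits(layers, "fvs_layer")) layers <- list(layers)
  if (length(layers) < 1) abort("A multilayer network needs at least 1 layer.")
  if (!all(map_lgl(layers, inherits, "fvs_layer"))) {
    abort("`layers` must all be `fvs_layer` objects.")
  }
  universe <- node_sort(unique(c(
    as.character(node_universe %||% character(0)),
    unlist(map(layers, layer_nodes))
  )))
  ids <- map_chr(layers, "layer_id")
  if (anyDuplicated(ids)) abort("Duplicate layer ids.")
  expanded <- map(layers, function(l) {
    raw <- l$nodes
    l2 <- layer(l$edges, nodes = universe, layer_id = l$layer_id)
    attr(l2, "raw_nodes") <- raw
    l2
  })
  names(expanded) <- ids
  structure(
    list(layers = expanded, node_universe = universe,
         S = length(expanded), N = length(universe)),
    class = "multilayer_network"
  )
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("<multilayer_network: S = %d layers, N = %d nodes>\n", x$S, x$N))
  for (l in x$layers) {
    cat(sprintf("  %s: %d edges (%d self-loops)\n",
                l$layer_id, n_edges(l), sum(l$edges$from == l$edges$to)))
  }
  invisible(x)
}

#' @export
as_tibble.multilayer_network <- function(x, ...) {
  bind_rows(map(x$layers, as_tibble))
}

#' Structural report for a multilayer network
#'
#' Report-only validation: per-layer node and edge counts, self-loop counts,
#' and the nodes each raw layer lacked before expansion to the shared
#' universe. Never raises.
#'
#' @param net A `multilayer_network`.
#' @return A tibble with one row per layer: `layer_id`, `n_nodes`, `n_edges`,
#'   `self_loops`, `raw_nodes` (node count before universe expansion) and
#'   `expanded_by` (nodes added to reach the universe). The shared universe
#'   size is in the `node_universe` attribute.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "multilayer_network"))
  rep <- bind_rows(map(net$layers, function(l) {
    raw <- attr(l, "raw_nodes") %||% l$nodes
    tibble(
      layer_id = l$layer_id,
      n_nodes = n_nodes(l),
      n_edges = n_edges(l),
      self_loops = sum(l$edges$from == l$edges$to),
      raw_nodes = length(raw),
      expanded_by = length(setdiff(l$nodes, raw))
    )
  }))
  attr(rep, "node_universe") <- net$N
  rep
}
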