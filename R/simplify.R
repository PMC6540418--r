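#' FVS-preserving graph simplification
#'
#' Applies, to fixpoint, three classical reductions that preserve minimum
#' feedback vertex sets:
#' * R1 — a node with a self-loop is in every FVS: move it to `forced_nodes`
#'   and delete it;
#' * R2 — a node with in-degree 0 or out-degree 0 is on no cycle: move it to
#'   `removed_nodes` and delete it;
#' * R3 — a node with in-degree 1 (resp. out-degree 1) and no self-loop is
#'   contracted into its sole predecessor (resp. successor); the merge is
#'   recorded. Contractions can create self-loops, which R1 then forces.
#'
#' An MFVS of the original layer is `forced_nodes` union an MFVS of the
#' residual (contracted nodes never need to enter the solution because the
#' surviving endpoint covers the same cycles).
#'
#' @param layer An [layer()] object.
#' @return An object of class `reduction_trace`: list with `forced_nodes`,
#'   `removed_nodes`, `contracted_pairs` (tibble `from` = deleted node,
#'   `into` = survivor) and `residual` (a layer in which every node has
#'   in-degree and out-degree at least 2 and no self-loop).
#' @export
simplify <- function(layer) {
  stopifnot(inherits(layer, "fvs_layer"))
  nodes <- layer$nodes
  ed <- layer$edges
  forced <- character(0)
  removed <- character(0)
  merges_from <- character(0)
  merges_into <- character(0)

  drop_nodes <- function(ed, drop) {
    ed[!(ed$from %in% drop | ed$to %in% drop), , drop = FALSE]
  }

  repeat {
    # R1: self-loops force membership.
    sl <- unique(ed$from[ed$from == ed$to])
    if (length(sl) > 0) {
      forced <- c(forced, sl)
      nodes <- setdiff(nodes, sl)
      ed <- drop_nodes(ed, sl)
      next
    }
    # R2: sources, sinks and isolated nodes lie on no cycle.
    d0 <- nodes[!(nodes %in% ed$from) | !(nodes %in% ed$to)]
    if (length(d0) > 0) {
      removed <- c(removed, d0)
      nodes <- setdiff(nodes, d0)
      ed <- drop_nodes(ed, d0)
      next
    }
    # R3: contract one degree-1 node (deterministic: first in node order).
    indeg <- table(ed$to)
    outdeg <- table(ed$from)
    cand_in <- names(indeg)[indeg == 1]
    cand_out <- names(outdeg)[outdeg == 1]
    cand <- node_sort(union(cand_in, cand_out))
    if (length(cand) == 0) break
    v <- cand[[1]]
    if (v %in% cand_in) {
      u <- ed$from[ed$to == v]
      # redirect v's out-edges to start at u
      ed$from[ed$from == v] <- u
      ed <- ed[ed$to != v, , drop = FALSE]
    } else {
      u <- ed$to[ed$from == v]
      ed$to[ed$to == v] <- u
      ed <- ed[ed$from != v, , drop = FALSE]
    }
    merges_from <- c(merges_from, v)
    merges_into <- c(merges_into, u)
    nodes <- setdiff(nodes, v)
    ed <- distinct(ed)
  }

  structure(
    list(
      forced_nodes = node_sort(forced),
      removed_nodes = node_sort(removed),
      contracted_pairs = tibble(from = merges_from, into = merges_into),
      residual = layer(ed, nodes = nodes, layer_id = layer$layer_id)
    ),
    class = "reduction_trace"
  )
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat(sprintf(
    "<reduction_trace: %d forced, %d removed, %d contracted; residual %d nodes / %d edges>\n",
    length(x$forced_nodes), length(x$removed_nodes),
    nrow(x$contracted_pairs), n_nodes(x$residual), n_edges(x$residual)
  ))
  invisible(x)
}
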