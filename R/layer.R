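#' Construct a directed network layer
#'
#' A layer is one interaction type of a multilayer network: a directed graph
#' on a set of node ids. Parallel edges are collapsed to one; self-loops are
#' kept (a self-loop is a directed cycle, so it forces its node into every
#' feedback vertex set). Node ids are opaque strings and are never case-folded.
#'
#' @param edges A data frame whose first two columns are the source and target
#'   node ids of each directed edge (extra columns, e.g. weights, are
#'   ignored), or `NULL` for an edgeless layer.
#' @param nodes Optional character vector of node ids; the layer's node set is
#'   the union of `nodes` and all edge endpoints, so isolated nodes can be
#'   declared.
#' @param layer_id Label for the layer.
#'
#' @return An object of class `fvs_layer` with fields `layer_id`, `nodes`
#'   (sorted character vector) and `edges` (tibble with columns `from`, `to`).
#' @examples
#' lay <- layer(data.frame(from = c("a", "b"), to = c("b", "a")))
#' n_nodes(lay)
#' @export
layer <- function(edges = NULL, nodes = NULL, layer_id = "layer1") {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    ed <- tibble(from = character(0), to = character(0))
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2) {
      abort("`edges` must have at least two columns (source, target).")
    }
    ed <- tibble(
      from = as.character(edges[[1]]),
      to = as.character(edges[[2]])
    )
    if (anyNA(ed$from) || anyNA(ed$to)) {
      abort("`edges` contains missing node ids.")
    }
    ed <- distinct(ed)
  }
  all_nodes <- node_sort(unique(c(as.character(nodes %||% character(0)),
                                  ed$from, ed$to)))
  structure(
    list(layer_id = layer_id, nodes = all_nodes, edges = ed),
    class = "fvs_layer"
  )
}

#' @export
print.fvs_layer <- function(x, ...) {
  cat(sprintf(
    "<fvs_layer '%s': %d nodes, %d edges (%d self-loops)>\n",
    x$layer_id, length(x$nodes), nrow(x$edges), sum(x$edges$from == x$edges$to)
  ))
  invisible(x)
}

#' @export
as_tibble.fvs_layer <- function(x, ...) {
  mutate(x$edges, layer_id = x$layer_id, .before = 1)
}

#' Layer accessors
#'
#' @param layer An `fvs_layer`.
#' @return `n_nodes()` and `n_edges()` return integers; `layer_nodes()` the
#'   sorted character vector of node ids.
#' @export
n_nodes <- function(layer) {
  stopifnot(inherits(layer, "fvs_layer"))
  length(layer$nodes)
}

#' @rdname n_nodes
#' @export
n_edges <- function(layer) {
  stopifnot(inherits(layer, "fvs_layer"))
  nrow(layer$edges)
}

#' @rdname n_nodes
#' @export
layer_nodes <- function(layer) {
  stopifnot(inherits(layer, "fvs_layer"))
  layer$nodes
}

# igraph view of a layer (vertices carry the node ids as names).
layer_igraph <- function(layer) {
  igraph::graph_from_data_frame(
    as.data.frame(layer$edges),
    directed = TRUE,
    vertices = data.frame(name = layer$nodes)
  )
}

# Integer adjacency index of a layer.
layer_index <- function(layer) {
  graph_index(layer$nodes, layer$edges$from, layer$edges$to)
}

# Induced sublayer after deleting `drop` nodes (unknown ids are an error).
delete_layer_nodes <- function(layer, drop) {
  drop <- as.character(drop)
  unknown <- setdiff(drop, layer$nodes)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown node(s): %s", paste(unknown, collapse = ", ")))
  }
  keep <- setdiff(layer$nodes, drop)
  ed <- filter(layer$edges, .data$from %in% keep, .data$to %in% keep)
  layer(ed, nodes = keep, layer_id = layer$layer_id)
}

#' @importFrom rlang .data
NULL
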