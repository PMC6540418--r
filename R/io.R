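# Readers and writers for the two plain-text network dialects plus the
# node-weight table. All parsing is by whitespace splitting so tab- and
# space-separated files are both accepted.

split_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(text = lines[keep], lineno = which(keep))
}

#' Read a per-layer directed edge list
#'
#' Format: one edge per line, `src<TAB>dst[<TAB>weight]` (any whitespace
#' separator); lines starting with `#` are comments. A third weight column is
#' parsed but discarded: the feedback-vertex-set machinery is purely
#' topological. Duplicate edges collapse to one.
#'
#' @param path Path to the edge-list file.
#' @param layer_id Label for the resulting layer.
#' @return An [layer()] object.
#' @export
read_edge_list <- function(path, layer_id = basename(path)) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  parsed <- split_lines(path)
  if (length(parsed$text) == 0) {
    warn(sprintf("Edge list '%s' has no edges; returning an empty layer.", path))
    return(layer(NULL, layer_id = layer_id))
  }
  toks <- strsplit(trimws(parsed$text), "\\s+")
  bad <- which(lengths(toks) < 2)
  if (length(bad) > 0) {
    abort(sprintf("Malformed edge list line %d in '%s': need at least 2 tokens.",
                  parsed$lineno[bad[1]], path))
  }
  layer(
    data.frame(from = map_chr(toks, 1), to = map_chr(toks, 2)),
    layer_id = layer_id
  )
}

#' Read a multiplex extended edge list
#'
#' Parses the 4-column dialect `layer source target weight` used by multiplex
#' network repositories. Layer ids must be positive integers; one layer is
#' built per distinct id, ordered ascending (this order defines the default
#' reference layer). The node universe is the union of all endpoints and every
#' layer is expanded to it. Weights are parsed but discarded.
#'
#' @param path Path to the multiplex file.
#' @return A [multilayer()] network.
#' @export
read_multiplex <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  parsed <- split_lines(path)
  if (length(parsed$text) == 0) {
    abort(sprintf("Multiplex file '%s' has no edges.", path))
  }
  toks <- strsplit(trimws(parsed$text), "\\s+")
  bad <- which(lengths(toks) != 4)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed multiplex line %d in '%s': expected 4 tokens (layer src dst weight), got %d.",
      parsed$lineno[bad[1]], path, lengths(toks)[bad[1]]))
  }
  lid_raw <- map_chr(toks, 1)
  lid <- suppressWarnings(as.integer(lid_raw))
  bad_id <- which(is.na(lid) | lid < 1 | lid_raw != as.character(lid))
  if (length(bad_id) > 0) {
    abort(sprintf("Multiplex line %d in '%s': layer id '%s' is not a positive integer.",
                  parsed$lineno[bad_id[1]], path, lid_raw[bad_id[1]]))
  }
  df <- tibble(lid = lid, from = map_chr(toks, 2), to = map_chr(toks, 3))
  layers <- map(sort(unique(df$lid)), function(id) {
    sub <- filter(df, .data$lid == id)
    layer(sub[, c("from", "to")], layer_id = as.character(id))
  })
  multilayer(layers)
}

#' Read a node function-weight table
#'
#' Two whitespace-separated columns: node id, non-negative numeric weight.
#' Unlisted nodes default to weight 0 on lookup ([weight_of()]). These
#' weights stand in for "biological function" when ranking dominated nodes.
#'
#' @param path Path to the table; an empty file yields all-zero weights.
#' @return A named numeric vector of class `function_weights`.
#' @export
read_node_weights <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  parsed <- split_lines(path)
  if (length(parsed$text) == 0) return(function_weights())
  toks <- strsplit(trimws(parsed$text), "\\s+")
  bad <- which(lengths(toks) < 2)
  if (length(bad) > 0) {
    abort(sprintf("Malformed weight line %d in '%s': need node id and weight.",
                  parsed$lineno[bad[1]], path))
  }
  w <- suppressWarnings(as.numeric(map_chr(toks, 2)))
  if (anyNA(w)) {
    abort(sprintf("Non-numeric weight on line %d of '%s'.",
                  parsed$lineno[which(is.na(w))[1]], path))
  }
  function_weights(setNames(w, map_chr(toks, 1)))
}

#' Construct function weights
#'
#' @param x Named non-negative numeric vector (node id -> weight).
#' @return A `function_weights` object.
#' @export
function_weights <- function(x = numeric(0)) {
  x <- unlist(x)
  if (length(x) > 0 && (is.null(names(x)) || any(names(x) == ""))) {
    abort("Function weights must be named by node id.")
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("Function weights must be finite and non-negative.")
  }
  structure(setNames(as.numeric(x), names(x)), class = "function_weights")
}

#' @rdname function_weights
#' @param w A `function_weights` object (or `NULL` for all-zero weights).
#' @param nodes Character vector of node ids to look up.
#' @return `weight_of()`: numeric vector of weights, 0 for unlisted nodes.
#' @export
weight_of <- function(w, nodes) {
  nodes <- as.character(nodes)
  if (is.null(w) || length(w) == 0) return(numeric(length(nodes)))
  out <- unclass(w)[nodes]
  out[is.na(out)] <- 0
  unname(out)
}

#' Write network files
#'
#' `write_edge_list()` emits `src<TAB>dst` lines; `write_multiplex()` emits
#' the 4-column `layer src dst weight` dialect (weight 1). Both are
#' byte-stable: rewriting the same object reproduces the file exactly.
#'
#' @param layer An `fvs_layer`.
#' @param net A `multilayer_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(layer, path) {
  stopifnot(inherits(layer, "fvs_layer"))
  ed <- layer$edges
  ord <- order(match(ed$from, layer$nodes), match(ed$to, layer$nodes))
  writeLines(paste(ed$from[ord], ed$to[ord], sep = "\t"), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_multiplex <- function(net, path) {
  stopifnot(inherits(net, "multilayer_network"))
  lines <- unlist(map(seq_along(net$layers), function(i) {
    l <- net$layers[[i]]
    ed <- l$edges
    if (nrow(ed) == 0) return(character(0))
    ord <- order(match(ed$from, l$nodes), match(ed$to, l$nodes))
    paste(i, ed$from[ord], ed$to[ord], 1)
  }))
  writeLines(lines, path)
  invisible(path)
}
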