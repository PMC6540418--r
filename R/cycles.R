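# Simple-cycle enumeration and per-node loop-membership counts. These are the
# "passing loops" that drive the dominated-node ranking of the greedy
# multilayer solver.

new_cycle_set <- function(cycles, truncated, cap, layer_id = NULL) {
  structure(
    list(cycles = cycles, truncated = truncated, cap = cap,
         layer_id = layer_id),
    class = "cycle_set"
  )
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set: %d cycle(s)%s>\n", length(x$cycles),
              if (x$truncated) sprintf(" [truncated at cap %d]", x$cap) else ""))
  for (cy in head(x$cycles, 20)) {
    cat("  ", paste(cy, collapse = " -> "), "\n")
  }
  if (length(x$cycles) > 20) cat("  ...\n")
  invisible(x)
}

#' @export
as_tibble.cycle_set <- function(x, ...) {
  tibble(
    cycle_id = seq_along(x$cycles),
    length = lengths(x$cycles),
    nodes = x$cycles
  )
}

#' @export
length.cycle_set <- function(x) length(x$cycles)

#' Enumerate the directed simple cycles of a layer
#'
#' Backtracking enumeration restricted to strongly connected components: for
#' each start vertex `s` in ascending node order, simple paths are grown over
#' vertices ordered after `s` (within the same component) and recorded when
#' they close back at `s`. Each cycle is therefore produced exactly once, in
#' its canonical rotation starting at its smallest node, in a deterministic
#' order. Self-loops are cycles of length 1.
#'
#' @param layer An [layer()] object.
#' @param cap Stop after this many cycles and set the `truncated` flag
#'   (dominated-node ranking only needs relative counts, so a truncated or
#'   length-bounded enumeration is still usable).
#' @param max_len Optional bound on cycle length (number of nodes); `Inf`
#'   enumerates all simple cycles.
#' @return A `cycle_set`: list of node-id sequences plus `truncated` and
#'   `cap`.
#' @examples
#' tri <- layer(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")))
#' enumerate_cycles(tri)
#' @export
enumerate_cycles <- function(layer, cap = 100000, max_len = Inf) {
  stopifnot(inherits(layer, "fvs_layer"), cap >= 1)
  idx <- layer_index(layer)
  n <- idx$n
  out <- vector("list", 256)
  count <- 0L
  truncated <- FALSE
  if (n > 0 && nrow(layer$edges) > 0) {
    g <- layer_igraph(layer)
    memb <- igraph::components(g, mode = "strong")$membership[idx$nodes]
    path <- integer(n)
    onpath <- logical(n)
    for (s in seq_len(n)) {
      if (truncated) break
      # self-loop at s
      if (s %in% idx$adj[[s]]) {
        count <- count + 1L
        if (count > length(out)) out <- c(out, vector("list", length(out)))
        out[[count]] <- idx$nodes[s]
        if (count >= cap) { truncated <- TRUE; break }
      }
      if (max_len < 2) next
      # grow simple paths s -> ... over vertices > s in the same SCC
      depth <- 1L
      path[1] <- s
      onpath[s] <- TRUE
      iter <- vector("list", n)
      iter[[1]] <- idx$adj[[s]]
      while (depth > 0L) {
        nexts <- iter[[depth]]
        if (length(nexts) == 0) {
          onpath[path[depth]] <- FALSE
          depth <- depth - 1L
          next
        }
        w <- nexts[[1]]
        iter[[depth]] <- nexts[-1]
        if (w == s && depth >= 2L) {
          count <- count + 1L
          if (count > length(out)) out <- c(out, vector("list", length(out)))
          out[[count]] <- idx$nodes[path[seq_len(depth)]]
          if (count >= cap) { truncated <- TRUE; break }
        } else if (w > s && !onpath[w] && memb[w] == memb[s] &&
                   depth + 1L <= max_len) {
          depth <- depth + 1L
          path[depth] <- w
          onpath[w] <- TRUE
          iter[[depth]] <- idx$adj[[w]]
        }
      }
      onpath[] <- FALSE
      if (truncated) break
    }
  }
  new_cycle_set(out[seq_len(count)], truncated, cap, layer$layer_id)
}

#' Count how many cycles pass through each node
#'
#' @param cycles A `cycle_set`.
#' @param nodes Character vector of node ids to query.
#' @return A tibble with columns `node` and `n_cycles` (0 for nodes on no
#'   enumerated cycle), one row per queried node, in query order.
#' @export
loops_through <- function(cycles, nodes) {
  stopifnot(inherits(cycles, "cycle_set"))
  nodes <- as.character(nodes)
  tal <- table(unlist(cycles$cycles))
  cnt <- as.integer(tal[nodes])
  cnt[is.na(cnt)] <- 0L
  tibble(node = nodes, n_cycles = cnt)
}

#' Cycles remaining after removing a node set
#'
#' Enumerates the simple cycles of the subgraph induced on the layer's nodes
#' minus `removed`. Empty output is equivalent to `removed` being a feedback
#' vertex set.
#'
#' @param layer An [layer()] object.
#' @param removed Character vector of nodes to delete (must belong to the
#'   layer).
#' @inheritParams enumerate_cycles
#' @return A `cycle_set`.
#' @export
residual_cycles <- function(layer, removed, cap = 100000, max_len = Inf) {
  enumerate_cycles(delete_layer_nodes(layer, removed), cap = cap,
                   max_len = max_len)
}
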