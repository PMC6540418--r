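# Single-layer minimum feedback vertex set machinery: validity checking,
# brute-force oracle, and the simplification + branch-and-bound exact solver.

new_fvs_result <- function(layer, fvs, method) {
  fvs <- node_sort(unique(as.character(fvs)))
  structure(
    list(
      layer_id = layer$layer_id,
      fvs = fvs,
      method = method,
      is_valid = is_fvs(layer, fvs),
      size = length(fvs)
    ),
    class = "fvs_result"
  )
}

#' @export
print.fvs_result <- function(x, ...) {
  cat(sprintf("<fvs_result [%s] layer '%s': size %d, %s>\n  {%s}\n",
              x$method, x$layer_id, x$size,
              if (x$is_valid) "valid" else "INVALID",
              paste(x$fvs, collapse = ", ")))
  invisible(x)
}

#' Is a node set a feedback vertex set?
#'
#' A candidate is an FVS of a directed layer iff deleting it leaves the layer
#' without directed cycles (checked by topological sortability of the induced
#' subgraph; self-loops count as cycles).
#'
#' @param layer An [layer()] object.
#' @param candidate Character vector of node ids (must all belong to the
#'   layer).
#' @return `TRUE` or `FALSE`.
#' @examples
#' tri <- layer(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")))
#' is_fvs(tri, "a")
#' is_fvs(tri, character(0))
#' @export
is_fvs <- function(layer, candidate) {
  stopifnot(inherits(layer, "fvs_layer"))
  candidate <- as.character(candidate)
  unknown <- setdiff(candidate, layer$nodes)
  if (length(unknown) > 0) {
    abort(sprintf("Candidate contains unknown node(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  res <- delete_layer_nodes(layer, candidate)
  if (any(res$edges$from == res$edges$to)) return(FALSE)
  igraph::is_dag(layer_igraph(res))
}

# ---- internal branch-and-bound on an integer adjacency index -----------

# Shortest directed cycle among alive vertices (no self-loops assumed).
# Returns an integer vector of cycle vertices, or NULL if acyclic.
shortest_cycle_idx <- function(adj, alive) {
  n <- length(adj)
  best <- NULL
  best_len <- Inf
  for (s in which(alive)) {
    # BFS from s over alive vertices
    dist <- rep(Inf, n)
    parent <- integer(n)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      if (dist[v] + 1 >= best_len) next
      for (w in adj[[v]]) {
        if (!alive[w] || w == v) next
        if (w == s) {
          # closed walk s -> ... -> v -> s, length dist[v]+1, simple by BFS tree
          len <- dist[v] + 1
          if (len < best_len) {
            cyc <- v
            p <- v
            while (p != s) {
              p <- parent[p]
              cyc <- c(cyc, p)
            }
            best <- cyc
            best_len <- len
          }
        } else if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          parent[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (best_len == 2) break
  }
  best
}

# Lower bound: size of a greedy packing of vertex-disjoint cycles.
disjoint_cycle_bound <- function(adj, alive) {
  k <- 0L
  alive <- alive
  repeat {
    cyc <- shortest_cycle_idx(adj, alive)
    if (is.null(cyc)) return(k)
    k <- k + 1L
    alive[cyc] <- FALSE
  }
}

# Greedy upper-bound FVS: remove the on-cycle vertex with the largest
# in*out degree product until acyclic. Deterministic.
greedy_fvs_idx <- function(adj, alive) {
  n <- length(adj)
  chosen <- integer(0)
  repeat {
    if (is_acyclic_idx(adj, alive)) return(chosen)
    onc <- on_cycle_idx(adj, alive)
    indeg <- integer(n)
    outdeg <- integer(n)
    for (i in which(alive)) {
      nb <- adj[[i]]
      nb <- nb[alive[nb]]
      outdeg[i] <- length(nb)
      indeg[nb] <- indeg[nb] + 1L
    }
    score <- ifelse(onc, (indeg + 1L) * (outdeg + 1L), -1L)
    v <- which.max(score)
    chosen <- c(chosen, v)
    alive[v] <- FALSE
  }
}

# Exact MFVS of the graph induced on `alive`, by branch-and-bound over the
# vertices of a shortest cycle. Self-loops are handled by an inline R1.
bb_mfvs_idx <- function(adj, alive, node_budget = 40) {
  if (sum(alive) > node_budget) {
    abort(sprintf(
      paste0("A strongly connected component with %d nodes exceeds the exact-search ",
             "budget (%d). Raise `node_budget` or use the greedy/ISG path."),
      sum(alive), node_budget))
  }
  env <- new.env(parent = emptyenv())
  env$best <- greedy_fvs_idx(adj, alive)

  reduce <- function(alive, chosen) {
    n <- length(adj)
    repeat {
      changed <- FALSE
      for (v in which(alive)) {
        nb <- adj[[v]]
        nb <- nb[alive[nb]]
        if (any(nb == v)) {            # self-loop: forced
          chosen <- c(chosen, v)
          alive[v] <- FALSE
          changed <- TRUE
        }
      }
      indeg <- integer(n)
      outdeg <- integer(n)
      for (v in which(alive)) {
        nb <- adj[[v]]
        nb <- nb[alive[nb] & nb != v]
        outdeg[v] <- length(nb)
        indeg[nb] <- indeg[nb] + 1L
      }
      d0 <- which(alive & (indeg == 0L | outdeg == 0L))
      if (length(d0) > 0) {
        alive[d0] <- FALSE
        changed <- TRUE
      }
      if (!changed) break
    }
    list(alive = alive, chosen = chosen)
  }

  rec <- function(alive, chosen) {
    r <- reduce(alive, chosen)
    alive <- r$alive
    chosen <- r$chosen
    if (length(chosen) >= length(env$best)) return(invisible())
    cyc <- shortest_cycle_idx(adj, alive)
    if (is.null(cyc)) {
      env$best <- chosen
      return(invisible())
    }
    lb <- disjoint_cycle_bound(adj, alive)
    if (length(chosen) + lb >= length(env$best)) return(invisible())
    for (v in sort(cyc)) {
      alive2 <- alive
      alive2[v] <- FALSE
      rec(alive2, c(chosen, v))
    }
    invisible()
  }

  rec(alive, integer(0))
  sort(env$best)
}

# ---- public solvers ----------------------------------------------------

#' Brute-force minimum FVS (testing oracle)
#'
#' Enumerates candidate node subsets in increasing size (and, within a size,
#' lexicographic node order) and returns the first valid FVS, which is
#' therefore a true minimum. Self-looped nodes are included up front (they
#' belong to every FVS) and the search is restricted to nodes lying on at
#' least one cycle; neither restriction affects minimality.
#'
#' @param layer An [layer()] object.
#' @param max_n Refuse layers with more than this many nodes.
#' @return An `fvs_result` with `method = "oracle"`.
#' @export
brute_force_mfvs <- function(layer, max_n = 15) {
  stopifnot(inherits(layer, "fvs_layer"))
  if (n_nodes(layer) > max_n) {
    abort(sprintf("brute_force_mfvs: %d nodes exceeds max_n = %d.",
                  n_nodes(layer), max_n))
  }
  idx <- layer_index(layer)
  alive <- rep(TRUE, idx$n)
  forced <- which(map_lgl(seq_len(idx$n), function(i) i %in% idx$adj[[i]]))
  alive[forced] <- FALSE
  cand <- which(on_cycle_idx(idx$adj, alive))
  if (is_acyclic_idx(idx$adj, alive)) {
    return(new_fvs_result(layer, idx$nodes[forced], "oracle"))
  }
  for (k in seq_len(length(cand))) {
    combos <- combn(cand, k)
    for (j in seq_len(ncol(combos))) {
      al <- alive
      al[combos[, j]] <- FALSE
      if (is_acyclic_idx(idx$adj, al)) {
        return(new_fvs_result(layer, idx$nodes[c(forced, combos[, j])], "oracle"))
      }
    }
  }
  new_fvs_result(layer, idx$nodes, "oracle")  # unreachable: all nodes always work
}

#' Exact minimum FVS via simplification and branch-and-bound
#'
#' Simplifies the layer with [simplify()], decomposes the residual into
#' strongly connected components, and solves each component exactly by
#' branch-and-bound (branching over the vertices of a shortest cycle, pruning
#' with the incumbent and a vertex-disjoint-cycle lower bound). The result is
#' the union of the forced nodes and the per-component optima: a valid,
#' minimum-cardinality FVS.
#'
#' @param layer An [layer()] object.
#' @param node_budget Error if a residual strongly connected component exceeds
#'   this many nodes (exact search is exponential in the worst case).
#' @param method Method tag stored on the result.
#' @return An `fvs_result`.
#' @export
exact_mfvs <- function(layer, node_budget = 40, method = "SG") {
  stopifnot(inherits(layer, "fvs_layer"))
  tr <- simplify(layer)
  res <- tr$residual
  picked <- character(0)
  if (n_nodes(res) > 0) {
    idx <- layer_index(res)
    comp <- igraph::components(layer_igraph(res), mode = "strong")
    memb <- comp$membership[idx$nodes]
    for (cid in seq_len(comp$no)) {
      members <- which(memb == cid)
      if (length(members) < 2) next  # residual has no self-loops
      alive <- rep(FALSE, idx$n)
      alive[members] <- TRUE
      sol <- bb_mfvs_idx(idx$adj, alive, node_budget = node_budget)
      picked <- c(picked, idx$nodes[sol])
    }
  }
  new_fvs_result(layer, c(tr$forced_nodes, picked), method)
}

#' The SG algorithm: simplification + exact search
#'
#' Single-layer minimum-FVS solver composing [simplify()] with the exact
#' branch-and-bound of [exact_mfvs()]; this is the per-layer building block
#' of the multilayer ISG and IISG methods.
#'
#' @inheritParams exact_mfvs
#' @return An `fvs_result` with `method = "SG"`.
#' @examples
#' tri <- layer(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")))
#' sg_mfvs(tri)
#' @export
sg_mfvs <- function(layer, node_budget = 40) {
  exact_mfvs(layer, node_budget = node_budget, method = "SG")
}
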