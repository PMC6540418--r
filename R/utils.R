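# Internal helpers shared across modules.

# Deterministic node ordering: numeric when every id parses as a number
# (so "10" sorts after "2"), otherwise byte-wise (radix) string order,
# independent of locale.
node_order <- function(ids) {
  ids <- as.character(ids)
  num <- suppressWarnings(as.numeric(ids))
  if (length(ids) > 0 && !anyNA(num)) {
    order(num, method = "radix")
  } else {
    order(ids, method = "radix")
  }
}

node_sort <- function(ids) {
  as.character(ids)[node_order(ids)]
}

# Integer adjacency index over a fixed, sorted node vector.
# Returns list(nodes, n, adj) where adj[[i]] is the sorted integer vector of
# out-neighbours of node i (self-loops included as i itself).
graph_index <- function(nodes, from, to) {
  nodes <- node_sort(unique(as.character(nodes)))
  n <- length(nodes)
  fi <- match(as.character(from), nodes)
  ti <- match(as.character(to), nodes)
  if (anyNA(fi) || anyNA(ti)) {
    abort("graph_index: edge endpoint not in node set.")
  }
  adj <- vector("list", n)
  if (length(fi) > 0) {
    sp <- split(ti, factor(fi, levels = seq_len(n)))
    adj <- lapply(sp, function(v) sort(unique(v)))
  } else {
    adj <- replicate(n, integer(0), simplify = FALSE)
  }
  list(nodes = nodes, n = n, adj = adj)
}

# Kahn's algorithm restricted to `alive` vertices; TRUE iff the induced
# subgraph is acyclic. Self-loops make it cyclic. Plain integer code so the
# brute-force oracle and branch-and-bound avoid per-call igraph construction.
is_acyclic_idx <- function(adj, alive) {
  n <- length(adj)
  indeg <- integer(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    nb <- adj[[i]]
    nb <- nb[alive[nb]]
    if (any(nb == i)) return(FALSE)
    if (length(nb) > 0) indeg[nb] <- indeg[nb] + 1L
  }
  queue <- which(alive & indeg == 0L)
  removed <- 0L
  total <- sum(alive)
  while (length(queue) > 0) {
    v <- queue[[length(queue)]]
    queue <- queue[-length(queue)]
    removed <- removed + 1L
    nb <- adj[[v]]
    nb <- nb[alive[nb] & nb != v]
    for (w in nb) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
    alive[v] <- FALSE
  }
  removed == total
}

# Vertices that lie on at least one directed cycle of the induced subgraph:
# members of a non-trivial strongly connected component, or self-looped.
on_cycle_idx <- function(adj, alive) {
  n <- length(adj)
  idx <- which(alive)
  if (length(idx) == 0) return(logical(n))
  el_from <- integer(0)
  el_to <- integer(0)
  selfloop <- logical(n)
  for (i in idx) {
    nb <- adj[[i]]
    nb <- nb[alive[nb]]
    if (any(nb == i)) selfloop[i] <- TRUE
    nb <- nb[nb != i]
    if (length(nb) > 0) {
      el_from <- c(el_from, rep.int(i, length(nb)))
      el_to <- c(el_to, nb)
    }
  }
  out <- selfloop
  if (length(el_from) > 0) {
    g <- igraph::graph_from_edgelist(
      cbind(match(el_from, idx), match(el_to, idx)),
      directed = TRUE
    )
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g, mode = "strong")
    big <- which(tabulate(comp$membership, comp$no) > 1L)
    out[idx[comp$membership %in% big]] <- TRUE
  }
  out
}
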