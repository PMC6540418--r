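# Shared fixtures and independent oracles for the test suite.

tri_layer <- function(id = "tri") {
  layer(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")),
        layer_id = id)
}

two_cycle <- function(a = "a", b = "b", id = "two") {
  layer(data.frame(from = c(a, b), to = c(b, a)), layer_id = id)
}

dag_layer <- function(id = "dag") {
  layer(data.frame(from = c("a", "a", "b", "c"), to = c("b", "c", "d", "e")),
        nodes = letters[1:5], layer_id = id)
}

rand_layer <- function(n, p, seed, self_loop_prob = 0, id = as.character(seed)) {
  net <- random_multilayer(n, S = 1, edge_prob = p,
                           self_loop_prob = self_loop_prob, seed = seed)
  l <- net$layers[[1]]
  l$layer_id <- id
  l
}

# Independent simple-cycle oracle: tests every node subset and every cyclic
# ordering of it. Exponential, for tiny graphs only; shares no code with
# enumerate_cycles().
all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  }
  out
}

oracle_cycles <- function(layer) {
  nodes <- layer$nodes
  ekey <- paste(layer$edges$from, layer$edges$to)
  has <- function(a, b) paste(a, b) %in% ekey
  out <- list()
  for (v in nodes) if (has(v, v)) out[[length(out) + 1]] <- v
  n <- length(nodes)
  if (n >= 2) {
    for (k in 2:n) {
      for (sub in combn(nodes, k, simplify = FALSE)) {
        s <- sub[1]                      # combn output is sorted
        for (p in all_perms(sub[-1])) {
          sq <- c(s, p)
          if (all(mapply(has, sq, c(sq[-1], s)))) {
            out[[length(out) + 1]] <- sq
          }
        }
      }
    }
  }
  out
}

# Order-free fingerprint of a cycle list (node-set + length identity is not
# enough for directed cycles, so keep the canonical rotation sequence).
cycle_key <- function(cycles) {
  sort(vapply(cycles, function(cy) {
    i <- which.min(match(cy, sort(cy)))
    paste(c(cy[i:length(cy)], cy[seq_len(i - 1)]), collapse = ">")
  }, character(1)))
}
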