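# Multilayer driver-node identification: the ISG baseline (union of per-layer
# exact FVSs), the greedy IISG improvement, an exhaustive minimum-union
# oracle, and a method comparison report.

new_union_result <- function(net, drivers, method, trace = NULL) {
  drivers <- node_sort(unique(as.character(drivers)))
  valid <- map_lgl(net$layers, function(l) is_fvs(l, intersect(drivers, l$nodes)))
  structure(
    list(
      driver_nodes = drivers,
      method = method,
      per_layer_valid = valid,
      size = length(drivers),
      trace = trace
    ),
    class = "union_result"
  )
}

#' @export
print.union_result <- function(x, ...) {
  cat(sprintf("<union_result [%s]: %d driver node(s), valid on %d/%d layers>\n  {%s}\n",
              x$method, x$size, sum(x$per_layer_valid),
              length(x$per_layer_valid),
              paste(x$driver_nodes, collapse = ", ")))
  invisible(x)
}

#' ISG: union of independently solved per-layer FVSs
#'
#' Baseline for the minimum FVS-union problem: solve each layer exactly with
#' the SG algorithm and take the union. Always valid on every layer, but the
#' per-layer optima are chosen blindly to one another, so the union is
#' generally larger than necessary.
#'
#' @param net A [multilayer()] network.
#' @param node_budget Passed to [sg_mfvs()].
#' @return A `union_result` with `method = "ISG"`.
#' @export
isg <- function(net, node_budget = 40) {
  stopifnot(inherits(net, "multilayer_network"))
  per <- map(net$layers, sg_mfvs, node_budget = node_budget)
  new_union_result(net, unlist(map(per, "fvs")), "ISG")
}

#' Rank dominated-node candidates
#'
#' Orders candidate nodes by the three dominance criteria: membership in the
#' reference-layer FVS first, then the number of enumerated cycles passing
#' through the node, then the node's function weight, with node id as the
#' final deterministic tie-break. Only nodes appearing in at least one cycle
#' of `L` are eligible.
#'
#' @param candidates Character vector of candidate node ids.
#' @param L A `cycle_set` (the passing loops under consideration).
#' @param F_r Character vector: the reference FVS (accumulated union when
#'   folding more than two layers).
#' @param w Optional [function_weights()].
#' @return A tibble sorted best-first with columns `node`,
#'   `in_reference_fvs`, `loop_count`, `function_weight`. Zero rows when no
#'   candidate lies on a cycle (the caller then advances to the next phase).
#' @export
dominated_rank <- function(candidates, L, F_r, w = NULL) {
  stopifnot(inherits(L, "cycle_set"))
  counts <- loops_through(L, unique(as.character(candidates)))
  sc <- tibble(
    node = counts$node,
    in_reference_fvs = counts$node %in% as.character(F_r),
    loop_count = counts$n_cycles,
    function_weight = weight_of(w, counts$node)
  )
  sc <- filter(sc, .data$loop_count > 0)
  id_rank <- match(sc$node, node_sort(sc$node))
  sc[order(-sc$in_reference_fvs, -sc$loop_count, -sc$function_weight,
           id_rank), , drop = FALSE]
}

# Nodes of `pool` that lie on some directed cycle of `layer`.
nodes_on_cycles <- function(layer, pool = layer$nodes) {
  idx <- layer_index(layer)
  onc <- on_cycle_idx(idx$adj, rep(TRUE, idx$n))
  intersect(as.character(pool), idx$nodes[onc])
}

# Enumerate cycles with the truncation fallback: if the full enumeration hits
# the cap, warn once and re-enumerate with a length bound (relative counts
# are all the ranking needs).
cycles_with_fallback <- function(layer, cap, fallback_len, warned_env) {
  cs <- enumerate_cycles(layer, cap = cap)
  if (cs$truncated) {
    if (!isTRUE(warned_env$warned)) {
      warn(sprintf(
        "Cycle enumeration truncated at %d cycles; ranking falls back to cycles of length <= %d.",
        cap, fallback_len))
      warned_env$warned <- TRUE
    }
    cs <- enumerate_cycles(layer, cap = cap, max_len = fallback_len)
  }
  cs
}

# One greedy pass over a study layer, given the current reference set F_r.
# Returns list(F_i, trace): F_i makes the study layer acyclic.
iisg_study_pass <- function(study, F_r, w = NULL, cap = 100000,
                            fallback_len = 12, exact_residual = FALSE,
                            node_budget = 40) {
  F_i <- character(0)
  trace <- list()
  wenv <- new.env(parent = emptyenv())

  # Phase A (Steps 2-4): while some reference node still lies on a cycle of
  # the study layer minus F_i, rank the nodes of the loops passing through
  # those reference nodes and move the top dominated node into F_i.
  repeat {
    sub <- delete_layer_nodes(study, F_i)
    active_ref <- nodes_on_cycles(sub, setdiff(F_r, F_i))
    if (length(active_ref) == 0) break
    cs <- cycles_with_fallback(sub, cap, fallback_len, wenv)
    through_ref <- map_lgl(cs$cycles, function(cy) any(cy %in% active_ref))
    L_i <- new_cycle_set(cs$cycles[through_ref], cs$truncated, cs$cap,
                         study$layer_id)
    if (length(L_i$cycles) == 0) break
    ranked <- dominated_rank(unique(unlist(L_i$cycles)), L_i, F_r, w)
    if (nrow(ranked) == 0) break
    pick <- ranked[1, , drop = FALSE]
    F_i <- c(F_i, pick$node)
    trace[[length(trace) + 1]] <- mutate(pick, phase = "reference_loops")
  }

  # Phase B (Steps 5-7): clear the remaining cycles of the study layer.
  if (exact_residual) {
    sub <- delete_layer_nodes(study, F_i)
    res <- exact_mfvs(sub, node_budget = node_budget)
    if (res$size > 0) {
      F_i <- c(F_i, res$fvs)
      trace[[length(trace) + 1]] <- tibble(
        node = res$fvs, in_reference_fvs = res$fvs %in% F_r,
        loop_count = NA_integer_, function_weight = weight_of(w, res$fvs),
        phase = "exact_residual"
      )
    }
  } else {
    repeat {
      sub <- delete_layer_nodes(study, F_i)
      if (length(nodes_on_cycles(sub)) == 0) break
      L_ip <- cycles_with_fallback(sub, cap, fallback_len, wenv)
      ranked <- dominated_rank(unique(unlist(L_ip$cycles)), L_ip, F_r, w)
      pick <- ranked[1, , drop = FALSE]
      F_i <- c(F_i, pick$node)
      trace[[length(trace) + 1]] <- mutate(pick, phase = "residual_loops")
    }
  }

  list(F_i = F_i, trace = bind_rows(trace))
}

#' IISG on a duplex network
#'
#' The greedy improvement over ISG for two layers. Steps: (1) solve the
#' reference layer exactly (`F_r`); (2-4) while loops of the study layer pass
#' through unused reference nodes, move the top dominated node into the study
#' FVS `F_i` and recount; (5-7) greedily clear the remaining study-layer
#' cycles the same way; (8) return `F_r` union `F_i`. Reusing reference nodes
#' first is what shrinks the union relative to ISG.
#'
#' @param reference,study [layer()] objects on the same node universe.
#' @param w Optional [function_weights()] used in dominated-node ranking.
#' @param cap,fallback_len Cycle-enumeration cap and the length bound used if
#'   the cap is hit (see [enumerate_cycles()]).
#' @param exact_residual If `TRUE`, replace the greedy residual phase with an
#'   exact FVS of the remaining study graph (often a smaller union; off by
#'   default, which follows the plain greedy procedure).
#' @param node_budget Passed to the exact solver.
#' @return A `union_result` with `method = "IISG"`; its `trace` field logs
#'   each dominated-node selection with its score tuple.
#' @examples
#' fx <- fig8_fixture()
#' iisg_duplex(fx$reference, fx$study)
#' @export
iisg_duplex <- function(reference, study, w = NULL, cap = 100000,
                        fallback_len = 12, exact_residual = FALSE,
                        node_budget = 40) {
  stopifnot(inherits(reference, "fvs_layer"), inherits(study, "fvs_layer"))
  net <- multilayer(list(reference, study))
  iisg(net, reference = 1, w = w, cap = cap, fallback_len = fallback_len,
       exact_residual = exact_residual, node_budget = node_budget)
}

#' IISG on a multilayer network
#'
#' For more than two layers the accumulated driver set plays the reference
#' role: the reference layer is solved exactly, then each remaining layer is
#' processed in order with the running union acting as `F_r`, so reference
#' nodes are reused across every layer.
#'
#' @param net A [multilayer()] network.
#' @param reference Index (1-based) or layer id of the reference layer;
#'   defaults to the first layer.
#' @inheritParams iisg_duplex
#' @return A `union_result` with `method = "IISG"` (or the single layer's
#'   exact FVS when `net` has one layer).
#' @export
iisg <- function(net, reference = 1, w = NULL, cap = 100000,
                 fallback_len = 12, exact_residual = FALSE,
                 node_budget = 40) {
  stopifnot(inherits(net, "multilayer_network"))
  if (is.character(reference)) {
    reference <- match(reference, names(net$layers))
  }
  if (is.na(reference) || reference < 1 || reference > net$S) {
    abort("`reference` must name or index a layer of the network.")
  }
  ref_layer <- net$layers[[reference]]
  F_r <- sg_mfvs(ref_layer, node_budget = node_budget)$fvs
  if (net$S == 1) {
    return(new_union_result(net, F_r, "IISG"))
  }
  union_set <- F_r
  traces <- list()
  for (i in setdiff(seq_len(net$S), reference)) {
    pass <- iisg_study_pass(net$layers[[i]], union_set, w = w, cap = cap,
                            fallback_len = fallback_len,
                            exact_residual = exact_residual,
                            node_budget = node_budget)
    union_set <- union(union_set, pass$F_i)
    if (nrow(pass$trace) > 0) {
      traces[[length(traces) + 1]] <- mutate(
        pass$trace, layer_id = net$layers[[i]]$layer_id, .before = 1)
    }
  }
  new_union_result(net, union_set, "IISG", trace = bind_rows(traces))
}

#' Exhaustive minimum-union oracle
#'
#' Enumerates node subsets in increasing size (lexicographic within a size)
#' and returns the smallest set whose removal leaves every layer acyclic: the
#' true optimum of the minimum FVS-union problem. Exponential; intended for
#' validating the heuristics on small instances.
#'
#' @param net A [multilayer()] network.
#' @param max_n Refuse networks with more than this many nodes.
#' @return A `union_result` with `method = "oracle"`.
#' @export
min_union_oracle <- function(net, max_n = 14) {
  stopifnot(inherits(net, "multilayer_network"))
  if (net$N > max_n) {
    abort(sprintf("min_union_oracle: %d nodes exceeds max_n = %d.",
                  net$N, max_n))
  }
  idxs <- map(net$layers, layer_index)
  universe <- net$node_universe
  # nodes forced by a self-loop in any layer; candidates lie on some cycle
  forced <- unique(unlist(map(idxs, function(ix) {
    ix$nodes[map_lgl(seq_len(ix$n), function(i) i %in% ix$adj[[i]])]
  })))
  cand <- node_sort(setdiff(
    unique(unlist(map(net$layers, nodes_on_cycles))), forced))
  ok <- function(drop) {
    all(map_lgl(idxs, function(ix) {
      is_acyclic_idx(ix$adj, !(ix$nodes %in% drop))
    }))
  }
  if (ok(forced)) return(new_union_result(net, forced, "oracle"))
  for (k in seq_len(length(cand))) {
    combos <- combn(cand, k)
    for (j in seq_len(ncol(combos))) {
      drop <- c(forced, combos[, j])
      if (ok(drop)) return(new_union_result(net, drop, "oracle"))
    }
  }
  new_union_result(net, universe, "oracle")
}

#' Compare driver-node methods on one network
#'
#' Runs the per-layer exact solver (SG), the union baseline (ISG), the greedy
#' union (IISG) and, when the network is small enough, the exhaustive
#' minimum-union oracle, and tabulates sizes, memberships and validity.
#'
#' @param net A [multilayer()] network.
#' @param w Optional [function_weights()].
#' @param oracle_max_n Run [min_union_oracle()] only if `net$N` is at most
#'   this (exhaustive search).
#' @param ... Passed on to [iisg()].
#' @return A tibble of class `multifvs_comparison` with columns `method`,
#'   `scope` (layer id or "union"), `size`, `valid` and `drivers`
#'   (comma-separated).
#' @export
compare_methods <- function(net, w = NULL, oracle_max_n = 14, ...) {
  stopifnot(inherits(net, "multilayer_network"))
  rows <- list()
  for (l in net$layers) {
    r <- sg_mfvs(l)
    rows[[length(rows) + 1]] <- tibble(
      method = "SG", scope = l$layer_id, size = r$size, valid = r$is_valid,
      drivers = paste(r$fvs, collapse = ","))
  }
  for (res in list(isg(net), iisg(net, w = w, ...))) {
    rows[[length(rows) + 1]] <- tibble(
      method = res$method, scope = "union", size = res$size,
      valid = all(res$per_layer_valid),
      drivers = paste(res$driver_nodes, collapse = ","))
  }
  if (net$N <= oracle_max_n) {
    res <- min_union_oracle(net, max_n = oracle_max_n)
    rows[[length(rows) + 1]] <- tibble(
      method = "oracle", scope = "union", size = res$size,
      valid = all(res$per_layer_valid),
      drivers = paste(res$driver_nodes, collapse = ","))
  }
  out <- bind_rows(rows)
  class(out) <- c("multifvs_comparison", class(out))
  out
}
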