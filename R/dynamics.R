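# Nonlinear multilayer dynamics and FVS-based control validation. Each layer
# runs decay-plus-saturating-coupling dynamics on its own copy of the node
# states; driver nodes are clamped simultaneously in every layer.

#' Build a nonlinear dynamics model on a multilayer network
#'
#' Instantiates, for every layer `a`, the vector field
#' `dx_i/dt = -decay * x_i + sum_j w_ij * tanh(gain * x_j)` over that layer's
#' edges `j -> i`, with edge weights drawn reproducibly from `seed`: magnitude
#' uniform in `coupling`, sign positive with probability `p_positive`.
#' Positive feedback loops with `gain * w > decay` make the system
#' multistable, which is what makes attractor-switching control a meaningful
#' test. This decay-type saturating form is the class for which clamping a
#' feedback vertex set is known to steer the system between attractors.
#'
#' The external-input description of the control problem is retained: the
#' 0/1 node-selection control matrix for a driver set is available via
#' [control_matrix()], while validation clamps driver states directly.
#'
#' @param net A [multilayer()] network.
#' @param decay Positive linear decay rate (per unit time).
#' @param coupling Length-2 numeric: range of edge-weight magnitudes.
#' @param gain Sigmoid gain of the saturating coupling.
#' @param p_positive Probability that an edge weight is positive.
#' @param seed Integer seed; the same seed always yields the same weights.
#' @return An object of class `dynamics_model`: the network, parameters, the
#'   per-layer dense weight matrices `W` (entry `[i, j]` is the weight of edge
#'   `j -> i`), the flattened state layout (`N * S` coordinates, layer-major)
#'   and coordinate names `node@layer`.
#' @export
build_dynamics <- function(net, decay = 1, coupling = c(0.5, 1.5), gain = 2,
                           p_positive = 0.8, seed = 1) {
  stopifnot(inherits(net, "multilayer_network"))
  if (!is.numeric(decay) || decay <= 0) abort("`decay` must be positive.")
  stopifnot(length(coupling) == 2, all(coupling >= 0), gain > 0)
  nodes <- net$node_universe
  N <- net$N
  W <- withr::with_seed(seed, {
    map(net$layers, function(l) {
      m <- matrix(0, N, N, dimnames = list(nodes, nodes))
      ed <- l$edges
      if (nrow(ed) > 0) {
        mag <- runif(nrow(ed), coupling[1], coupling[2])
        sgn <- ifelse(runif(nrow(ed)) < p_positive, 1, -1)
        m[cbind(match(ed$to, nodes), match(ed$from, nodes))] <- mag * sgn
      }
      m
    })
  })
  coord_names <- unlist(map(names(net$layers), function(id) paste0(nodes, "@", id)))
  structure(
    list(net = net, decay = decay, gain = gain, W = W,
         coupling = coupling, p_positive = p_positive, seed = seed,
         N = N, S = net$S, coord_names = coord_names),
    class = "dynamics_model"
  )
}

#' @export
print.dynamics_model <- function(x, ...) {
  cat(sprintf("<dynamics_model: %d layer(s) x %d nodes, decay %.3g, gain %.3g, seed %d>\n",
              x$S, x$N, x$decay, x$gain, x$seed))
  invisible(x)
}

#' Control matrix for a driver set
#'
#' The block-diagonal 0/1 node-selection matrix mapping one external input
#' channel per (driver, layer) pair into the flattened `N * S` state: each
#' column has a single 1 at its driver's coordinate in its layer.
#'
#' @param model A `dynamics_model`.
#' @param drivers Character vector of driver node ids.
#' @return A `(N*S) x (length(drivers)*S)` matrix.
#' @export
control_matrix <- function(model, drivers) {
  stopifnot(inherits(model, "dynamics_model"))
  idx <- clamp_indices(model, drivers)
  B <- matrix(0, model$N * model$S, length(idx),
              dimnames = list(model$coord_names, NULL))
  if (length(idx) > 0) B[cbind(idx, seq_along(idx))] <- 1
  B
}

clamp_indices <- function(model, drivers) {
  drivers <- as.character(drivers)
  unknown <- setdiff(drivers, model$net$node_universe)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown driver node(s): %s", paste(unknown, collapse = ", ")))
  }
  pos <- match(drivers, model$net$node_universe)
  unlist(map(seq_len(model$S) - 1L, function(a) a * model$N + pos))
}

# Right-hand side of the free (u = 0) system on the flattened state.
model_field <- function(model, x) {
  out <- numeric(model$N * model$S)
  for (a in seq_len(model$S)) {
    sl <- ((a - 1) * model$N + 1):(a * model$N)
    xa <- x[sl]
    out[sl] <- -model$decay * xa + model$W[[a]] %*% tanh(model$gain * xa)
  }
  out
}

integrate_model <- function(model, init, t_max, clamp_idx = integer(0),
                            n_steps = 200, diverge = 1e6) {
  rhs <- function(t, x, parms) {
    dx <- model_field(model, x)
    dx[clamp_idx] <- 0
    list(dx)
  }
  times <- seq(0, t_max, length.out = n_steps + 1)
  sol <- deSolve::ode(y = init, times = times, func = rhs, parms = NULL)
  bad <- !is.finite(sol[, -1, drop = FALSE]) | abs(sol[, -1, drop = FALSE]) > diverge
  if (any(bad)) {
    last_ok <- max(1, which(rowSums(bad) > 0)[1] - 1)
    sol <- sol[seq_len(last_ok), , drop = FALSE]
    attr(sol, "diverged") <- TRUE
  }
  sol
}

#' Relax the free system to a fixed point
#'
#' Integrates the uncontrolled dynamics from `init` until the residual
#' `max(abs(F(x)))` drops below `tol` or `t_max` is reached.
#'
#' @param model A `dynamics_model`.
#' @param init Numeric state of length `N * S` (recycled if length 1).
#' @param t_max Maximum integration time.
#' @param tol Residual tolerance for declaring a fixed point.
#' @return An object of class `attractor`: `state` (named numeric),
#'   `residual_norm`, `converged`.
#' @export
find_attractor <- function(model, init, t_max = 200, tol = 1e-6) {
  stopifnot(inherits(model, "dynamics_model"), tol > 0)
  dim_full <- model$N * model$S
  init <- rep_len(as.numeric(init), dim_full)
  x <- init
  t_done <- 0
  chunk <- max(t_max / 10, 1e-6)
  diverged <- FALSE
  repeat {
    res <- max(abs(model_field(model, x)))
    if (res < tol || t_done >= t_max || diverged) break
    sol <- integrate_model(model, x, min(chunk, t_max - t_done))
    diverged <- isTRUE(attr(sol, "diverged"))
    x <- as.numeric(sol[nrow(sol), -1])
    t_done <- t_done + min(chunk, t_max - t_done)
  }
  res <- max(abs(model_field(model, x)))
  structure(
    list(state = setNames(x, model$coord_names), residual_norm = res,
         converged = !diverged && res < tol),
    class = "attractor"
  )
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("<attractor: converged = %s, residual = %.3g>\n",
              x$converged, x$residual_norm))
  invisible(x)
}

#' Probe distinct attractors from random initial states
#'
#' Convenience sampler: relaxes the free system from `n_starts` random states
#' and groups the converged fixed points by max-norm distance below
#' `ident_tol`.
#'
#' @param model A `dynamics_model`.
#' @param n_starts Number of random initial states.
#' @param seed Integer seed for the initial states.
#' @param scale Initial states are uniform in `[-scale, scale]`.
#' @param ident_tol Two fixed points closer than this (max-norm) are the same
#'   attractor.
#' @inheritParams find_attractor
#' @return List of distinct `attractor` objects, most frequently reached
#'   first; each carries a `basin_count` attribute.
#' @export
probe_attractors <- function(model, n_starts = 10, seed = 1, scale = 2,
                             t_max = 200, tol = 1e-6, ident_tol = 1e-3) {
  stopifnot(inherits(model, "dynamics_model"))
  dim_full <- model$N * model$S
  inits <- withr::with_seed(seed, {
    map(seq_len(n_starts), function(i) runif(dim_full, -scale, scale))
  })
  found <- list()
  counts <- integer(0)
  for (x0 in inits) {
    at <- find_attractor(model, x0, t_max = t_max, tol = tol)
    if (!at$converged) next
    hit <- 0
    for (k in seq_along(found)) {
      if (max(abs(found[[k]]$state - at$state)) < ident_tol) { hit <- k; break }
    }
    if (hit == 0) {
      found[[length(found) + 1]] <- at
      counts <- c(counts, 1L)
    } else {
      counts[hit] <- counts[hit] + 1L
    }
  }
  ord <- order(-counts)
  found <- found[ord]
  for (k in seq_along(found)) attr(found[[k]], "basin_count") <- counts[ord][k]
  found
}

#' Clamp driver nodes and simulate toward a target attractor
#'
#' Overrides the state of every driver node, in every layer, to its value in
#' the target attractor (hard clamping, the control primitive of FVS-based
#' attractor steering), integrates the remaining coordinates from `init`, and
#' reports success iff the final state is within `tol` of the target on all
#' coordinates.
#'
#' @param model A `dynamics_model`.
#' @param drivers Character vector of driver node ids (clamped in all layers).
#' @param target An `attractor` with `converged = TRUE`.
#' @param init Numeric initial state (length `N * S`, recycled if length 1).
#' @param t_max Integration horizon.
#' @param tol Max-norm tolerance for success.
#' @param n_steps Number of saved trajectory points.
#' @return An object of class `control_sim`: `success`, `final_state`,
#'   `trajectory` (tibble: `time`, then one column per coordinate), `drivers`.
#' @export
clamp_and_simulate <- function(model, drivers, target, init, t_max = 200,
                               tol = 1e-3, n_steps = 200) {
  stopifnot(inherits(model, "dynamics_model"), inherits(target, "attractor"))
  if (!isTRUE(target$converged)) abort("`target` must be a converged attractor.")
  dim_full <- model$N * model$S
  init <- rep_len(as.numeric(init), dim_full)
  idx <- clamp_indices(model, drivers)
  x0 <- init
  x0[idx] <- target$state[idx]
  sol <- integrate_model(model, setNames(x0, model$coord_names), t_max,
                         clamp_idx = idx, n_steps = n_steps)
  final <- as.numeric(sol[nrow(sol), -1])
  success <- !isTRUE(attr(sol, "diverged")) &&
    max(abs(final - target$state)) < tol
  traj <- as_tibble(as.data.frame(sol))
  structure(
    list(success = success,
         final_state = setNames(final, model$coord_names),
         trajectory = traj, drivers = node_sort(as.character(drivers)),
         target = target, tol = tol),
    class = "control_sim"
  )
}

#' @export
print.control_sim <- function(x, ...) {
  cat(sprintf("<control_sim: %d driver(s) clamped, success = %s>\n",
              length(x$drivers), x$success))
  invisible(x)
}

#' Success rate of clamping a driver set
#'
#' Repeats [clamp_and_simulate()] from random initial states and tabulates
#' the fraction that reach the target attractor.
#'
#' @param model A `dynamics_model`.
#' @param drivers Driver node ids.
#' @param target A converged `attractor`.
#' @param n_inits Number of random initial states.
#' @param seed Seed for the initial states.
#' @param scale Initial states uniform in `[-scale, scale]`.
#' @inheritParams clamp_and_simulate
#' @return A tibble: `n_trials`, `n_success`, `success_rate`.
#' @export
control_success_rate <- function(model, drivers, target, n_inits = 20,
                                 seed = 1, scale = 2, t_max = 200,
                                 tol = 1e-3) {
  dim_full <- model$N * model$S
  inits <- withr::with_seed(seed, {
    map(seq_len(n_inits), function(i) runif(dim_full, -scale, scale))
  })
  succ <- map_lgl(inits, function(x0) {
    clamp_and_simulate(model, drivers, target, x0, t_max = t_max,
                       tol = tol, n_steps = 50)$success
  })
  tibble(n_trials = length(succ), n_success = sum(succ),
         success_rate = mean(succ))
}
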