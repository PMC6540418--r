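# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy an FVS result
#'
#' @param x An `fvs_result`.
#' @param ... Unused.
#' @return One row per FVS member: `layer_id`, `method`, `node`.
#' @export
tidy.fvs_result <- function(x, ...) {
  tibble(layer_id = x$layer_id, method = x$method,
         node = if (x$size > 0) x$fvs else character(0))
}

#' @rdname tidy.fvs_result
#' @return `glance()`: one row with `layer_id`, `method`, `size`, `is_valid`.
#' @export
glance.fvs_result <- function(x, ...) {
  tibble(layer_id = x$layer_id, method = x$method, size = x$size,
         is_valid = x$is_valid)
}

#' Tidy a driver-node union result
#'
#' @param x A `union_result`.
#' @param ... Unused.
#' @return One row per driver node: `method`, `node`.
#' @export
tidy.union_result <- function(x, ...) {
  tibble(method = x$method,
         node = if (x$size > 0) x$driver_nodes else character(0))
}

#' @rdname tidy.union_result
#' @return `glance()`: one row with `method`, `size`, `valid_all_layers`,
#'   `n_layers`.
#' @export
glance.union_result <- function(x, ...) {
  tibble(method = x$method, size = x$size,
         valid_all_layers = all(x$per_layer_valid),
         n_layers = length(x$per_layer_valid))
}

#' Plot a method comparison
#'
#' Bar chart of driver-set sizes per method/scope from [compare_methods()].
#'
#' @param object A `multifvs_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multifvs_comparison <- function(object, ...) {
  object <- mutate(object,
                   label = ifelse(.data$scope == "union", .data$method,
                                  paste0(.data$method, " (", .data$scope, ")")))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$label, .data$size),
                               y = .data$size, fill = .data$scope)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$size), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "driver-set size",
                  title = "Driver-node set sizes by method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a control simulation trajectory
#'
#' One line per state coordinate; clamped driver coordinates are flat by
#' construction.
#'
#' @param object A `control_sim` from [clamp_and_simulate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.control_sim <- function(object, ...) {
  traj <- object$trajectory
  long <- tidyr::pivot_longer(traj, -"time", names_to = "coordinate",
                              values_to = "state")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$state,
                                     group = .data$coordinate)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(title = sprintf("Clamped simulation (%d drivers): %s",
                                  length(object$drivers),
                                  if (object$success) "converged to target"
                                  else "did not reach target"),
                  x = "time", y = "node state") +
    ggplot2::theme_minimal()
}
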