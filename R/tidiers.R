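#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an attractor analysis into one row per attractor state
#'
#' Steady states contribute one row; limit cycles one row per cycle
#' position. Rows are ordered like the analysis summary (descending basin
#' size, ties by smallest state index). Each node appears twice: as a label
#' column (`<node>`) and as an integer column (`<node>_state`). Basin
#' percentages are kept at full precision here; file export rounds them to
#' one decimal.
#'
#' @param x a [find_attractors()] result.
#' @param ... unused.
#' @return A tibble with `attractor`, `cycle_position`, `cycle_length`,
#'   `index`, per-node columns, `basin_size`, and `basin_pct`.
#' @method tidy logic_analysis
#' @export
tidy.logic_analysis <- function(x, ...) {
  compiled <- x$compiled
  radices <- compiled$radices
  rows <- purrr::map2_dfr(x$summary$attractor, x$cycles, function(id, cy) {
    states <- index_to_state(cy - 1, radices)
    tb <- tibble::tibble(
      attractor = id,
      cycle_position = seq_along(cy),
      cycle_length = length(cy),
      index = cy - 1
    )
    for (i in seq_along(compiled$node_names)) {
      nm <- compiled$node_names[i]
      tb[[nm]] <- compiled$labels[[i]][states[, i] + 1L]
      tb[[paste0(nm, "_state")]] <- states[, i]
    }
    tb$basin_size <- x$summary$basin_size[id]
    tb$basin_pct <- x$summary$basin_pct[id]
    tb
  })
  rows
}

#' One-row summary of an attractor analysis
#'
#' @param x a [find_attractors()] result.
#' @param ... unused.
#' @return A tibble with `model`, `total_states`, `n_attractors`,
#'   `n_steady_states`, `n_limit_cycles`, and `largest_basin_pct`.
#' @method glance logic_analysis
#' @export
glance.logic_analysis <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    total_states = x$total_states,
    n_attractors = nrow(x$summary),
    n_steady_states = sum(x$summary$cycle_length == 1),
    n_limit_cycles = sum(x$summary$cycle_length > 1),
    largest_basin_pct = max(x$summary$basin_pct)
  )
}

#' Plot basin sizes of an attractor analysis
#'
#' A bar chart of basin percentages, one bar per attractor, steady states
#' and limit cycles distinguished by fill.
#'
#' @param object a [find_attractors()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot logic_analysis
#' @export
autoplot.logic_analysis <- function(object, ...) {
  s <- object$summary
  s$type <- ifelse(s$cycle_length == 1, "steady state", "limit cycle")
  ggplot2::ggplot(s, ggplot2::aes(
    x = factor(.data$attractor), y = .data$basin_pct, fill = .data$type
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "attractor", y = "basin of attraction (% of state space)",
      fill = NULL, title = object$model
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a state-space graph
#'
#' Lays out the functional graph (each state and its successor) with a
#' deterministic Kamada-Kawai embedding and draws states as points colored
#' by basin, with attractor states emphasized.
#'
#' @param graph an edge list from [state_space_graph()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_state_space <- function(graph, ...) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$from), to = as.character(graph$to)),
    directed = TRUE,
    vertices = data.frame(name = as.character(graph$from))
  )
  xy <- igraph::layout_with_kk(g)
  pos <- tibble::tibble(
    state = as.character(graph$from),
    x = xy[, 1], y = xy[, 2],
    basin = factor(graph$attractor),
    on_cycle = graph$on_cycle,
    label = graph$from_label
  )
  seg <- tibble::tibble(
    x = pos$x, y = pos$y,
    xend = pos$x[match(as.character(graph$to), pos$state)],
    yend = pos$y[match(as.character(graph$to), pos$state)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      color = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$basin,
        size = .data$on_cycle)
    ) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4), guide = "none") +
    ggplot2::labs(color = "basin") +
    ggplot2::theme_void()
}
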