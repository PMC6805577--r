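#' Mixed-radix state indexing
#'
#' A global state assigns one state integer to every node in canonical
#' (declaration) order. States are enumerated by a mixed-radix integer
#' index: the first node is the most significant digit, so lexicographic
#' order of state tuples equals numeric order of indices.
#' `index = sum_i states[i] * prod(radices[(i+1):n])`.
#'
#' @param states integer vector of per-node states (or a matrix with one
#'   row per state tuple).
#' @param radices integer vector of per-node state counts.
#' @param index 0-based integer index (vectorized).
#' @return `state_to_index()`: 0-based index (numeric, exact for state
#'   spaces below 2^53). `index_to_state()`: an integer matrix with one row
#'   per index and one column per node.
#' @examples
#' state_to_index(c(0, 1, 0), c(2, 2, 3)) # 3
#' index_to_state(11, c(2, 2, 3))         # 1 1 2
#' @export
state_to_index <- function(states, radices) {
  if (!is.matrix(states)) states <- matrix(states, nrow = 1)
  if (ncol(states) != length(radices)) {
    stop("state tuple has ", ncol(states), " components; expected ",
      length(radices), call. = FALSE)
  }
  if (any(states < 0) || any(sweep(states, 2, radices, `>=`))) {
    stop("state component out of range for its radix", call. = FALSE)
  }
  w <- radix_weights(radices)
  drop(states %*% w)
}

#' @rdname state_to_index
#' @export
index_to_state <- function(index, radices) {
  n_total <- prod(radices)
  if (any(index < 0) || any(index >= n_total)) {
    stop("index out of range 0..", n_total - 1, call. = FALSE)
  }
  w <- radix_weights(radices)
  out <- matrix(0L, nrow = length(index), ncol = length(radices))
  for (i in seq_along(radices)) {
    out[, i] <- as.integer((index %/% w[i]) %% radices[i])
  }
  colnames(out) <- names(radices)
  out
}

radix_weights <- function(radices) {
  n <- length(radices)
  rev(cumprod(rev(c(radices[-1], 1))))
}

#' Synchronous successor of a global state
#'
#' All nodes update simultaneously: each node's next state is read from its
#' transition table at the current global state. The map is total and
#' deterministic.
#'
#' @param compiled a [compile_model()] result (possibly perturbed by
#'   [apply_experiment()]).
#' @param states integer vector of per-node states in canonical order, or a
#'   matrix with one row per state.
#' @return Next state(s), same shape as the input.
#' @export
successor <- function(compiled, states) {
  stopifnot(inherits(compiled, "compiled_logic_model"))
  vec <- !is.matrix(states)
  if (vec) states <- matrix(as.integer(states), nrow = 1)
  nxt <- states
  for (k in seq_along(compiled$updates)) {
    u <- compiled$updates[[k]]
    if (length(u$inputs) == 0) {
      nxt[, k] <- u$table[1L]
    } else {
      key <- state_to_index(states[, u$inputs, drop = FALSE], u$radices_in)
      nxt[, k] <- u$table[key + 1L]
    }
  }
  if (vec) drop(nxt) else nxt
}

# Successor array over the whole state space: entry i is the 1-based index
# of the successor of the state with 0-based index i-1. Chunked so the digit
# matrix never exceeds ~1e6 rows.
successor_array <- function(compiled, chunk = 1e6) {
  n <- compiled$total_states
  radices <- compiled$radices
  w <- radix_weights(radices)
  succ <- numeric(n)
  lo <- 0
  while (lo < n) {
    hi <- min(lo + chunk, n)
    idx <- seq.int(lo, hi - 1)
    digits <- index_to_state(idx, radices)
    out <- numeric(hi - lo)
    for (k in seq_along(compiled$updates)) {
      u <- compiled$updates[[k]]
      if (length(u$inputs) == 0) {
        nk <- rep.int(u$table[1L], hi - lo)
      } else {
        key <- digits[, u$inputs, drop = FALSE] %*% radix_weights(u$radices_in)
        nk <- u$table[drop(key) + 1L]
      }
      out <- out + nk * w[k]
    }
    succ[(lo + 1):hi] <- out + 1
    lo <- hi
  }
  succ
}

#' Find all attractors of the synchronous dynamics
#'
#' Exhaustively enumerates the state space: from every not-yet-classified
#' state the successor map is iterated until a state repeats, which closes
#' either a new cycle (a steady state when its length is 1) or a path into
#' an already-classified basin; the whole walked path is then assigned to
#' that attractor. Successors are memoized in a precomputed array so each
#' state's update is evaluated exactly once.
#'
#' @param compiled a [compile_model()] result (possibly perturbed).
#' @param analysis_cap refuse state spaces larger than this (default 1e7);
#'   raise it explicitly for bigger models.
#' @return A `logic_analysis` with a `summary` tibble (one row per
#'   attractor: `attractor`, `cycle_length`, `basin_size`, `basin_pct`),
#'   the cycles themselves, and the full state-to-attractor assignment.
#'   Attractors are numbered by descending basin size, ties broken by the
#'   smallest state index on the cycle.
#' @export
find_attractors <- function(compiled, analysis_cap = 1e7) {
  stopifnot(inherits(compiled, "compiled_logic_model"))
  n <- compiled$total_states
  if (n > analysis_cap) {
    stop("state space has ", format(n, big.mark = ","), " states, above the ",
      "analysis cap of ", format(analysis_cap, big.mark = ","),
      "; pass a larger analysis_cap to proceed", call. = FALSE)
  }
  succ <- successor_array(compiled)
  basin_of <- integer(n) # 0 = unassigned, -1 = on the current walk
  cycles <- list()
  path <- integer(n)
  for (s in seq_len(n)) {
    if (basin_of[s] != 0L) next
    len <- 0L
    cur <- s
    while (basin_of[cur] == 0L) {
      basin_of[cur] <- -1L
      len <- len + 1L
      path[len] <- cur
      cur <- succ[cur]
    }
    if (basin_of[cur] == -1L) {
      pos <- match(cur, path[seq_len(len)])
      cycles[[length(cycles) + 1L]] <- path[pos:len]
      id <- length(cycles)
    } else {
      id <- basin_of[cur]
    }
    basin_of[path[seq_len(len)]] <- id
  }
  basin_size <- tabulate(basin_of, nbins = length(cycles))
  # canonical rotation: each cycle starts at its smallest state index
  cycles <- lapply(cycles, function(cy) {
    i <- which.min(cy)
    if (i > 1) cy <- c(cy[i:length(cy)], cy[seq_len(i - 1)])
    cy
  })
  ord <- order(-basin_size, purrr::map_dbl(cycles, 1))
  cycles <- cycles[ord]
  basin_size <- basin_size[ord]
  basin_of <- match(basin_of, ord)
  structure(
    list(
      model = compiled$name,
      compiled = compiled,
      total_states = n,
      summary = tibble::tibble(
        attractor = seq_along(cycles),
        cycle_length = lengths(cycles),
        basin_size = basin_size,
        basin_pct = 100 * basin_size / n
      ),
      cycles = cycles,
      basin_of = basin_of
    ),
    class = "logic_analysis"
  )
}

#' Simulate a trajectory from an initial state
#'
#' Iterates the synchronous successor from `init` until a state repeats
#' (the trajectory has entered its attractor) or `max_steps` updates have
#' been taken. With `max_steps >= total_states` the repeat is guaranteed.
#'
#' @param compiled a [compile_model()] result.
#' @param init initial state: integer vector in canonical node order, or a
#'   character vector of state labels.
#' @param max_steps maximum number of updates (default 1000).
#' @return A `logic_trajectory`: tibble with `step`, `index`, and one
#'   integer column per node; attributes `transient_length`,
#'   `cycle_length` (NA if incomplete), and `complete`.
#' @export
simulate_model <- function(compiled, init, max_steps = 1000) {
  stopifnot(inherits(compiled, "compiled_logic_model"))
  init <- resolve_state(compiled, init)
  radices <- compiled$radices
  states <- matrix(init, nrow = 1)
  idx <- state_to_index(init, radices)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(format(idx, scientific = FALSE), 1L, envir = seen)
  repeat_at <- NA_integer_
  for (step in seq_len(max_steps)) {
    cur <- successor(compiled, states[nrow(states), ])
    i <- state_to_index(cur, radices)
    key <- format(i, scientific = FALSE)
    states <- rbind(states, cur)
    idx <- c(idx, i)
    if (!is.null(seen[[key]])) {
      repeat_at <- seen[[key]]
      break
    }
    assign(key, nrow(states), envir = seen)
  }
  complete <- !is.na(repeat_at)
  n_kept <- if (complete) nrow(states) - 1L else nrow(states)
  tb <- tibble::as_tibble(states[seq_len(n_kept), , drop = FALSE],
    .name_repair = ~ make.unique(compiled$node_names))
  tb <- dplyr::bind_cols(
    tibble::tibble(step = seq_len(n_kept) - 1L, index = idx[seq_len(n_kept)]), tb
  )
  structure(tb,
    class = c("logic_trajectory", class(tb)),
    transient_length = if (complete) repeat_at - 1L else NA_integer_,
    cycle_length = if (complete) n_kept - repeat_at + 1L else NA_integer_,
    complete = complete
  )
}

resolve_state <- function(compiled, init) {
  n <- length(compiled$radices)
  if (length(init) != n) {
    stop("initial state needs ", n, " components (one per node)", call. = FALSE)
  }
  if (is.character(init) && any(is.na(suppressWarnings(as.numeric(init))))) {
    init <- purrr::map_int(seq_len(n), function(i) {
      m <- match(init[i], compiled$labels[[i]])
      if (is.na(m)) {
        stop("'", init[i], "' is not a state label of node '",
          compiled$node_names[i], "'", call. = FALSE)
      }
      m - 1L
    })
  }
  init <- as.integer(init)
  if (any(init < 0) || any(init >= compiled$radices)) {
    stop("initial state out of range for node(s) ",
      paste(compiled$node_names[init < 0 | init >= compiled$radices],
        collapse = ", "), call. = FALSE)
  }
  init
}

#' Extract the state-space graph (each state and its successor)
#'
#' The synchronous dynamics form a functional graph: every state has
#' exactly one outgoing edge. The full graph, or the basin of one
#' attractor, is returned as a tidy edge list ready for [write_state_graph()]
#' or plotting.
#'
#' @param analysis a [find_attractors()] result.
#' @param basin optional attractor number; restrict the graph to that
#'   attractor's basin.
#' @param graph_cap refuse graphs larger than this many states
#'   (default 2600); raise explicitly for bigger drawings.
#' @return A tibble with one row per state: `from`, `to` (0-based state
#'   indices), `from_label`, `to_label` (comma-separated state labels),
#'   `attractor` (the basin's attractor number), and `on_cycle`.
#' @export
state_space_graph <- function(analysis, basin = NULL, graph_cap = 2600) {
  stopifnot(inherits(analysis, "logic_analysis"))
  compiled <- analysis$compiled
  keep <- if (is.null(basin)) {
    seq_len(analysis$total_states)
  } else {
    if (!basin %in% analysis$summary$attractor) {
      stop("no attractor numbered ", basin, call. = FALSE)
    }
    which(analysis$basin_of == basin)
  }
  if (length(keep) > graph_cap) {
    stop("selected state space has ", format(length(keep), big.mark = ","),
      " states, above the graph cap of ", format(graph_cap, big.mark = ","),
      "; pass a larger graph_cap to draw it anyway", call. = FALSE)
  }
  radices <- compiled$radices
  states <- index_to_state(keep - 1, radices)
  nxt <- successor(compiled, states)
  to <- state_to_index(nxt, radices)
  on_cycle <- keep %in% unlist(analysis$cycles)
  tibble::tibble(
    from = keep - 1,
    to = to,
    from_label = state_labels(compiled, states),
    to_label = state_labels(compiled, nxt),
    attractor = analysis$basin_of[keep],
    on_cycle = on_cycle
  )
}

state_labels <- function(compiled, states) {
  if (!is.matrix(states)) states <- matrix(states, nrow = 1)
  cols <- lapply(seq_len(ncol(states)), function(i) {
    compiled$labels[[i]][states[, i] + 1L]
  })
  do.call(paste, c(cols, sep = ","))
}

#' @export
print.logic_analysis <- function(x, digits = 1, ...) {
  cat("<logic_analysis> of '", x$model, "': ",
    format(x$total_states, big.mark = ","), " states, ",
    nrow(x$summary), " attractor(s) (",
    sum(x$summary$cycle_length == 1), " steady, ",
    sum(x$summary$cycle_length > 1), " cyclic)\n", sep = "")
  pins <- x$compiled$pins
  if (length(pins) > 0) {
    cat("  perturbed model: ", paste0(names(pins), "=", pins, collapse = ", "),
      " held constant in the update rules, so the attractor set is complete\n",
      sep = "")
  }
  s <- x$summary
  s$basin_pct <- round(s$basin_pct, digits)
  print(s, ...)
  invisible(x)
}
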