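#' Create an empty multi-state logical network model
#'
#' A model is a wiring diagram: a set of nodes, each with a small number of
#' ordinal states (internally `0 .. n-1`, each with a human-readable label),
#' and signed directed edges. Every node carries a total transition table
#' (its "big state transition table", BSTT) mapping each combination of its
#' regulators' states plus its own state to its next state. By default the
#' table is filled by the additive rule
#' `next = clamp(self + sum(activator states) - sum(inhibitor states))`;
#' individual rows can be overridden with [set_rule()].
#'
#' @param name model name (free-form string).
#' @param metadata optional named list of free-form annotations.
#' @return A `logic_model` object. Grow it with [add_node()] and [add_edge()].
#' @seealso [add_node()], [add_edge()], [set_rule()], [compile_model()],
#'   [find_attractors()]
#' @examples
#' m <- logic_model("toy") |>
#'   add_node("A", states = 2) |>
#'   add_node("B", states = 2) |>
#'   add_node("C", states = 3) |>
#'   add_edge("A", "C", "activate") |>
#'   add_edge("B", "C", "inhibit")
#' m
#' @export
logic_model <- function(name = "model", metadata = list()) {
  structure(
    list(
      name = as.character(name)[1],
      nodes = tibble::tibble(
        name = character(), state_count = integer(),
        labels = list(), x = double(), y = double()
      ),
      edges = tibble::tibble(
        from = character(), to = character(),
        sign = character(), contribution = list()
      ),
      overrides = list(),
      metadata = metadata
    ),
    class = "logic_model"
  )
}

#' Add a node to a model
#'
#' @param model a [logic_model()].
#' @param name unique node name.
#' @param states either an integer number of ordinal levels (2-5 by default
#'   validation) or a character vector of state labels; label `i+1`
#'   corresponds to internal state `i`.
#' @param labels optional character vector of state labels when `states` is
#'   a count; defaults to `"0" .. "n-1"`.
#' @param position optional numeric `c(x, y)` diagram coordinates
#'   (metadata only; never used by the dynamics).
#' @return The model with the node appended. Node declaration order is
#'   canonical: it fixes the order of state tuples and the mixed-radix
#'   state indexing.
#' @export
add_node <- function(model, name, states = 2, labels = NULL, position = NULL) {
  stopifnot(inherits(model, "logic_model"))
  if (is.character(states)) {
    labels <- states
    states <- length(states)
  }
  states <- as.integer(states)
  if (is.null(labels)) labels <- as.character(seq_len(states) - 1L)
  pos <- if (is.null(position)) c(NA_real_, NA_real_) else as.numeric(position)
  model$nodes <- dplyr::bind_rows(
    model$nodes,
    tibble::tibble(
      name = as.character(name), state_count = states,
      labels = list(as.character(labels)), x = pos[1], y = pos[2]
    )
  )
  model
}

#' Add a signed edge to a model
#'
#' An `activate` edge contributes `+s` to the target's additive update when
#' its source is in state `s`; an `inhibit` edge contributes `-s`. A `custom`
#' edge carries an explicit contribution table: a signed integer delta for
#' every source state.
#'
#' @param model a [logic_model()].
#' @param from,to source and target node names (must exist; at most one edge
#'   per ordered pair; self-edges allowed).
#' @param sign `"activate"`, `"inhibit"`, or `"custom"`.
#' @param contribution for `sign = "custom"`: integer vector of length equal
#'   to the source's state count; entry `s+1` is the delta contributed when
#'   the source is in state `s`.
#' @return The model with the edge appended.
#' @export
add_edge <- function(model, from, to,
                     sign = c("activate", "inhibit", "custom"),
                     contribution = NULL) {
  stopifnot(inherits(model, "logic_model"))
  sign <- match.arg(sign)
  contribution <- if (is.null(contribution)) list(NULL) else list(as.integer(contribution))
  model$edges <- dplyr::bind_rows(
    model$edges,
    tibble::tibble(
      from = as.character(from), to = as.character(to),
      sign = sign, contribution = contribution
    )
  )
  model
}

#' Override one row of a node's transition table
#'
#' The default additive table stays in place for every other row; an
#' override replaces exactly one row and can be removed again with
#' [clear_rule()], restoring the additive default.
#'
#' @param model a [logic_model()].
#' @param node target node name.
#' @param when the input-state tuple of the row, as integers in the node's
#'   BSTT input order (edge sources in declaration order, then the node
#'   itself last).
#' @param then the overridden next state for `node` (integer, or one of the
#'   node's state labels).
#' @return The model with the override recorded.
#' @export
set_rule <- function(model, node, when, then) {
  stopifnot(inherits(model, "logic_model"))
  node <- as.character(node)
  if (is.character(then)) {
    i <- match(node, model$nodes$name)
    if (is.na(i)) stop("set_rule: unknown node '", node, "'", call. = FALSE)
    then <- match(as.character(then), model$nodes$labels[[i]]) - 1L
  }
  ov <- model$overrides[[node]] %||%
    tibble::tibble(when = list(), then = integer())
  when <- as.integer(when)
  keep <- !purrr::map_lgl(ov$when, identical, when)
  model$overrides[[node]] <- dplyr::bind_rows(
    ov[keep, ],
    tibble::tibble(when = list(when), then = as.integer(then))
  )
  model
}

#' @rdname set_rule
#' @export
clear_rule <- function(model, node, when) {
  stopifnot(inherits(model, "logic_model"))
  node <- as.character(node)
  ov <- model$overrides[[node]]
  if (is.null(ov)) return(model)
  when <- as.integer(when)
  keep <- !purrr::map_lgl(ov$when, identical, when)
  model$overrides[[node]] <- ov[keep, ]
  if (nrow(model$overrides[[node]]) == 0) model$overrides[[node]] <- NULL
  model
}

#' Clamp an additive update into a node's state range
#'
#' The additive update is integer arithmetic constrained to the target's
#' state range: any total below 0 maps to 0 and any total above the highest
#' state maps to the highest state.
#'
#' @param value integer (vectorized) unclamped total.
#' @param max_state the node's highest state, `state_count - 1`.
#' @return `pmin(pmax(value, 0), max_state)`, as integer.
#' @examples
#' clamp_state(-1, 2) # 0
#' clamp_state(3, 2)  # 2
#' @export
clamp_state <- function(value, max_state) {
  stopifnot(max_state >= 1)
  as.integer(pmin(pmax(value, 0L), max_state))
}

#' Signed contribution of one edge for a given source state
#'
#' @param edge a list (or one row of a model's `edges` tibble coerced to a
#'   list) with elements `sign` and, for custom edges, `contribution`.
#' @param source_state integer source state(s), `0 .. state_count-1`.
#' @return Signed integer delta(s): `+s` for activate, `-s` for inhibit, the
#'   table entry for custom.
#' @export
edge_contribution <- function(edge, source_state) {
  s <- as.integer(source_state)
  contribution <- edge$contribution
  if (is.list(contribution)) contribution <- contribution[[1]]
  switch(edge$sign,
    activate = s,
    inhibit = -s,
    custom = {
      if (is.null(contribution) || any(s + 1L > length(contribution))) {
        stop("custom edge ", edge$from %||% "?", " -> ", edge$to %||% "?",
          " is missing a contribution entry for source state ",
          paste(s[s + 1L > length(contribution)], collapse = ", "),
          call. = FALSE
        )
      }
      as.integer(contribution[s + 1L])
    },
    stop("unknown edge sign '", edge$sign, "'", call. = FALSE)
  )
}

#' Validate a model against its structural invariants
#'
#' Checks are reported, never raised: the result is a tibble with one row
#' per violation (`element`, `kind`, `message`); zero rows means the model
#' is valid. Checked invariants: unique node names; state counts within
#' `2 .. max_states`; label lists matching the state count and unique within
#' a node; edges referencing existing nodes; at most one edge per ordered
#' node pair; custom edges carrying a complete contribution table; overrides
#' referencing existing nodes, well-formed input tuples, and in-range
#' outputs.
#'
#' @param model a [logic_model()].
#' @param max_states upper cap on per-node state counts (default 5).
#' @return A tibble of violations; `nrow(.) == 0` iff the model is valid.
#' @export
validate_model <- function(model, max_states = 5) {
  stopifnot(inherits(model, "logic_model"))
  bad <- list()
  flag <- function(element, kind, message) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(
      element = element, kind = kind, message = message
    )
  }
  nodes <- model$nodes
  dup <- unique(nodes$name[duplicated(nodes$name)])
  for (d in dup) flag(d, "duplicate_node", paste0("node name '", d, "' is used more than once"))
  for (i in seq_len(nrow(nodes))) {
    nm <- nodes$name[i]
    sc <- nodes$state_count[i]
    if (is.na(sc) || sc < 2 || sc > max_states) {
      flag(nm, "state_count", paste0(
        "node '", nm, "' has ", sc, " states; allowed range is 2..", max_states
      ))
    }
    labs <- nodes$labels[[i]]
    if (length(labs) != sc) {
      flag(nm, "labels", paste0(
        "node '", nm, "' declares ", sc, " states but ", length(labs), " labels"
      ))
    }
    if (anyDuplicated(labs)) {
      flag(nm, "labels", paste0("node '", nm, "' has duplicated state labels"))
    }
  }
  edges <- model$edges
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    id <- paste0(e$from, " -> ", e$to)
    for (endpoint in c(e$from, e$to)) {
      if (!endpoint %in% nodes$name) {
        flag(id, "unknown_node", paste0("edge ", id, " references unknown node '", endpoint, "'"))
      }
    }
    if (e$sign == "custom") {
      sc <- nodes$state_count[match(e$from, nodes$name)]
      tab <- e$contribution[[1]]
      if (!is.na(sc) && (is.null(tab) || length(tab) != sc || anyNA(tab))) {
        flag(id, "contribution", paste0(
          "custom edge ", id, " must give one signed delta per source state (", sc, " entries)"
        ))
      }
    }
  }
  ekey <- paste(edges$from, edges$to)
  for (k in unique(ekey[duplicated(ekey)])) {
    flag(gsub(" ", " -> ", k), "duplicate_edge",
      paste0("more than one edge for ordered pair ", gsub(" ", " -> ", k)))
  }
  for (node in names(model$overrides)) {
    i <- match(node, nodes$name)
    if (is.na(i)) {
      flag(node, "override", paste0("overrides given for unknown node '", node, "'"))
      next
    }
    inputs <- bstt_inputs(model, node)
    radices <- nodes$state_count[match(inputs, nodes$name)]
    ov <- model$overrides[[node]]
    for (j in seq_len(nrow(ov))) {
      when <- ov$when[[j]]
      then <- ov$then[j]
      if (length(when) != length(inputs) || any(when < 0) || any(when >= radices)) {
        flag(node, "override", paste0(
          "override row (", paste(when, collapse = ","), ") for node '", node,
          "' does not match its inputs (", paste(inputs, collapse = ","), ")"
        ))
      }
      if (is.na(then) || then < 0 || then >= nodes$state_count[i]) {
        flag(node, "override", paste0(
          "override output ", then, " for node '", node, "' is outside 0..",
          nodes$state_count[i] - 1L
        ))
      }
    }
  }
  if (length(bad) == 0) {
    tibble::tibble(element = character(), kind = character(), message = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

# BSTT input order for a node: incoming-edge sources in edge declaration
# order, then the node itself, always last (even under a self-edge, where the
# node then appears twice and both columns read the same state).
bstt_inputs <- function(model, node) {
  c(model$edges$from[model$edges$to == node], node)
}

#' Build a node's big state transition table (BSTT)
#'
#' Enumerates every combination of the node's input states (regulators in
#' edge declaration order, then the node's own state last) and fills the
#' next-state column with the additive default
#' `clamp(self + sum of signed edge contributions)`, then applies any row
#' overrides recorded on the model.
#'
#' Rows are ordered lexicographically over the input tuple (first input
#' varies slowest), i.e. by mixed-radix row index.
#'
#' @param model a valid [logic_model()].
#' @param node target node name.
#' @return A `logic_bstt`: list with `target`, `input_order`, `radices`, and
#'   `rows` — a tibble with one integer column per input, `next_state`, and
#'   a logical `overridden` flag.
#' @export
build_bstt <- function(model, node) {
  stopifnot(inherits(model, "logic_model"))
  nodes <- model$nodes
  if (!node %in% nodes$name) stop("build_bstt: unknown node '", node, "'", call. = FALSE)
  inputs <- bstt_inputs(model, node)
  radices <- nodes$state_count[match(inputs, nodes$name)]
  n_in <- length(inputs)
  n_rows <- prod(radices)
  digits <- index_to_state(seq_len(n_rows) - 1L, radices) # n_rows x n_in matrix
  in_edges <- model$edges[model$edges$to == node, ]
  total <- digits[, n_in] # self term
  for (i in seq_len(nrow(in_edges))) {
    total <- total + edge_contribution(as.list(in_edges[i, ]), digits[, i])
  }
  max_state <- nodes$state_count[match(node, nodes$name)] - 1L
  nxt <- clamp_state(total, max_state)
  overridden <- logical(n_rows)
  ov <- model$overrides[[node]]
  for (j in seq_len(nrow(ov %||% tibble::tibble()))) {
    when <- ov$when[[j]]
    if (length(when) != n_in || any(when < 0) || any(when >= radices)) {
      stop("override row (", paste(when, collapse = ","), ") for node '", node,
        "' does not name an existing input tuple", call. = FALSE)
    }
    if (ov$then[j] < 0 || ov$then[j] > max_state) {
      stop("override output ", ov$then[j], " for node '", node,
        "' is outside 0..", max_state, call. = FALSE)
    }
    key <- state_to_index(when, radices) + 1L
    nxt[key] <- ov$then[j]
    overridden[key] <- TRUE
  }
  rows <- tibble::as_tibble(digits, .name_repair = ~ make.unique(inputs, sep = "."))
  rows$next_state <- nxt
  rows$overridden <- overridden
  structure(
    list(target = node, input_order = inputs, radices = radices, rows = rows),
    class = "logic_bstt"
  )
}

#' Compile a model into per-node update functions
#'
#' Validation is run first (any violation is an error); then every node's
#' BSTT is built and frozen into a lookup table over the global state. Nodes
#' with no incoming edges get the identity update — the additive rule with
#' an empty sum is `clamp(self) = self`.
#'
#' @param model a [logic_model()].
#' @param max_states validation cap passed to [validate_model()].
#' @return A `compiled_logic_model`: deterministic synchronous update rules
#'   plus the state-indexing metadata ([state_to_index()] radices/weights).
#' @export
compile_model <- function(model, max_states = 5) {
  report <- validate_model(model, max_states = max_states)
  if (nrow(report) > 0) {
    stop("model '", model$name, "' is invalid:\n  ",
      paste(report$message, collapse = "\n  "), call. = FALSE)
  }
  nodes <- model$nodes
  radices <- nodes$state_count
  updates <- vector("list", nrow(nodes))
  names(updates) <- nodes$name
  for (k in seq_len(nrow(nodes))) {
    bstt <- build_bstt(model, nodes$name[k])
    updates[[k]] <- list(
      inputs = match(bstt$input_order, nodes$name),
      radices_in = bstt$radices,
      table = bstt$rows$next_state
    )
  }
  structure(
    list(
      name = model$name,
      node_names = nodes$name,
      radices = radices,
      labels = nodes$labels,
      total_states = prod(radices),
      updates = updates,
      pins = integer()
    ),
    class = "compiled_logic_model"
  )
}

#' @export
print.logic_model <- function(x, ...) {
  cat("<logic_model> '", x$name, "': ", nrow(x$nodes), " nodes, ",
    nrow(x$edges), " edges, ",
    sum(purrr::map_int(x$overrides, nrow)), " overridden rows\n", sep = "")
  if (nrow(x$nodes) > 0) {
    cat("  states: ", paste0(x$nodes$name, "(", x$nodes$state_count, ")",
      collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.logic_bstt <- function(x, ...) {
  cat("<logic_bstt> for '", x$target, "' over (",
    paste(x$input_order, collapse = ", "), "): ",
    nrow(x$rows), " rows, ", sum(x$rows$overridden), " overridden\n", sep = "")
  print(x$rows, ...)
  invisible(x)
}

#' @export
print.compiled_logic_model <- function(x, ...) {
  cat("<compiled_logic_model> '", x$name, "': ", length(x$node_names),
    " nodes, ", format(x$total_states, big.mark = ","), " states", sep = "")
  if (length(x$pins) > 0) {
    cat("; pinned: ", paste0(names(x$pins), "=", x$pins, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
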