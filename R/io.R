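MODEL_SCHEMA_VERSION <- "1.0"

#' Read and write models as versioned JSON documents
#'
#' The on-disk format is a small, human-editable JSON document
#' (`schema_version` "1.0"). States are stored as labels — the integer
#' mapping is fixed by label order — so files stay readable and portable.
#' Override rows and experiment pins are stored as labels too. Unknown
#' fields in the document or the model object are preserved on a round
#' trip. Validation runs on load: a document whose model violates an
#' invariant (for example a node with more than `max_states` states, or an
#' edge to an unknown node) is rejected with a message naming the offending
#' element.
#'
#' @param path file path.
#' @param model a [logic_model()].
#' @param experiments named or unnamed list of [experiment()] objects to
#'   store alongside the model.
#' @param max_states validation cap applied on load.
#' @return `read_model()`: a list with `model` (a `logic_model`) and
#'   `experiments` (list of `logic_experiment`). `write_model()`: the path,
#'   invisibly. Writing is canonical: the same model always produces the
#'   same bytes.
#' @export
read_model <- function(path, max_states = 5) {
  force(path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in '", path, "': ",
      conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$schema_version)) {
    stop("'", path, "' is missing schema_version", call. = FALSE)
  }
  if (!identical(as.character(doc$schema_version), MODEL_SCHEMA_VERSION)) {
    stop("unsupported schema_version '", doc$schema_version, "' (expected ",
      MODEL_SCHEMA_VERSION, ")", call. = FALSE)
  }
  m <- doc$model
  if (is.null(m) || is.null(m$nodes)) {
    stop("'", path, "' has no model/nodes section", call. = FALSE)
  }
  model <- logic_model(m$name %||% "model", metadata = as.list(m$metadata))
  for (nd in m$nodes) {
    if (is.null(nd$name) || is.null(nd$states)) {
      stop("every node needs 'name' and 'states' (list of labels)", call. = FALSE)
    }
    pos <- if (is.null(nd$position)) NULL else unlist(nd$position)
    model <- add_node(model, nd$name, states = unlist(nd$states), position = pos)
  }
  for (e in m$edges %||% list()) {
    if (is.null(e$from) || is.null(e$to) || is.null(e$sign)) {
      stop("every edge needs 'from', 'to', and 'sign'", call. = FALSE)
    }
    model <- add_edge(model, e$from, e$to, sign = e$sign,
      contribution = if (is.null(e$contribution)) NULL else unlist(e$contribution))
  }
  for (ov in m$overrides %||% list()) {
    node <- ov$node
    if (is.null(node) || !node %in% model$nodes$name) {
      stop("override names unknown node '", node %||% "?", "'", call. = FALSE)
    }
    inputs <- bstt_inputs(model, node)
    when <- labels_to_states(model, inputs, unlist(ov$when), context = node)
    then <- labels_to_states(model, node, ov$then, context = node)
    model <- set_rule(model, node, when, then)
  }
  extra <- doc$model[setdiff(names(doc$model),
    c("name", "nodes", "edges", "overrides", "metadata"))]
  if (length(extra) > 0) model$metadata$.extra <- extra
  doc_extra <- doc[setdiff(names(doc),
    c("schema_version", "model", "experiments"))]
  if (length(doc_extra) > 0) model$metadata$.document_extra <- doc_extra

  report <- validate_model(model, max_states = max_states)
  if (nrow(report) > 0) {
    stop("model in '", path, "' is invalid:\n  ",
      paste(report$message, collapse = "\n  "), call. = FALSE)
  }
  experiments <- lapply(doc$experiments %||% list(), function(x) {
    pins <- integer()
    for (node in names(x$pins %||% list())) {
      if (!node %in% model$nodes$name) {
        stop("experiment '", x$name %||% "?", "' pins unknown node '", node, "'",
          call. = FALSE)
      }
      pins[node] <- labels_to_states(model, node, x$pins[[node]], context = x$name)
    }
    structure(list(name = x$name %||% "experiment", pins = pins),
      class = "logic_experiment")
  })
  names(experiments) <- purrr::map_chr(experiments, "name")
  list(model = model, experiments = experiments)
}

# map labels (or already-numeric strings/ints) to state integers for the
# given node(s); `nodes` is recycled against `labels`
labels_to_states <- function(model, nodes, labels, context = "") {
  labels <- unlist(labels)
  nodes <- rep_len(nodes, length(labels))
  purrr::map2_int(nodes, labels, function(nd, lb) {
    labs <- model$nodes$labels[[match(nd, model$nodes$name)]]
    i <- match(as.character(lb), labs)
    if (!is.na(i)) return(i - 1L)
    v <- suppressWarnings(as.integer(lb))
    if (!is.na(v)) return(v)
    stop("'", lb, "' is not a state label of node '", nd, "'",
      if (nzchar(context)) paste0(" (in ", context, ")"), call. = FALSE)
  })
}

#' @rdname read_model
#' @export
write_model <- function(model, path, experiments = list()) {
  stopifnot(inherits(model, "logic_model"))
  nodes <- lapply(seq_len(nrow(model$nodes)), function(i) {
    nd <- list(name = model$nodes$name[i], states = model$nodes$labels[[i]])
    if (!is.na(model$nodes$x[i])) nd$position <- c(model$nodes$x[i], model$nodes$y[i])
    nd
  })
  edges <- lapply(seq_len(nrow(model$edges)), function(i) {
    e <- list(from = model$edges$from[i], to = model$edges$to[i],
      sign = model$edges$sign[i])
    if (!is.null(model$edges$contribution[[i]])) {
      e$contribution <- model$edges$contribution[[i]]
    }
    e
  })
  overrides <- list()
  for (node in names(model$overrides)) {
    inputs <- bstt_inputs(model, node)
    in_labels <- model$nodes$labels[match(inputs, model$nodes$name)]
    out_labels <- model$nodes$labels[[match(node, model$nodes$name)]]
    ov <- model$overrides[[node]]
    for (j in seq_len(nrow(ov))) {
      overrides[[length(overrides) + 1L]] <- list(
        node = node,
        when = purrr::map2_chr(in_labels, ov$when[[j]], ~ .x[.y + 1L]),
        then = out_labels[ov$then[j] + 1L]
      )
    }
  }
  meta <- model$metadata
  extra <- meta$.extra
  doc_extra <- meta$.document_extra
  meta$.extra <- NULL
  meta$.document_extra <- NULL
  m <- list(name = model$name, nodes = nodes, edges = edges)
  if (length(overrides) > 0) m$overrides <- overrides
  if (length(meta) > 0) m$metadata <- meta
  m <- c(m, extra)
  exps <- lapply(experiments, function(x) {
    node_labels <- model$nodes$labels[match(names(x$pins), model$nodes$name)]
    pins <- purrr::map2(node_labels, x$pins, ~ .x[.y + 1L])
    names(pins) <- names(x$pins)
    list(name = x$name, pins = pins)
  })
  doc <- list(schema_version = MODEL_SCHEMA_VERSION, model = m)
  if (length(exps) > 0) doc$experiments <- unname(exps)
  doc <- c(doc, doc_extra)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Export an attractor summary table to CSV
#'
#' One row per attractor state, grouped by attractor: steady states
#' contribute one row, limit cycles one row per cycle position. Attractors
#' are ordered by descending basin size (ties by smallest state index);
#' basin percentages are written with one decimal place. Columns: the
#' attractor number, cycle position and length, each node's state as a
#' label (`<node>`) and as an integer (`<node>_state`), the basin size, and
#' the basin percentage.
#'
#' @param analysis a [find_attractors()] result.
#' @param path output file (RFC 4180 CSV, UTF-8).
#' @return The path, invisibly.
#' @export
write_attractor_csv <- function(analysis, path) {
  tb <- tidy(analysis)
  tb$basin_pct <- sprintf("%.1f", tb$basin_pct)
  readr::write_csv(tb, path)
  invisible(path)
}

#' Export a state-space graph to DOT or GraphML
#'
#' Nodes are labeled with their state tuples (as labels); states on an
#' attractor cycle carry an `on_cycle` attribute so they can be styled by
#' any Graphviz/GraphML consumer.
#'
#' @param graph an edge list from [state_space_graph()].
#' @param path output file.
#' @param format `"dot"` or `"graphml"`; defaults to the file extension.
#' @return The path, invisibly.
#' @export
write_state_graph <- function(graph, path, format = c("auto", "dot", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("dot", "graphml")) {
      stop("cannot infer graph format from extension '.", ext,
        "'; pass format = \"dot\" or \"graphml\"", call. = FALSE)
    }
    format <- ext
  }
  if (format == "dot") {
    lines <- c(
      "digraph state_space {",
      sprintf("  \"%s\" [label=\"%s\", attractor=%d, on_cycle=%s];",
        graph$from, graph$from_label, graph$attractor,
        ifelse(graph$on_cycle, "true", "false")),
      sprintf("  \"%s\" -> \"%s\";", graph$from, graph$to),
      "}"
    )
    writeLines(lines, path, useBytes = TRUE)
  } else {
    vertices <- data.frame(
      name = as.character(graph$from),
      label = graph$from_label,
      attractor = graph$attractor,
      on_cycle = graph$on_cycle,
      stringsAsFactors = FALSE
    )
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(graph$from), to = as.character(graph$to),
        stringsAsFactors = FALSE),
      directed = TRUE, vertices = vertices
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
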