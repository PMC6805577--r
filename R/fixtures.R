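#' Bundled example models
#'
#' `toy_model()` is a minimal three-node network used throughout the
#' documentation and tests: A (2 states) activates C (3 states) and
#' B (2 states) inhibits it, so C's transition table is
#' `C' = clamp(A - B + C)` over 12 rows while A and B, having no inputs,
#' hold their states. Its 12-state dynamics are fully hand-checkable:
#' 8 steady states, no limit cycles, basins (3, 3, 1, 1, 1, 1, 1, 1).
#'
#' `demo_model()` is the same wiring with wider state spaces —
#' A (2 states) and B (3 states) both feeding C (4 states) — giving a
#' 24-state space that exercises mixed radices.
#'
#' @return A [logic_model()].
#' @examples
#' toy_model() |> compile_model() |> find_attractors()
#' @export
toy_model <- function() {
  logic_model("toy") |>
    add_node("A", states = 2) |>
    add_node("B", states = 2) |>
    add_node("C", states = 3) |>
    add_edge("A", "C", "activate") |>
    add_edge("B", "C", "inhibit")
}

#' @rdname toy_model
#' @export
demo_model <- function() {
  logic_model("demo") |>
    add_node("A", states = 2) |>
    add_node("B", states = 3) |>
    add_node("C", states = 4) |>
    add_edge("A", "C", "activate") |>
    add_edge("B", "C", "inhibit")
}

#' The Arabidopsis floral organ fate network scaffold
#'
#' Node-and-state scaffold of the 15-gene regulatory network for floral
#' organ cell-fate determination in *Arabidopsis thaliana* (Espinosa-Soto,
#' Padilla-Longoria & Alvarez-Buylla 2004, Plant Cell 16:2923-2939): eight
#' binary nodes (FT, EMF1, SEP, AP2, WUS, UFO, CLF, LUG) and seven ternary
#' nodes (LFY, AP1, FUL, TFL1, AG, AP3, PI), for a state space of
#' 2^8 * 3^7 = 559,872 global states.
#'
#' The published logical rules are not redistributed with this package;
#' transcribe them from the cited reference into a rules file (see the
#' template at
#' `system.file("extdata", "floral-rules-template.json", package = "mvnet")`)
#' and pass its path to obtain the complete dynamic model. Without a rules
#' file the scaffold has no edges (every node holds its state), which is
#' sufficient for structural work.
#'
#' @param rules_path optional path to a transcription of the logical rules;
#'   see [read_rules()] for the format.
#' @return A [logic_model()] with 15 nodes, and — when `rules_path` is
#'   given — fully specified transition tables.
#' @export
floral_scaffold <- function(rules_path = NULL) {
  onoff <- c("OFF", "ON")
  lmh <- c("LOW", "MEDIUM", "HIGH")
  model <- logic_model("floral")
  for (nm in c("FT", "EMF1", "SEP", "AP2", "WUS", "UFO", "CLF", "LUG")) {
    model <- add_node(model, nm, states = onoff)
  }
  for (nm in c("LFY", "AP1", "FUL", "TFL1", "AG", "AP3", "PI")) {
    model <- add_node(model, nm, states = lmh)
  }
  if (!is.null(rules_path)) model <- read_rules(model, rules_path)
  model
}

#' Load fully specified logical rules into a model
#'
#' A rules file is a JSON document `{"rules": [...]}` where each entry
#' gives one node's complete logical rule as a truth table:
#' `{"node": "...", "inputs": ["...", ...], "rows": [{"when": [s, ...],
#' "then": s}, ...]}`. `when` lists integer input states in `inputs` order
#' and the rows must cover every input combination exactly once. The rule
#' is installed as custom (zero-contribution) edges from each input plus a
#' full set of transition-table overrides; the node's own state is appended
#' as the final table column as always, with the output repeated across it
#' unless the node lists itself among its inputs.
#'
#' @param model a [logic_model()] whose nodes the rules must match.
#' @param rules_path path to the rules JSON.
#' @return The model with edges and overrides installed.
#' @export
read_rules <- function(model, rules_path) {
  stopifnot(inherits(model, "logic_model"))
  force(rules_path)
  doc <- tryCatch(
    jsonlite::fromJSON(rules_path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in '", rules_path, "': ",
      conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$rules)) stop("rules file has no 'rules' array", call. = FALSE)
  nodes <- model$nodes
  for (rule in doc$rules) {
    node <- rule$node
    if (is.null(node) || !node %in% nodes$name) {
      stop("rules file names unknown node '", node %||% "?", "'", call. = FALSE)
    }
    inputs <- as.character(unlist(rule$inputs))
    if (!all(inputs %in% nodes$name)) {
      stop("rule for '", node, "' has unknown input(s) ",
        paste(setdiff(inputs, nodes$name), collapse = ", "), call. = FALSE)
    }
    for (src in inputs) {
      sc <- nodes$state_count[match(src, nodes$name)]
      model <- add_edge(model, src, node, "custom",
        contribution = rep(0L, sc))
    }
    radices_in <- nodes$state_count[match(inputs, nodes$name)]
    self_count <- nodes$state_count[match(node, nodes$name)]
    n_expected <- prod(radices_in)
    rows <- rule$rows %||% list()
    if (length(rows) != n_expected) {
      stop("rule for '", node, "' has ", length(rows), " rows; its inputs (",
        paste(inputs, collapse = ","), ") require ", n_expected, call. = FALSE)
    }
    seen <- logical(n_expected)
    when_list <- vector("list", n_expected * self_count)
    then_vec <- integer(n_expected * self_count)
    j <- 0L
    for (row in rows) {
      when <- as.integer(unlist(row$when))
      then <- as.integer(row$then)
      if (length(when) != length(inputs) || any(when < 0) ||
          any(when >= radices_in)) {
        stop("rule row (", paste(when, collapse = ","), ") for '", node,
          "' does not match its declared inputs", call. = FALSE)
      }
      if (is.na(then) || then < 0 || then >= self_count) {
        stop("rule output ", then, " for '", node, "' is outside 0..",
          self_count - 1L, call. = FALSE)
      }
      key <- state_to_index(when, radices_in) + 1L
      if (seen[key]) {
        stop("rule for '", node, "' lists input combination (",
          paste(when, collapse = ","), ") more than once", call. = FALSE)
      }
      seen[key] <- TRUE
      for (s in seq_len(self_count) - 1L) {
        j <- j + 1L
        when_list[[j]] <- c(when, s)
        then_vec[j] <- then
      }
    }
    model$overrides[[node]] <- tibble::tibble(when = when_list, then = then_vec)
  }
  model
}
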