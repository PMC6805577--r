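#' Generate a random multi-state network model
#'
#' Draws a seed-reproducible random model for property-based testing and
#' benchmarking: node state counts are sampled from `state_count_choices`,
#' each ordered node pair (self-pairs included) receives an edge with
#' probability `edge_probability`, each edge is inhibiting with probability
#' `inhibitor_fraction` (activating otherwise), and a fraction
#' `override_fraction` of every node's transition-table rows is replaced by
#' a uniformly random output. The generator uses R's Mersenne-Twister
#' stream (`normal.kind = "Inversion"`, `sample.kind = "Rejection"`) seeded
#' with `seed`, so the same seed yields the same model on any platform; the
#' caller's RNG state is left untouched. Generated models always pass
#' [validate_model()].
#'
#' @param n_nodes number of nodes (>= 1).
#' @param state_count_choices integer vector of allowed state counts,
#'   within 2..5.
#' @param edge_probability probability of each ordered-pair edge, in 0..1.
#' @param inhibitor_fraction probability that an edge inhibits, in 0..1.
#' @param override_fraction expected fraction of BSTT rows overridden per
#'   node, in 0..1.
#' @param seed integer seed.
#' @return A valid [logic_model()].
#' @export
random_model <- function(n_nodes, state_count_choices = 2:3,
                         edge_probability = 0.25, inhibitor_fraction = 0.3,
                         override_fraction = 0, seed = 1) {
  stopifnot(
    n_nodes >= 1,
    all(state_count_choices >= 2), all(state_count_choices <= 5),
    edge_probability >= 0, edge_probability <= 1,
    inhibitor_fraction >= 0, inhibitor_fraction <= 1,
    override_fraction >= 0, override_fraction <= 1
  )
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
    normal.kind = "Inversion", sample.kind = "Rejection")

  names <- sprintf("N%02d", seq_len(n_nodes))
  counts <- state_count_choices[
    sample.int(length(state_count_choices), n_nodes, replace = TRUE)
  ]
  model <- logic_model(paste0("random-", seed))
  for (i in seq_len(n_nodes)) {
    model <- add_node(model, names[i], states = counts[i])
  }
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      if (stats::runif(1) < edge_probability) {
        sign <- if (stats::runif(1) < inhibitor_fraction) "inhibit" else "activate"
        model <- add_edge(model, names[i], names[j], sign)
      }
    }
  }
  if (override_fraction > 0) {
    for (k in seq_len(n_nodes)) {
      inputs <- bstt_inputs(model, names[k])
      radices <- counts[match(inputs, names)]
      n_rows <- prod(radices)
      hit <- which(stats::runif(n_rows) < override_fraction)
      if (length(hit) == 0) next
      when_list <- lapply(hit, function(r) drop(index_to_state(r - 1L, radices)))
      then_vec <- sample.int(counts[k], length(hit), replace = TRUE) - 1L
      model$overrides[[names[k]]] <- tibble::tibble(
        when = when_list, then = as.integer(then_vec)
      )
    }
  }
  model
}
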