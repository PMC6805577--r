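# Independent brute-force oracle for attractor analysis.
#
# Deliberately shares no code path with the package internals: states are
# encoded with a locally written mixed-radix scheme, successors are
# re-derived from the model definition (edges + overrides, additive rule),
# and the functional graph is decomposed by composition-squaring
# (f^(2^k) with 2^k >= N maps every state onto its cycle; the cycle states
# are exactly the image), not by walking paths.

oracle_encode <- function(tuple, radices) {
  idx <- 0
  for (i in seq_along(radices)) idx <- idx * radices[i] + tuple[i]
  idx
}

oracle_decode <- function(idx, radices) {
  n <- length(radices)
  out <- integer(n)
  for (i in n:1) {
    out[i] <- idx %% radices[i]
    idx <- idx %/% radices[i]
  }
  out
}

# plain re-implementation of one synchronous step from the model spec
oracle_step <- function(model, tuple, pins = integer()) {
  nodes <- model$nodes
  nxt <- integer(nrow(nodes))
  for (k in seq_len(nrow(nodes))) {
    nm <- nodes$name[k]
    if (nm %in% names(pins)) {
      nxt[k] <- pins[[nm]]
      next
    }
    es <- model$edges[model$edges$to == nm, ]
    total <- tuple[k]
    for (i in seq_len(nrow(es))) {
      s <- tuple[match(es$from[i], nodes$name)]
      total <- total + switch(es$sign[i],
        activate = s, inhibit = -s, custom = es$contribution[[i]][s + 1])
    }
    val <- max(0, min(total, nodes$state_count[k] - 1))
    ov <- model$overrides[[nm]]
    if (!is.null(ov)) {
      key <- c(tuple[match(es$from, nodes$name)], tuple[k])
      for (j in seq_len(nrow(ov))) {
        if (identical(as.integer(ov$when[[j]]), as.integer(key))) {
          val <- ov$then[j]
          break
        }
      }
    }
    nxt[k] <- val
  }
  nxt
}

# full decomposition: list of cycles (1-based state indices, rotated to
# start at the smallest) and the basin size of each
oracle_attractors <- function(model, pins = integer()) {
  radices <- model$nodes$state_count
  n <- prod(radices)
  succ <- integer(n)
  for (i in seq_len(n)) {
    tuple <- oracle_decode(i - 1, radices)
    succ[i] <- oracle_encode(oracle_step(model, tuple, pins), radices) + 1L
  }
  f <- succ
  for (r in seq_len(ceiling(log2(max(n, 2))))) f <- f[f]
  cycle_states <- sort(unique(f))
  cycle_id <- integer(n)
  cycles <- list()
  for (c0 in cycle_states) {
    if (cycle_id[c0] != 0L) next
    cy <- c0
    cur <- succ[c0]
    while (cur != c0) {
      cy <- c(cy, cur)
      cur <- succ[cur]
    }
    id <- length(cycles) + 1L
    i <- which.min(cy)
    if (i > 1) cy <- c(cy[i:length(cy)], cy[seq_len(i - 1)])
    cycles[[id]] <- cy
    cycle_id[cy] <- id
  }
  basin <- tabulate(cycle_id[f], nbins = length(cycles))
  list(cycles = cycles, basin_size = basin)
}

# canonical, order-free form for comparing two decompositions
canonical_attractors <- function(cycles, basin_size) {
  cycles <- lapply(cycles, as.integer)
  ord <- order(vapply(cycles, min, numeric(1)))
  list(cycles = cycles[ord], basin_size = as.integer(basin_size[ord]))
}

analysis_canonical <- function(analysis) {
  canonical_attractors(analysis$cycles, analysis$summary$basin_size)
}
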