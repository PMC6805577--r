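test_that("mixed-radix indexing is the lexicographic bijection", {
  expect_equal(state_to_index(c(0, 0, 0), c(2, 2, 3)), 0)
  expect_equal(state_to_index(c(1, 1, 2), c(2, 2, 3)), 11)
  expect_equal(state_to_index(c(0, 1, 0), c(2, 2, 3)), 3)
  expect_error(state_to_index(c(0, 2, 0), c(2, 2, 3)), "out of range")
  expect_error(index_to_state(12, c(2, 2, 3)), "out of range")

  for (radices in list(c(2, 2, 3), c(5, 2), c(3, 4, 2, 2))) {
    n <- prod(radices)
    states <- index_to_state(0:(n - 1), radices)
    expect_equal(state_to_index(states, radices), 0:(n - 1)) # inverse
    # lexicographic order of tuples equals numeric order of indices
    expect_true(all(diff(state_to_index(states[order_tuples(states), ], radices)) == 1))
  }
})

test_that("the synchronous successor updates every node from the same current state", {
  cm <- compile_model(toy_model())
  expect_identical(successor(cm, c(1, 0, 0)), c(1L, 0L, 1L))
  expect_identical(successor(cm, c(1, 0, 2)), c(1L, 0L, 2L)) # fixed point
  expect_identical(successor(cm, c(0, 1, 0)), c(0L, 1L, 0L)) # fixed point
  # matrix form agrees with vector form
  states <- index_to_state(0:11, cm$radices)
  batch <- successor(cm, states)
  for (i in 1:12) expect_identical(batch[i, ], successor(cm, states[i, ]))
})

test_that("the toy model decomposes into the 8 hand-derived steady states", {
  a <- find_attractors(compile_model(toy_model()))
  expect_equal(nrow(a$summary), 8)
  expect_true(all(a$summary$cycle_length == 1))
  expect_equal(a$summary$basin_size, c(3, 3, 1, 1, 1, 1, 1, 1))
  expect_equal(sum(a$summary$basin_size), 12)
  expect_equal(sum(a$summary$basin_pct), 100)
  # the two basin-3 attractors are (0,1,0) and (1,0,2)
  top <- sort(unlist(a$cycles[1:2])) - 1
  expect_equal(top, c(
    state_to_index(c(0, 1, 0), c(2, 2, 3)),
    state_to_index(c(1, 0, 2), c(2, 2, 3))
  ))
})

test_that("steady states and limit cycles are both found and closed under the successor", {
  a <- find_attractors(compile_model(not_loop_model()))
  expect_equal(sort(a$summary$cycle_length), c(1, 1, 2))
  cm <- compile_model(not_loop_model())
  for (cy in a$cycles) {
    for (s in cy) {
      cur <- drop(index_to_state(s - 1, cm$radices))
      for (k in seq_along(cy)) cur <- successor(cm, cur)
      expect_equal(state_to_index(cur, cm$radices) + 1, s) # closure
    }
  }

  b <- find_attractors(compile_model(self_inhibit_model()))
  expect_equal(b$summary$basin_size, 3)
  expect_equal(b$cycles[[1]], 1) # the all-zero state
})

test_that("analysis refuses state spaces above the cap with guidance", {
  cm <- compile_model(toy_model())
  expect_error(find_attractors(cm, analysis_cap = 10), "analysis_cap")
  expect_silent(invisible(find_attractors(cm, analysis_cap = 12)))
})

test_that("analysis is deterministic and matches the brute-force oracle on random models", {
  for (seed in 1:25) {
    m <- property_model(seed, overrides = seed %% 2 == 0)
    a <- find_attractors(compile_model(m))
    expect_identical(analysis_canonical(a), analysis_canonical(find_attractors(compile_model(m))))
    oracle <- oracle_attractors(m)
    expect_identical(
      analysis_canonical(a),
      canonical_attractors(oracle$cycles, oracle$basin_size)
    )
    expect_equal(sum(a$summary$basin_size), prod(m$nodes$state_count))
  }
})

test_that("trajectories reach the attractor that the exhaustive analysis assigns", {
  m <- toy_model()
  cm <- compile_model(m)
  a <- find_attractors(cm)

  tr <- simulate_model(cm, c(1, 0, 0))
  expect_equal(tr$index, c(6, 7, 8))
  expect_equal(attr(tr, "transient_length"), 2)
  expect_equal(attr(tr, "cycle_length"), 1)

  tr0 <- simulate_model(cm, c(0, 1, 0)) # from a steady state
  expect_equal(nrow(tr0), 1)
  expect_equal(attr(tr0, "transient_length"), 0)

  # every initial state lands in its assigned basin
  for (i in 0:11) {
    tri <- simulate_model(cm, drop(index_to_state(i, cm$radices)))
    terminal <- tri$index[nrow(tri)] + 1
    expect_equal(a$basin_of[terminal], a$basin_of[i + 1])
  }

  # a 2-cycle is reported as such
  cm2 <- compile_model(not_loop_model())
  tr2 <- simulate_model(cm2, c(0, 0))
  expect_equal(attr(tr2, "cycle_length"), 2)

  # exhausted step budget flags the trajectory incomplete
  tr3 <- simulate_model(cm, c(1, 0, 0), max_steps = 1)
  expect_false(attr(tr3, "complete"))

  expect_error(simulate_model(cm, c(9, 0, 0)), "out of range")
  expect_error(simulate_model(cm, c("bogus", "0", "0")), "not a state label")
})

test_that("the state-space graph is functional: one out-edge per state", {
  a <- find_attractors(compile_model(toy_model()))
  g <- state_space_graph(a)
  expect_equal(nrow(g), 12)
  expect_equal(sort(g$from), 0:11) # each state exactly once
  expect_true(all(g$to %in% g$from))
  expect_equal(sum(g$on_cycle), 8)

  # basin restriction: 3 states, 2 non-loop edges + 1 self-loop
  big <- which(a$summary$basin_size == 3)[1]
  gb <- state_space_graph(a, basin = big)
  expect_equal(nrow(gb), 3)
  expect_equal(sum(gb$from == gb$to), 1)
  expect_true(all(a$basin_of[gb$from + 1] == big))

  # single steady state alone is one self-loop
  small <- which(a$summary$basin_size == 1)[1]
  gs <- state_space_graph(a, basin = small)
  expect_equal(nrow(gs), 1)
  expect_equal(gs$from, gs$to)

  expect_error(state_space_graph(a, graph_cap = 5), "graph cap")
  expect_error(state_space_graph(a, basin = 99), "no attractor")
})
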