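# small models used across test files, built in code

# single 3-state node inhibiting itself: next = clamp(c - c) = 0 everywhere
self_inhibit_model <- function() {
  logic_model("self-inhibit") |>
    add_node("C", states = 3) |>
    add_edge("C", "C", "inhibit")
}

# two binary nodes, each the negation of the other (full table overrides):
# (a, b) -> (1 - b, 1 - a); two fixed points and one period-2 cycle
not_loop_model <- function() {
  m <- logic_model("not-loop") |>
    add_node("A", states = 2) |>
    add_node("B", states = 2) |>
    add_edge("A", "B", "activate") |>
    add_edge("B", "A", "activate")
  for (b in 0:1) for (a in 0:1) {
    m <- set_rule(m, "A", c(b, a), 1L - b) # inputs of A: (B, A)
    m <- set_rule(m, "B", c(a, b), 1L - a) # inputs of B: (A, B)
  }
  m
}

# random-model configuration used by the property suites; total state space
# is at most 3^5 = 243, well inside brute-force range
property_model <- function(seed, overrides = FALSE) {
  random_model(
    n_nodes = 3L + (seed %% 3L),
    state_count_choices = 2:3,
    edge_probability = 0.35,
    inhibitor_fraction = 0.4,
    override_fraction = if (overrides) 0.15 else 0,
    seed = seed
  )
}

order_tuples <- function(states) {
  do.call(order, as.data.frame(states))
}
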