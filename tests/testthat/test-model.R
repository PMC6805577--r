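test_that("validation reports every structural violation with the offending element", {
  bad <- logic_model("bad") |>
    add_node("A", states = 2) |>
    add_node("A", states = 2) |>
    add_node("B", states = 6) |>
    add_node("C", states = 3, labels = c("x", "x", "y")) |>
    add_edge("A", "Z", "activate") |>
    add_edge("B", "C", "custom", contribution = c(0, 1)) # needs 6 entries
  report <- validate_model(bad)
  expect_true("duplicate_node" %in% report$kind)
  expect_true(any(report$kind == "state_count" & report$element == "B"))
  expect_true(any(report$kind == "labels" & report$element == "C"))
  expect_true(any(report$kind == "unknown_node" & grepl("Z", report$message)))
  expect_true(any(report$kind == "contribution"))

  # the cap is configurable, not mathematical
  six <- logic_model() |> add_node("N", states = 6)
  expect_true(nrow(validate_model(six)) > 0)
  expect_equal(nrow(validate_model(six, max_states = 6)), 0)

  expect_equal(nrow(validate_model(toy_model())), 0)
})

test_that("duplicate ordered edges and bad overrides are reported, not raised", {
  m <- toy_model() |> add_edge("A", "C", "inhibit")
  expect_true(any(validate_model(m)$kind == "duplicate_edge"))

  m2 <- toy_model() |> set_rule("C", c(1, 0), 1) # tuple too short
  expect_true(any(validate_model(m2)$kind == "override"))
  m3 <- toy_model() |> set_rule("C", c(1, 0, 0), 5) # output out of range
  expect_true(any(validate_model(m3)$kind == "override"))
})

test_that("clamping follows the printed boundary rules", {
  expect_identical(clamp_state(-1, 2), 0L)
  expect_identical(clamp_state(3, 2), 2L)
  expect_identical(clamp_state(1, 2), 1L)
  expect_identical(clamp_state(-5:5, 2), c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 2L, 2L, 2L, 2L))
})

test_that("edge contributions are +state, -state, or the custom table entry", {
  expect_identical(edge_contribution(list(sign = "activate"), 2), 2L)
  expect_identical(edge_contribution(list(sign = "inhibit"), 1), -1L)
  expect_identical(edge_contribution(list(sign = "activate"), 0), 0L)
  expect_identical(edge_contribution(list(sign = "inhibit"), 0), 0L)
  expect_identical(
    edge_contribution(list(sign = "custom", contribution = c(0L, -2L, 3L)), 0:2),
    c(0L, -2L, 3L)
  )
  expect_error(
    edge_contribution(list(sign = "custom", contribution = c(0L)), 1),
    "missing a contribution"
  )
})

test_that("the default BSTT is the clamped additive rule over all input tuples", {
  b <- build_bstt(toy_model(), "C")
  expect_identical(b$input_order, c("A", "B", "C"))
  expect_equal(nrow(b$rows), 2 * 2 * 3)
  row <- function(a, bb, cc) b$rows$next_state[b$rows$A == a & b$rows$B == bb & b$rows$C == cc]
  expect_equal(row(1, 0, 1), 2) # A - B + C = 2
  expect_equal(row(0, 1, 0), 0) # clamped below range
  expect_equal(row(1, 0, 2), 2) # clamped above range
  for (cc in 0:2) expect_equal(row(1, 1, cc), cc) # +1 - 1 cancels
  expect_true(all(b$rows$next_state >= 0 & b$rows$next_state <= 2))
  expect_false(any(b$rows$overridden))
})

test_that("overrides change exactly one row and are reversible", {
  m <- toy_model()
  b0 <- build_bstt(m, "C")
  m2 <- set_rule(m, "C", c(1, 0, 1), 0)
  b2 <- build_bstt(m2, "C")
  changed <- which(b2$rows$next_state != b0$rows$next_state)
  expect_length(changed, 1)
  expect_identical(which(b2$rows$overridden), changed)
  expect_equal(b2$rows$next_state[changed], 0)
  b3 <- build_bstt(clear_rule(m2, "C", c(1, 0, 1)), "C")
  expect_identical(b3$rows, b0$rows)

  expect_error(build_bstt(set_rule(m, "C", c(5, 0, 0), 1), "C"), "input tuple")
  expect_error(build_bstt(set_rule(m, "C", c(1, 0, 0), 9), "C"), "outside")
})

test_that("default tables are monotone in each input and deterministic to rebuild", {
  for (seed in 1:10) {
    m <- property_model(seed)
    for (node in m$nodes$name) {
      b <- build_bstt(m, node)
      expect_identical(build_bstt(m, node)$rows, b$rows) # determinism
      es <- m$edges[m$edges$to == node, ]
      signs <- c(ifelse(es$sign == "inhibit", -1, 1), 1) # self counts as activator
      radices <- b$radices
      tuples <- as.matrix(b$rows[, seq_along(radices)])
      for (j in seq_along(radices)) {
        can_step <- tuples[, j] + 1 < radices[j]
        if (!any(can_step)) next
        up <- tuples[can_step, , drop = FALSE]
        up[, j] <- up[, j] + 1L
        delta <- b$rows$next_state[state_to_index(up, radices) + 1] -
          b$rows$next_state[can_step]
        if (signs[j] > 0) expect_true(all(delta >= 0)) else expect_true(all(delta <= 0))
      }
    }
  }
})

test_that("compilation gives identity updates to input-free nodes and honors self-edges", {
  iso <- logic_model() |> add_node("X", states = 2)
  cm <- compile_model(iso)
  expect_identical(successor(cm, 0L), 0L)
  expect_identical(successor(cm, 1L), 1L)

  # toy model: A and B identity, C additive — checked over all 12 tuples
  cm2 <- compile_model(toy_model())
  for (a in 0:1) for (b in 0:1) for (cc in 0:2) {
    expect_identical(
      successor(cm2, c(a, b, cc)),
      c(a, b, max(0L, min(a - b + cc, 2L)))
    )
  }

  # self-inhibition: +c and -c cancel to 0 for every state
  cm3 <- compile_model(self_inhibit_model())
  for (cc in 0:2) expect_identical(successor(cm3, cc), 0L)

  expect_error(compile_model(logic_model() |> add_node("N", states = 7)), "invalid")
})

test_that("compiling the same model twice yields identical results", {
  m <- property_model(42, overrides = TRUE)
  expect_identical(compile_model(m), compile_model(m))
})
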