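toy_state <- function(net, ...) system_state(net, ...)

test_that("evaluate_rule implements the additive and product transfer functions", {
  comp <- data.frame(id = c("T", "U", "V"))
  ints <- data.frame(source = c("U", "V"), target = c("T", "T"),
                     sign = c(1, -1), layer = "fast")
  net <- layered_network(comp, ints)
  rule <- net$rules[["T.fast"]]

  st <- toy_state(net, fast = c(U = 0, V = 0, T = 0.5))
  expect_equal(evaluate_rule(rule, st), 0)          # zero input forces zero

  st <- toy_state(net, fast = c(U = 0.8, V = 0.5))
  expect_equal(evaluate_rule(rule, st), 0.3)        # 0.8 - 0.5, saturation 1

  # upper clamp: activators {1, 1}, inhibitor {1}, saturation 1
  comp2 <- data.frame(id = c("T", "U", "V", "W"))
  ints2 <- data.frame(source = c("U", "V", "W"), target = "T",
                      sign = c(1, 1, -1), layer = "fast")
  net2 <- layered_network(comp2, ints2)
  st2 <- toy_state(net2, fast = c(U = 1, V = 1, W = 1))
  expect_equal(evaluate_rule(net2$rules[["T.fast"]], st2), 1)

  # product combiner: prod(activators) * prod(1 - inhibitors)
  prule <- update_rule("T", "fast",
                       data.frame(source = c("U", "V"), sign = c(1, -1)),
                       combiner = "product")
  st3 <- toy_state(net, fast = c(U = 0.8, V = 0.5))
  expect_equal(evaluate_rule(prule, st3), 0.8 * 0.5)

  # saturation rescales the additive form
  srule <- update_rule("T", "fast", data.frame(source = "U", sign = 1),
                       saturation = 0.5)
  st4 <- toy_state(net, fast = c(U = 0.3))
  expect_equal(evaluate_rule(srule, st4), 0.6)

  # empty rule: input holds its value
  inp <- update_rule("U", "fast")
  expect_equal(evaluate_rule(inp, st4), 0.3)
})

test_that("global activity is the product of the two layers, clamp overrides", {
  comp <- data.frame(id = "TAK1", has_fast = TRUE, has_slow = TRUE)
  ints <- data.frame(source = "TAK1", target = "TAK1", sign = 1,
                     layer = c("fast", "slow"))
  net <- layered_network(comp, ints)
  expect_equal(global_activity(system_state(net, fast = c(TAK1 = 0.76),
                                            slow = c(TAK1 = 1)), "TAK1"),
               c(TAK1 = 0.76))
  expect_equal(unname(global_activity(system_state(net, fast = c(TAK1 = 1),
                                                   slow = c(TAK1 = 0)), "TAK1")), 0)
  expect_equal(unname(global_activity(system_state(net, fast = c(TAK1 = 0.5),
                                                   slow = c(TAK1 = 0.5)), "TAK1")), 0.25)
  st <- system_state(net, fast = c(TAK1 = 0.9), slow = c(TAK1 = 0.9),
                     clamp = c(TAK1 = 0.1))
  expect_equal(unname(global_activity(st, "TAK1")), 0.1)
  expect_error(global_activity(st, "NOPE"), "unknown component")
})

test_that("clamped inputs propagate down an activation chain", {
  net <- make_fixture("chain", 3)
  tr <- simulate_network(net, system_state(net, fast = c(C2 = 0, C3 = 0)),
                         clamps = c(C1 = 1), config = engine_config(seed = 4))
  expect_true(tr$converged)
  expect_state_near(tr$final, c(C2 = 1, C3 = 1))
})

test_that("the mutual-inhibition toggle holds its polarized state", {
  net <- make_sat1_toggle()  # saturation 1, as in the canonical formulation
  st <- system_state(net, fast = c(A = 1, B = 0))
  expect_true(is_stable(net, st))
  tr <- simulate_network(net, st, config = engine_config(seed = 1))
  expect_true(tr$converged)
  expect_state_near(tr$final, c(A = 1, B = 0))
  # brute-force check of both rules at the fixed point
  expect_equal(evaluate_rule(net$rules[["A.fast"]], st), 1)
  expect_equal(evaluate_rule(net$rules[["B.fast"]], st), 0)
})

test_that("is_stable applies the tolerance per sub-variable", {
  comp <- data.frame(id = c("A", "B"))
  ints <- data.frame(source = "A", target = "B", sign = 1, layer = "fast")
  net <- layered_network(comp, ints)
  st <- system_state(net, fast = c(A = 0.5, B = 0.5))
  expect_true(is_stable(net, st))
  st2 <- system_state(net, fast = c(A = 0.52, B = 0.5))
  expect_false(is_stable(net, st2))                       # moves B by 0.02
  expect_true(is_stable(net, st2, engine_config(tolerance = 0.05)))
})

test_that("trajectories stay in [0,1] and converged traces are stable (property)", {
  for (seed in 1:6) {
    net <- make_fixture("random_layered", n_components = 5, seed = seed)
    set.seed(seed * 100)
    init <- chondronet:::random_state(net)
    tr <- simulate_network(net, init, config = engine_config(),
                           record_history = TRUE)
    expect_true(all(tr$final$fast >= 0 & tr$final$fast <= 1))
    expect_true(all(tr$final$slow >= 0 & tr$final$slow <= 1))
    if (!is.null(tr$history)) {
      expect_true(all(tr$history$value >= 0 & tr$history$value <= 1))
    }
    if (tr$converged) {
      expect_true(is_stable(net, tr$final))
    }
  }
})

test_that("identical seeds reproduce traces bit-for-bit", {
  net <- make_fixture("random_layered", n_components = 6, seed = 8)
  init <- system_state(net, default = 0.5)
  t1 <- simulate_network(net, init, config = engine_config(seed = 77),
                         record_history = TRUE)
  t2 <- simulate_network(net, init, config = engine_config(seed = 77),
                         record_history = TRUE)
  expect_identical(t1$final, t2$final)
  expect_identical(t1$steps_used, t2$steps_used)
  expect_identical(t1$history, t2$history)
  t3 <- simulate_network(net, init, config = engine_config(seed = 78))
  expect_s3_class(t3, "simulation_trace")  # different seed may differ; no crash
})

test_that("a stable state is stable under any update order (50 reshuffles)", {
  net <- make_fixture("toggle_switch")
  st <- system_state(net, fast = c(A = 1, B = 0))
  for (seed in 1:50) {
    tr <- simulate_network(net, st, config = engine_config(seed = seed))
    expect_true(tr$converged)
    expect_state_near(tr$final, c(A = 1, B = 0))
  }
})

test_that("non-convergence is reported, never silently truncated", {
  # negation loop (A = NOT B, B = A) has no fixed point reachable from a
  # binary start: values shuttle between 0 and 1 forever
  comp <- data.frame(id = c("A", "B"))
  ints <- data.frame(source = c("B", "A"), target = c("A", "B"),
                     sign = c(-1, 1), layer = "fast")
  rules <- list(update_rule("A", "fast", data.frame(source = "B", sign = -1),
                            combiner = "product"),
                update_rule("B", "fast", data.frame(source = "A", sign = 1),
                            combiner = "product"))
  net <- layered_network(comp, ints, rules)
  tr <- simulate_network(net, system_state(net, fast = c(A = 1, B = 0)),
                         config = engine_config(max_total_steps = 40,
                                                max_fast_passes = 3, seed = 2))
  expect_false(tr$converged)
  expect_lte(tr$steps_used, 40)
})

test_that("invalid clamps and states are rejected", {
  net <- make_fixture("chain", 3)
  expect_error(simulate_network(net, clamps = c(NOPE = 1)), "unknown component")
  expect_error(simulate_network(net, clamps = c(C1 = 1.5)), "\\[0, 1\\]")
  expect_error(system_state(net, fast = c(C1 = -0.1)), "\\[0, 1\\]")
})
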