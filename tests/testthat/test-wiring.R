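test_that("default wiring reproduces the published architecture counts", {
  g <- build_wiring(wiring_config(), seed = 1)
  l <- g$layers
  expect_equal(length(l$sensory), 75)
  expect_equal(length(l$inter) + length(l$command), 14)
  expect_equal(length(l$motor), 6)
  expect_equal(length(l$inter) + length(l$command) + length(l$motor), 20)
  expect_equal(length(unlist(l)), 95)
  expect_length(validate_wiring(g), 0)
})

test_that("wiring is reproducible and respects the insertion mechanisms", {
  g1 <- build_wiring(wiring_config(), seed = 7)
  g2 <- build_wiring(wiring_config(), seed = 7)
  expect_identical(g1$edges, g2$edges)
  g3 <- build_wiring(wiring_config(), seed = 8)
  expect_false(identical(g1$edges, g3$edges))

  # p2 = 1: every source keeps all its candidate draws
  gp1 <- build_wiring(wiring_config(p2 = 1), seed = 3)
  out_deg <- table(factor(gp1$edges$src[gp1$edges$mechanism == 1],
                          levels = gp1$layers$sensory))
  expect_true(all(out_deg >= 1))

  # p2 = 0, p3 = 1 (fully stochastic wiring): all afferents come from the
  # top-up mechanism, none orphaned
  for (seed in 1:25) {
    g0 <- build_wiring(wiring_config(p2 = 0, p3 = 1, motor_fanin = "sparse"),
                       seed = seed)
    expect_true(all(g0$edges$mechanism %in% c(2, 3)))
    non_sensory <- unlist(g0$layers[c("inter", "command", "motor")])
    expect_true(all(non_sensory %in% g0$edges$tgt))
  }
})

test_that("the dense readout wires every command-motor pair; sparse mode does not", {
  g <- build_wiring(wiring_config(motor_fanin = "full"), seed = 2)
  motor_edges <- g$edges[g$edges$tgt %in% g$layers$motor, ]
  expect_equal(nrow(motor_edges),
               length(g$layers$command) * length(g$layers$motor))
  expect_true(all(motor_edges$src %in% g$layers$command))
  gs <- build_wiring(wiring_config(motor_fanin = "sparse"), seed = 2)
  expect_lt(sum(gs$edges$tgt %in% gs$layers$motor), nrow(motor_edges))
  expect_length(validate_wiring(gs), 0)
})

test_that("no non-sensory neuron is orphaned across random configurations", {
  set.seed(99)
  for (i in 1:200) {
    cfg <- wiring_config(
      n_sensory = sample(3:20, 1), n_inter = sample(2:8, 1),
      n_command = sample(2:8, 1), n_motor = sample(1:6, 1),
      fanout_per_source = sample(1:5, 1),
      p2 = runif(1), p3 = runif(1, 0.05, 1), p4 = runif(1),
      motor_fanin = "sparse")
    g <- build_wiring(cfg, seed = i)
    expect_length(validate_wiring(g), 0)
  }
})

test_that("layer discipline violations are detected", {
  g <- build_wiring(wiring_config(), seed = 1)
  # isolate a motor neuron
  bad <- g
  motor1 <- bad$layers$motor[1]
  bad$edges <- bad$edges[bad$edges$tgt != motor1, ]
  v <- validate_wiring(bad)
  expect_length(v, 1)
  expect_match(v, as.character(motor1))
  # corrupt a polarity
  bad2 <- g
  bad2$edges$polarity[1] <- 0
  expect_match(validate_wiring(bad2), "polarity", all = FALSE)
  # skip-layer edge
  bad3 <- g
  bad3$edges <- rbind(bad3$edges,
                      data.frame(src = g$layers$sensory[1], tgt = g$layers$motor[1],
                                 mechanism = 1L, polarity = 1))
  expect_match(validate_wiring(bad3), "layer discipline", all = FALSE)
})

test_that("sparsity is the occupied fraction of feasible synapse slots", {
  g <- build_wiring(wiring_config(), seed = 5)
  l <- g$layers
  slots <- 75 * length(l$inter) + length(l$inter) * length(l$command) +
    length(l$command) * length(l$motor) + length(l$command)^2
  expect_equal(sparsity(g), nrow(g$edges) / slots)
  expect_gt(sparsity(g), 0); expect_lt(sparsity(g), 1)
  # degenerate graphs
  empty <- g; empty$edges <- g$edges[0, ]
  expect_equal(sparsity(empty), 0)
  full <- g
  pairs <- rbind(expand.grid(src = l$sensory, tgt = l$inter),
                 expand.grid(src = l$inter, tgt = l$command),
                 expand.grid(src = l$command, tgt = l$motor),
                 expand.grid(src = l$command, tgt = l$command))
  full$edges <- data.frame(pairs, mechanism = 1L, polarity = 1)
  expect_equal(sparsity(full), 1)
})

test_that("mechanism-1 out-degree matches its Bernoulli insertion rate", {
  # moderate Monte Carlo here; the acceptance suite runs the full version
  f <- 4; p2 <- 0.5
  cfg <- wiring_config(fanout_per_source = f, p2 = p2)
  degs <- vapply(1:400, function(s) {
    e <- build_wiring(cfg, seed = s)$edges
    sum(e$mechanism == 1 & e$src %in% 1:75) / 75
  }, numeric(1))
  se <- sd(degs) / sqrt(length(degs))
  expect_lt(abs(mean(degs) - f * p2), 3 * se)
})
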