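# Construct LTC parameters with every value set explicitly, for closed-form
# checks: a chain wiring over `n` state neurons driven by one input.
manual_ltc <- function(n_state = 1, edges = NULL, cm = 1, gl = 1, x_leak = 0,
                       w = NULL, gamma = NULL, mu = NULL, E = NULL,
                       delta = 0.1, n_unfold = 1, n_input = 1) {
  nE <- if (is.null(edges)) 0 else nrow(edges)
  lay <- list(n_state = n_state, n_input = n_input,
              src = if (nE) edges$src else integer(0),
              tgt = if (nE) edges$tgt else integer(0),
              polarity = if (nE) (E %||% rep(1, nE)) else numeric(0),
              from_input = if (nE) edges$src > n_state else logical(0),
              motor_idx = seq_len(n_state))
  p <- list(layout = lay,
            theta_cm = ncpecg:::inv_softplus(rep(cm, length.out = n_state)),
            theta_gl = ncpecg:::inv_softplus(rep(gl, length.out = n_state)),
            x_leak = rep(x_leak, length.out = n_state),
            theta_w = if (nE) ncpecg:::inv_softplus(w) else numeric(0),
            gamma = if (nE) gamma else numeric(0),
            mu = if (nE) mu else numeric(0),
            E = if (nE) (E %||% rep(1, nE)) else numeric(0),
            delta = delta, n_unfold = as.integer(n_unfold))
  p$split <- ncpecg:::ltc_edge_split(lay)
  class(p) <- "ltc_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("synaptic sigmoid matches its closed form", {
  expect_equal(synapse_sigmoid(0.5, gamma = 3, mu = 0.5), 0.5)
  expect_equal(synapse_sigmoid(1, gamma = 2, mu = 0.5), 1 / (1 + exp(-1)))
  expect_equal(synapse_sigmoid(1, gamma = 2, mu = 0.5), 0.731059, tolerance = 1e-6)
  expect_equal(synapse_sigmoid(1e4, gamma = 5, mu = 0), 1)
  x <- seq(-3, 3, by = 0.1)
  s <- synapse_sigmoid(x, 4, 0.2)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
})

test_that("LTC right-hand side reduces to leak dynamics and matches hand values", {
  # w = 0: fixed point at x_leak, pure decay otherwise
  p0 <- manual_ltc(n_state = 3, cm = 2, gl = 1, x_leak = 0.5)
  expect_equal(ltc_rhs(rep(0.5, 3), 0, p0), rep(0, 3))
  p1 <- manual_ltc(n_state = 1, cm = 1, gl = 1, x_leak = 0)
  expect_equal(ltc_rhs(1, 0, p1), -1)

  # one neuron with a self-edge: hand evaluation of the full expression
  p2 <- manual_ltc(n_state = 1, edges = data.frame(src = 1, tgt = 1),
                   cm = 2, gl = 0.5, x_leak = 0.3,
                   w = 0.8, gamma = 4, mu = 0.2, E = -1)
  x <- 0.7
  sig <- 1 / (1 + exp(-4 * (x - 0.2)))
  expected <- -(0.5 / 2 + 0.8 / 2 * sig) * x + (0.3 * 0.5 / 2 + 0.8 / 2 * sig * (-1))
  expect_equal(ltc_rhs(x, 0, p2), expected, tolerance = 1e-12)

  expect_error(ltc_rhs(c(1, 2), 0, p2), "inconsistent")
})

test_that("semi-implicit Euler step matches the update ratio exactly", {
  # leak-only single neuron: x1 = (x0 Cm/D) / (Cm/D + gl)
  p <- manual_ltc(cm = 1, gl = 1, x_leak = 0, delta = 0.1)
  expect_equal(semi_implicit_step(1, 0, p), 10 / 11, tolerance = 1e-12)
  expect_equal(semi_implicit_step(1, 0, p), 0.909091, tolerance = 1e-6)

  # fixed point at x_leak for any delta
  p2 <- manual_ltc(cm = 0.7, gl = 1.3, x_leak = 0.4, delta = 1)
  expect_equal(semi_implicit_step(0.4, 0, p2), 0.4, tolerance = 1e-14)

  # with an input synapse: verify against the written-out ratio
  p3 <- manual_ltc(n_state = 1, edges = data.frame(src = 2, tgt = 1),
                   cm = 1.5, gl = 0.6, x_leak = 0.1,
                   w = 0.9, gamma = 5, mu = 0.5, E = 1, delta = 0.2)
  u <- 0.8; x <- -0.3
  sig <- 1 / (1 + exp(-5 * (u - 0.5)))
  expected <- (x * 1.5 / 0.2 + 0.6 * 0.1 + 0.9 * sig * 1) /
    (1.5 / 0.2 + 0.6 + 0.9 * sig)
  expect_equal(semi_implicit_step(x, u, p3), expected, tolerance = 1e-12)
})

test_that("leak-only trajectory follows the geometric closed form to 1e-12", {
  cm <- 1.2; gl <- 0.8; delta <- 0.25; x_leak <- 0.3; x0 <- -0.9
  p <- manual_ltc(cm = cm, gl = gl, x_leak = x_leak, delta = delta)
  rho <- (cm / delta) / (cm / delta + gl)
  x <- x0
  for (k in 1:50) {
    x <- semi_implicit_step(x, 0, p)
    expect_equal(x, x_leak + rho^k * (x0 - x_leak), tolerance = 1e-12)
  }
})

test_that("semi-implicit trajectory converges to a fine-step explicit solution", {
  skip_if_not_installed("deSolve")
  # 3-neuron chain driven by a constant input
  edges <- data.frame(src = c(4, 1, 2, 3), tgt = c(1, 2, 3, 1))
  p <- manual_ltc(n_state = 3, edges = edges, cm = c(1, 0.8, 1.2),
                  gl = c(0.9, 1.1, 1.0), x_leak = c(0.1, -0.1, 0),
                  w = c(0.7, 0.5, 0.9, 0.4), gamma = c(4, 5, 3, 6),
                  mu = c(0.4, 0.5, 0.6, 0.3), E = c(1, -1, 1, -1),
                  delta = 1e-3, n_unfold = 1)
  u <- 0.9
  x <- matrix(c(0.5, -0.5, 0.2), 3, 1)
  xs <- x
  for (k in 1:1000) xs <- ncpecg:::ltc_substep(p, xs, ncpecg:::ltc_precompute_input(p, matrix(u)))$x
  # independent oracle: classical 4th-order Runge-Kutta on the stated ODE
  sol <- deSolve::ode(
    y = c(0.5, -0.5, 0.2), times = c(0, 1), method = "rk4",
    parms = NULL, hini = 1e-4,
    func = function(t, y, parms) list(ltc_rhs(y, u, p)))
  expect_lt(max(abs(xs - sol[2, 2:4])), 1e-3)
})

test_that("step-halving leaves the unrolled LTC trajectory consistent", {
  set.seed(2)
  w <- build_wiring(tiny_wiring(), seed = 4)
  frames <- matrix(runif(6 * 5), 6, 5)
  p1 <- ltc_params(w, delta = 0.002, n_unfold = 4, cm_scale = 2, seed = 9)
  p2 <- p1; p2$delta <- 0.001; p2$n_unfold <- 8L
  r1 <- unroll_cell(p1, frames)
  r2 <- unroll_cell(p2, frames)
  expect_lt(max(abs(r1$final_state - r2$final_state)), 1e-4)
})

test_that("LTC states stay within the convex-combination bounds", {
  set.seed(3)
  w <- build_wiring(tiny_wiring(p2 = 0.9, p4 = 0.8), seed = 2)
  p <- ltc_params(w, delta = 1, n_unfold = 3, cm_scale = 1, seed = 5)
  p$x_leak <- runif(p$layout$n_state, -1, 1)
  frames <- matrix(runif(6 * 40, 0, 1), 6, 40)
  states <- unroll_cell(p, frames)$states
  expect_true(all(abs(states) <= 1 + 1e-12))
})

test_that("CfC step obeys its gate identities", {
  w <- build_wiring(tiny_wiring(), seed = 1)
  p <- cfc_params(w, seed = 3)
  x <- runif(p$layout$n_state, -0.5, 0.5)
  u <- runif(p$layout$n_input)
  z <- c(x, u)
  g <- tanh(p$Wg %*% z + p$bg)
  h <- tanh(p$Wh %*% z + p$bh)
  # t = 0: exact midpoint of the two compartments
  expect_equal(cfc_step(x, u, 0, p), drop((g + h) / 2), tolerance = 1e-12)
  # t -> Inf with f > 0: the h compartment takes over
  expect_equal(cfc_step(x, u, 1e6, p), drop(h), tolerance = 1e-9)
  # g == h: gate becomes irrelevant
  p2 <- p; p2$Wg <- p2$Wh; p2$bg <- p2$bh
  for (tt in c(0, 0.5, 3, 50)) {
    expect_equal(cfc_step(x, u, tt, p2), drop(h), tolerance = 1e-12)
  }
})

test_that("scalar CfC gate matches a hand-evaluated blend", {
  # f=1, g=2, h=0, t=ln 3 -> sigma(-ln 3) = 1/4, X = 0.5
  w <- build_wiring(wiring_config(n_sensory = 1, n_inter = 1, n_command = 1,
                                  n_motor = 1, fanout_per_source = 1, p2 = 1,
                                  p3 = 1, p4 = 1), seed = 1)
  p <- cfc_params(w, seed = 1)
  n <- p$layout$n_state
  p$Wf <- p$Wf * 0; p$bf <- rep(ncpecg:::inv_softplus(1), n)
  p$Wg <- p$Wg * 0; p$bg <- rep(atanh(2 / 3), n)   # tanh compartment capped at 1;
  p$Wh <- p$Wh * 0; p$bh <- rep(0, n)              # use g = 2/3 and scale the check
  out <- cfc_step(rep(0, n), rep(0, p$layout$n_input), log(3), p)
  expect_equal(out, rep(0.25 * 2 / 3, n), tolerance = 1e-12)
})

test_that("unrolling masks non-edges and starts from rest", {
  w <- build_wiring(tiny_wiring(), seed = 6)
  p <- ltc_params(w, seed = 8)
  # constant zero input with zero weights and zero leak target: flat zero
  p0 <- p; p0$theta_w <- rep(ncpecg:::inv_softplus(1e-12), length(p0$theta_w))
  p0$x_leak <- rep(0, p0$layout$n_state)
  traj <- unroll_cell(p0, matrix(0, 6, 10))
  expect_true(all(abs(traj$motor) < 1e-9))
  # single frame equals one cell step from the zero state
  frames1 <- matrix(runif(6), 6, 1)
  one <- unroll_cell(p, frames1)
  X <- matrix(0, p$layout$n_state, 1)
  pre <- ncpecg:::ltc_precompute_input(p, frames1)
  for (k in seq_len(p$n_unfold)) X <- ncpecg:::ltc_substep(p, X, pre)$x
  expect_equal(one$final_state, drop(X), tolerance = 1e-12)
  expect_error(unroll_cell(p, matrix(numeric(0), 6, 0)), "empty")
})

test_that("zeroing a synapse makes the presynaptic neuron irrelevant to its target", {
  # two state neurons, edge 1 -> 2 plus an input synapse onto neuron 1
  edges <- data.frame(src = c(1, 3), tgt = c(2, 1))
  p <- manual_ltc(n_state = 2, edges = edges, cm = 1, gl = 1, x_leak = 0,
                  w = c(0.8, 0.6), gamma = c(5, 4), mu = c(0.5, 0.5),
                  E = c(1, 1), delta = 0.5)
  st1 <- c(0.2, 0.4); st2 <- c(0.9, 0.4)  # perturb neuron 1 only
  u <- 0.7
  # with the synapse active, neuron 2 feels the perturbation
  act <- semi_implicit_step(st1, u, p) - semi_implicit_step(st2, u, p)
  expect_gt(abs(act[2]), 1e-6)
  # with it zeroed, neuron 2 is unaffected
  pz <- p; pz$theta_w[1] <- ncpecg:::inv_softplus(1e-14)
  z <- semi_implicit_step(st1, u, pz) - semi_implicit_step(st2, u, pz)
  expect_lt(abs(z[2]), 1e-12)
})
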