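test_that("model building validates parameters and references", {
  net <- get_fixture("fig1a")$network
  expect_error(build_dynamics(net, list(defaults = list(d = 0))), "positive")
  expect_error(build_dynamics(net, list(defaults = list(beta = -1))), "positive")
  expect_error(build_dynamics(net, list(nodes = list(Q = list(d = 2)))),
               "unknown node")
  expect_error(build_dynamics(net, list(edges = list(list(source = "B",
                                                          target = "C", w = 2)))),
               "unknown edge")
})

test_that("drift at the origin matches the closed formula", {
  # F_n(0) = c_n + b_n * sigma(-beta_n * theta_n); fig1a has all-activating
  # unit-weight inputs, so theta = |I_n|/2
  net <- get_fixture("fig1a")$network
  m <- build_dynamics(net)
  f0 <- drift(m, c(0, 0, 0))
  expect_equal(unname(f0["A"]), plogis(10 * (0 - 1)), tolerance = 1e-12)
  expect_equal(unname(f0["B"]), plogis(10 * (0 - 1)), tolerance = 1e-12)
  expect_equal(unname(f0["C"]), plogis(10 * (0 - 0.5)), tolerance = 1e-12)
})

test_that("top nodes relax to the analytic equilibrium c/d from any start", {
  iso <- regulatory_network("x")
  m <- build_dynamics(iso, list(nodes = list(x = list(d = 2, c = 4))))
  for (x0 in c(0, 2, 9)) {
    ss <- find_steady_state(m, x0)
    expect_true(ss$converged)
    expect_equal(unname(ss$state["x"]), 2, tolerance = 1e-7)
  }
  # fig1e top nodes sit at c_top/d at steady state
  me <- build_dynamics(get_fixture("fig1e")$network)
  ss <- find_steady_state(me, rep(0.9, 5))
  expect_equal(unname(ss$state[c("p", "q")]), c(0.5, 0.5), tolerance = 1e-7)
})

test_that("pure decay integrates to the exponential solution", {
  iso <- regulatory_network("x")
  m <- build_dynamics(iso, list(defaults = list(c_top = 0)))
  tr <- simulate(m, 1, 1, n_out = 11)
  expect_equal(tr$x[nrow(tr)], exp(-1), tolerance = 1e-6)
  expect_equal(tr$x[1], 1)              # trajectory includes the initial state
})

test_that("clamped coordinates are held exactly, not approximately", {
  m <- build_dynamics(get_fixture("fig1a")$network)
  tr <- simulate(m, c(0.1, 0.2, 0.3), 10, clamps = clamp_assignment(A = 0.7))
  expect_true(all(tr$A == 0.7))
  ss <- find_steady_state(m, c(0, 0, 0), clamps = clamp_assignment(A = 0.7))
  expect_identical(unname(ss$state["A"]), 0.7)
  # clamping every node leaves an empty subsystem with residual zero
  ss_all <- find_steady_state(m, c(1, 1, 1),
                              clamps = clamp_assignment(A = 0.2, B = 0.4, C = 0.6))
  expect_true(ss_all$converged)
  expect_identical(ss_all$residual, 0)
})

test_that("an exact equilibrium is a fixed point of the integrator", {
  m <- build_dynamics(get_fixture("toggle")$network)
  ss <- find_steady_state(m, c(1, 0))
  expect_true(ss$converged)
  tr <- simulate(m, ss$state, 50)
  expect_equal(as.numeric(tr[nrow(tr), -1]), unname(ss$state), tolerance = 1e-6)
})

test_that("decay condition holds numerically at sampled states", {
  withr::local_seed(21)
  for (i in 1:5) {
    gen <- synth_spec(sample(4:7, 1), sample(6:10, 1),
                      n_toggle_motifs = 1, seed = 600 + i)
    m <- build_dynamics(generate_network(gen))
    upper <- state_box_upper(m)
    for (r in 1:5) {
      x <- runif(m$n, 0, pmax(upper, 1e-9))
      dFdx <- selfpart_derivative(m, x)
      expect_true(all(dFdx <= -m$d + 1e-6))
    }
  }
})

test_that("trajectories started in the invariant box stay in it", {
  withr::local_seed(22)
  for (i in 1:5) {
    m <- build_dynamics(generate_network(
      synth_spec(5, 8, n_toggle_motifs = 1, seed = 700 + i)))
    upper <- state_box_upper(m)
    x0 <- runif(m$n, 0, pmax(upper, 1e-9))
    tr <- simulate(m, x0, 100, n_out = 51)
    vals <- as.matrix(tr[, -1])
    expect_true(all(vals >= -1e-6))
    expect_true(all(t(vals) <= upper + 1e-6))
  }
})

test_that("acyclic dynamics converges on one globally stable equilibrium", {
  me <- build_dynamics(get_fixture("fig1e")$network)
  at <- enumerate_attractors(me, n_inits = 20, seed = 31)
  expect_equal(length(at$attractors), 1L)
  expect_equal(at$n_nonconverged, 0L)
  expect_equal(sum(at$basin_counts), 20L)
})

test_that("the toggle is bistable and attractor sweeps are seed-deterministic", {
  mt <- build_dynamics(get_fixture("toggle")$network)
  at <- enumerate_attractors(mt, n_inits = 50, seed = 3)
  expect_equal(length(at$attractors), 2L)
  states <- vapply(at$attractors, function(s) s$state, numeric(2))
  # the two states mirror each other: one node high, the other low
  expect_true(all(abs(sort(states[, 1]) - sort(states[, 2])) < 1e-6))
  at2 <- enumerate_attractors(mt, n_inits = 50, seed = 3)
  expect_identical(vapply(at$attractors, function(s) s$state, numeric(2)),
                   vapply(at2$attractors, function(s) s$state, numeric(2)))
})

test_that("a fully clamped model has exactly the clamp vector as attractor", {
  m <- build_dynamics(get_fixture("toggle")$network)
  cl <- clamp_assignment(u = 0.3, v = 0.8)
  at <- enumerate_attractors(m, n_inits = 5, seed = 9, clamps = cl)
  expect_equal(length(at$attractors), 1L)
  expect_identical(unname(at$attractors[[1]]$state), c(0.3, 0.8))
})

test_that("prescribed regulators determine a regulated node's course uniquely", {
  # two-node chain p -> q: different initial q converge onto one trajectory
  chain <- regulatory_network(c("p", "q"), data.frame(
    source = "p", target = "q", sign = "+"))
  m <- build_dynamics(chain)
  t1 <- simulate(m, c(0.5, 0), 20, n_out = 41)
  t2 <- simulate(m, c(0.5, 1), 20, n_out = 41)
  gap <- abs(t1$q - t2$q)
  expect_equal(gap[1], 1)
  expect_lt(gap[length(gap)], 1e-6)
  expect_true(all(diff(gap) <= 1e-9))   # monotone contraction
})

test_that("steady-state JSON is keyed by node id", {
  m <- build_dynamics(get_fixture("toggle")$network)
  ss <- find_steady_state(m, c(1, 0))
  js <- jsonlite::fromJSON(steady_state_json(ss))
  expect_named(js$state, c("u", "v"))
  expect_true(js$converged)
})
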