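# Hill regulation, the Euler fixed-point iteration and attractor enumeration.

test_that("Hill factors take their closed-form values and respect the domain", {
  expect_equal(hill_activation(0, 3, 8), 0)
  expect_equal(hill_activation(0.5, 3, 8), 0.5)   # 8 * 0.125 = 1 -> 1/2
  expect_equal(hill_activation(1, 3, 8), 8 / 9)
  expect_equal(hill_inhibition(0, 3, 8), 1)
  expect_equal(hill_inhibition(0.5, 3, 8), 0.5)
  expect_equal(hill_inhibition(1, 3, 8), 1 / 9)
  # monotonicity on a grid
  xs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(hill_activation(xs)) > 0))
  expect_true(all(diff(hill_inhibition(xs)) < 0))
  expect_error(hill_activation(1.2), "\\[0, 1\\]")
  expect_error(hill_inhibition(-0.1), "\\[0, 1\\]")
})

test_that("pooled production rate reproduces the four-regulator worked example", {
  net <- make_toy_network("bax_motif")
  full <- c(BAX = 0, `c-Myc` = 1, p53 = 1, `Bcl-2` = 0, `Bcl-xL` = 0)
  expect_equal(production_rate("BAX", full, net), 16 / 17, tolerance = 1e-14)
  off <- c(BAX = 0, `c-Myc` = 0, p53 = 0, `Bcl-2` = 0, `Bcl-xL` = 0)
  expect_equal(production_rate("BAX", off, net), 0)
  mixed <- c(BAX = 0, `c-Myc` = 0.5, p53 = 0, `Bcl-2` = 0.5, `Bcl-xL` = 0)
  expect_equal(production_rate("BAX", mixed, net), 0.25)
})

test_that("state derivative is production minus degradation", {
  net <- make_toy_network("no_edges")
  d <- state_derivative(c(A = 1, B = 0.5, C = 0), net)
  # unregulated nodes are constitutively on: f = 1, so dx/dt = 1 - x
  expect_equal(unname(d), c(0, 0.5, 1))

  bax <- make_toy_network("bax_motif")
  st <- c(BAX = 0, `c-Myc` = 1, p53 = 1, `Bcl-2` = 0, `Bcl-xL` = 0)
  expect_equal(unname(state_derivative(st, bax)["BAX"]), 16 / 17)

  # a state placed at x = f is a fixed point of that node by construction
  st2 <- st
  st2["BAX"] <- 16 / 17
  expect_equal(unname(state_derivative(st2, bax)["BAX"]), 0)
})

test_that("zero-mode convention drives unactivated nodes to zero", {
  net <- make_toy_network("no_edges")
  p <- dynamics_params(no_regulator = "zero", n_starts = 10, seed = 1)
  aset <- find_attractors(net, p)
  expect_length(aset$attractors, 1)
  expect_true(all(aset$attractors[[1]]$state < 1e-3))
})

test_that("the self-activator converges to the closed-form stable roots", {
  net <- make_toy_network("self_activator")
  golden <- (1 + sqrt(5)) / 4   # stable root of 8x^3 - 8x^2 + 1 = 0
  hi <- iterate_to_attractor(c(A = 0.9), net)
  expect_s3_class(hi, "endo_attractor")
  expect_equal(unname(hi$state), golden, tolerance = 1e-3)
  expect_lt(hi$residual, 1e-4)
  lo <- iterate_to_attractor(c(A = 0.1), net)
  expect_equal(unname(lo$state), 0, tolerance = 1e-3)
  # an exact fixed point is returned unchanged at the first iteration
  at0 <- iterate_to_attractor(c(A = 0), net)
  expect_equal(unname(at0$state), 0)
  expect_equal(at0$converged_at, 1L)
})

test_that("attractor enumeration matches the 1-node bisection oracle", {
  net <- make_toy_network("self_activator")
  aset <- find_attractors(net, dynamics_params(n_starts = 200, seed = 42))
  found <- sort(vapply(aset$attractors, function(a) unname(a$state), numeric(1)))
  oracle <- stable_fixed_points_1d(function(x) hill_activation(x) - x)
  expect_length(found, length(oracle))
  expect_equal(found, oracle, tolerance = 1e-3)
})

test_that("the toggle's attractors match the 2-node oracle and its symmetry", {
  net <- make_toy_network("toggle")
  aset <- find_attractors(net, dynamics_params(n_starts = 300, seed = 7))
  expect_gte(length(aset$attractors), 2)
  # algebraic fixed points: x = 1/(1+8 y^3), y = 1/(1+8 x^3); eliminate y
  h <- function(x) hill_inhibition(hill_inhibition(x)) - x
  xs <- stable_fixed_points_1d(h)
  for (at in aset$attractors) {
    x <- unname(at$state["A"])
    expect_lt(min(abs(xs - x)), 1e-3)
    expect_equal(unname(at$state["B"]), hill_inhibition(x), tolerance = 1e-3)
  }
  # the attractor set is closed under swapping A and B
  states <- lapply(aset$attractors, `[[`, "state")
  for (st in states) {
    swapped <- c(A = unname(st["B"]), B = unname(st["A"]))
    d <- vapply(states, function(s) max(abs(s - swapped)), numeric(1))
    expect_lt(min(d), 0.01)
  }
})

test_that("a network without edges relaxes every node to tau", {
  aset <- find_attractors(make_toy_network("no_edges"),
                          dynamics_params(n_starts = 50, seed = 3))
  expect_length(aset$attractors, 1)
  expect_equal(unname(aset$attractors[[1]]$state), rep(1, 3), tolerance = 1e-3)
})

test_that("iterates stay in [0,1] and residuals pass re-evaluation", {
  for (s in 1:10) {
    net <- make_toy_network("random", n_nodes = 8, density = 0.3, seed = s)
    aset <- find_attractors(net, dynamics_params(n_starts = 15, seed = 100 + s))
    expect_gte(aset$state_range[1], 0)
    expect_lte(aset$state_range[2], 1)
    for (at in aset$attractors) {
      d <- state_derivative(at$state, net)
      expect_lt(max(abs(d)), 1e-4)
    }
  }
})

test_that("attractor sets are robust to the random-start seed", {
  sorted_states <- function(aset) {
    sts <- lapply(aset$attractors, `[[`, "state")
    sts[order(vapply(sts, function(s) s[[1]], numeric(1)))]
  }
  for (nm in c("self_activator", "toggle")) {
    net <- make_toy_network(nm)
    a1 <- sorted_states(find_attractors(net, dynamics_params(n_starts = 1000, seed = 11)))
    a2 <- sorted_states(find_attractors(net, dynamics_params(n_starts = 1000, seed = 99)))
    expect_length(a1, length(a2))
    for (i in seq_along(a1)) expect_lt(max(abs(a1[[i]] - a2[[i]])), 0.01)
  }
})

test_that("attractors under (n=3, a=8) and (n=4, a=16) are equivalent", {
  high_low <- function(aset) {
    pats <- vapply(aset$attractors, function(a) {
      paste(as.integer(a$state > 0.5), collapse = "")
    }, character(1))
    sort(unique(pats))
  }
  for (nm in c("self_activator", "toggle", "bax_motif")) {
    net <- make_toy_network(nm)
    a38 <- find_attractors(net, dynamics_params(n = 3, a = 8, n_starts = 200, seed = 5))
    a416 <- find_attractors(net, dynamics_params(n = 4, a = 16, n_starts = 200, seed = 5))
    expect_equal(length(a38$attractors), length(a416$attractors), info = nm)
    expect_equal(high_low(a38), high_low(a416), info = nm)
  }
})

test_that("parameter validation enforces the switch-like regime", {
  expect_error(dynamics_params(n = 2))
  expect_error(dynamics_params(n = 11))
  expect_error(dynamics_params(dt = 0))
  expect_error(dynamics_params(epsilon = -1))
})

test_that("attractor tables expose the optional 0-1 rescale", {
  net <- make_toy_network("self_activator")
  aset <- find_attractors(net, dynamics_params(n_starts = 100, seed = 2))
  raw <- attractor_table(aset)
  resc <- attractor_table(aset, rescale = TRUE)
  expect_equal(as.numeric(resc["A", ]), as.numeric(raw["A", ]) * 9 / 8)
  expect_equal(resc["basin_count", ], raw["basin_count", ])
})
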