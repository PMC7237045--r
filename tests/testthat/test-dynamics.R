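test_that("the transfer function matches its closed form", {
  expect_equal(transfer(2, bias = 2), 0.5)
  expect_equal(transfer(0, bias = 2), 0.5 * (1 + tanh(-2)))
  expect_equal(transfer(1e3), 1)
  expect_equal(transfer(-1e3), 0)
  # derivative against central differences
  x <- seq(-3, 6, by = 0.5)
  num <- (transfer(x + 1e-6) - transfer(x - 1e-6)) / 2e-6
  expect_equal(transfer_deriv(x), num, tolerance = 1e-8)
})

test_that("the zero-input fixed point is self-consistent and stable", {
  # no recurrence: fixed point at the origin
  net0 <- small_net(seed = 1, p_conn = 0)
  x0 <- find_fixed_point(net0)
  expect_equal(as.numeric(x0), rep(0, 50))
  expect_equal(transfer(as.numeric(x0)), rep(0.5 * (1 + tanh(-2)), 50))

  net <- build_network(network_spec(), seed = 2)
  x0 <- find_fixed_point(net)
  resid <- max(abs(as.vector(net$weights %*% transfer(x0)) - x0))
  expect_lt(resid, 1e-11)
  # evolving from a small perturbation returns to the fixed point
  pert <- x0 + rnorm(length(x0), sd = 0.05)
  tr <- trial_set(1, n_pulses = c(0, 0), alphas = c(1, 1), seed = 3)
  act <- simulate_network(net, tr, x_init = pert)
  expect_lt(max(abs(act$x_final[, 1] - x0)), 1e-4)
})

test_that("spontaneous firing rates are small", {
  for (s in 1:2) {
    net <- build_network(network_spec(), seed = s)
    expect_lte(max(transfer(find_fixed_point(net))), 0.05)
  }
})

test_that("zero-input dynamics stay at the fixed point", {
  net <- small_net(seed = 4)
  tr <- trial_set(1, n_pulses = c(0, 0), alphas = c(1, 1), seed = 5)
  act <- simulate_network(net, tr, bins = 50)
  x0_rates <- as.numeric(transfer(find_fixed_point(net), net$spec$bias))
  spread <- apply(act$rates[, , 1], 1, function(r) diff(range(r)))
  expect_lt(max(spread), 1e-5)
  expect_equal(act$rates[, 50, 1], x0_rates, tolerance = 1e-5)
})

test_that("the C++ integrator matches the double-precision R reference", {
  net <- small_net(seed = 6)
  tr <- quick_trials(n_per = 2, seed = 7)
  ref <- selnet:::euler_reference(net, tr, dt = 0.01)
  act <- simulate_network(net, tr, dt = 0.01, bins = 5000L)
  expect_equal(act$rates, ref$rates, tolerance = 2e-5)
  expect_equal(act$x_final, ref$x_final, tolerance = 2e-4)
})

test_that("halving the integration step barely changes the solution", {
  net <- small_net(seed = 8)
  tr <- quick_trials(n_per = 1, seed = 9)
  a1 <- simulate_network(net, tr, dt = 0.01, bins = 50)
  a2 <- simulate_network(net, tr, dt = 0.005, bins = 50)
  expect_lt(max(abs(a1$rates[, 50, ] - a2$rates[, 50, ])), 1e-3)
})

test_that("rates are bounded and simulations are deterministic", {
  net <- small_net(seed = 10)
  tr <- quick_trials(n_per = 3, alphas = c(12, 6), seed = 11)
  a <- simulate_network(net, tr)
  expect_true(all(a$rates >= 0 & a$rates <= 1))
  b <- simulate_network(net, tr)
  expect_identical(a$rates, b$rates)
})

test_that("small inputs follow the linearized dynamics", {
  # for weak stimuli the deviation from the fixed point obeys
  # tau dx/dt = (Jt - I) x + c i(t) with Jt the linearized connectivity
  net <- small_net(seed = 12)
  x0 <- find_fixed_point(net)
  Jt <- linearize_network(net, x0)
  eps <- 0.01
  tr <- trial_set(1, n_pulses = c(4, 4), alphas = c(eps, eps), seed = 13)
  dt <- 0.01
  times <- seq(0, 50 - dt, by = dt)
  curr <- selnet:::currents_matrix(tr$pulses[1], times, dt, 0.5, eps)
  cm <- as.numeric(net$input_mask)
  xl <- numeric(length(x0))
  xfull <- x0
  err <- 0
  scale <- 0
  for (t in seq_along(times)) {
    xl <- xl + dt * (as.vector(Jt %*% xl) + cm * curr[t] - xl)
    xfull <- xfull + dt * (as.vector(net$weights %*% transfer(xfull)) +
                             cm * curr[t] - xfull)
    err <- max(err, max(abs((xfull - x0) - xl)))
    scale <- max(scale, max(abs(xl)))
  }
  expect_lt(err, 0.05 * scale)  # first-order agreement
})

test_that("downsampling averages time windows correctly", {
  r <- array(0, c(2, 6, 1))
  r[1, , 1] <- c(1, 1, 1, 5, 5, 5)     # piecewise constant
  r[2, , 1] <- seq(0.1, 0.6, by = 0.1)  # linear ramp
  act <- fake_activity(r, labels = "low", bin_width = 1)
  d3 <- downsample_activity(act, window = 2)
  expect_equal(d3$rates[1, , 1], c(1, 3, 5))
  expect_equal(d3$rates[2, , 1], c(0.15, 0.35, 0.55))  # window midpoints
  d1 <- downsample_activity(act, window = 6)
  expect_equal(as.numeric(d1$rates[, 1, 1]), c(3, 0.35))
  expect_error(downsample_activity(act, window = 4), "divide")
})

test_that("diverging dynamics abort with a diagnostic", {
  spec <- network_spec(n_exc = 40, n_inh = 10, g_exc = 40, g_inh = -1,
                       weight_sd = 0)
  net <- build_network(spec, seed = 1)
  tr <- quick_trials(n_per = 1, alphas = c(50, 50), seed = 2)
  expect_error(simulate_network(net, tr, x_init = rep(0, 50)), "diverged")
})
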