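test_that("sigmoid matches its closed form and is bounded and monotone", {
  p <- sigmoid_params()
  # at v = v0 the denominator is exactly 2
  expect_equal(sigmoid(p$v0, p), p$e0)
  # saturation towards 2 e0
  expect_gt(sigmoid(p$v0 + 1000 / p$r, p), 1.999 * p$e0)
  # scalar evaluation at v = 0: 5 / (1 + e^{3.36})
  expect_equal(sigmoid(0, p), 5 / (1 + exp(0.56 * 6)), tolerance = 1e-12)
  v <- seq(-50, 50, by = 0.25)
  s <- sigmoid(v, p)
  expect_true(all(s > 0 & s < 2 * p$e0))
  expect_true(all(diff(s) > 0))
  expect_error(sigmoid(NaN, p), "non-finite")
})

test_that("impulse response has the analytic peak, integral and support", {
  k <- synaptic_kernel(3.25, 100)
  expect_identical(impulse_response(k, -0.01), 0)
  expect_identical(impulse_response(k, 0), 0)
  # numeric maximization agrees with the d/dt = 0 solution t = 1/omega
  opt <- stats::optimize(function(t) impulse_response(k, t),
                         c(0, 0.2), maximum = TRUE)
  expect_equal(opt$maximum, 1 / k$omega, tolerance = 1e-3)
  expect_equal(opt$objective, k$G / exp(1), tolerance = 1e-6)
  # quadrature over [0, 20/omega] recovers the analytic integral G/omega
  q <- stats::integrate(function(t) impulse_response(k, t), 0, 20 / k$omega,
                        rel.tol = 1e-10)
  expect_equal(q$value, k$G / k$omega, tolerance = 1e-6)
})

test_that("region derivatives implement the three presynaptic drives", {
  sg <- sigmoid_params()
  ke <- synaptic_kernel(3.25, 100)
  ki <- synaptic_kernel(22, 50, "inhibitory")
  cc <- connectivity_constants()
  d0 <- region_derivatives(numeric(6), 0, sg, ke, ki, cc)
  s0 <- sigmoid(0, sg)
  expect_equal(d0[1:3], numeric(3))
  expect_equal(d0[4], ke$G * ke$omega * s0)
  expect_equal(d0[5], ke$G * ke$omega * cc$C2 * s0)
  expect_equal(d0[6], ki$G * ki$omega * cc$C4 * s0)
  # doubling the input changes only the excitatory branch, linearly
  d1 <- region_derivatives(numeric(6), 100, sg, ke, ki, cc)
  d2 <- region_derivatives(numeric(6), 200, sg, ke, ki, cc)
  expect_equal(d2[5] - d1[5], ke$G * ke$omega * 100)
  expect_equal(d2[c(4, 6)], d1[c(4, 6)])
})

test_that("a root-found equilibrium has vanishing derivatives", {
  skip_if_not_installed("pracma")
  f <- function(s) region_derivatives(s, 220)
  root <- pracma::fsolve(f, x0 = c(1, 10, 10, 0, 0, 0), tol = 1e-12)
  expect_lt(max(abs(region_derivatives(root$x, 220))), 1e-8)
})

test_that("the Euler path reproduces the synaptic kernel at first order", {
  # a single unit-rate impulse (height 1/dt for one step) through the
  # excitatory branch with all connectivity zeroed isolates one kernel
  ke <- synaptic_kernel(3.25, 100)
  ki <- synaptic_kernel(22, 50, "inhibitory")
  run <- function(dt) {
    n <- round(0.2 / dt)
    drv <- c(1 / dt, numeric(n - 1))
    x <- simulate_traditional(
      ke = ke, ki = ki, noise = noise_spec(0, 0),
      cfg = sim_config(dt = dt, duration = 0.2, burn_in = 0),
      seed = 1, connectivity = connectivity_constants(0, 0, 0, 0),
      external_drive = drv)
    tgrid <- seq_len(n) * dt
    list(err = max(abs(x$values - impulse_response(ke, tgrid))),
         peak = max(x$values), integral = sum(x$values) * dt)
  }
  dt1 <- 4 / 4096
  r1 <- run(dt1)
  r2 <- run(dt1 / 2)
  expect_equal(r1$peak, ke$G / exp(1), tolerance = 0.1)
  expect_equal(r1$integral, ke$G / ke$omega, tolerance = 0.05)
  # first-order convergence: error roughly halves when dt halves
  expect_lt(r2$err, 0.7 * r1$err)
  expect_gt(r2$err, 0.3 * r1$err)
  # and the finer run is closer to both analytic summaries
  expect_lt(abs(r2$peak - ke$G / exp(1)), abs(r1$peak - ke$G / exp(1)))
})

test_that("compiled integrator matches the pure-R reference step for step", {
  cfg <- short_cfg(duration = 0.5, burn_in = 0.1)
  n <- round(cfg$duration / cfg$dt)
  n_burn <- round(cfg$burn_in / cfg$dt)
  set.seed(7)
  nz <- rnorm(n, 220, 10)
  ref <- ref_simulate_traditional(nz, cfg$dt, n_burn)
  x <- simulate_traditional(noise = noise_spec(220, 100), cfg = cfg, seed = 7)
  expect_equal(x$values, ref, tolerance = 1e-12)
})

test_that("the Euler trajectory converges to an adaptive ODE solution", {
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, parms) list(region_derivatives(y, 220))
  err <- vapply(c(4 / 4096, 1 / 32768), function(dt) {
    cfg <- sim_config(dt = dt, duration = 0.25, burn_in = 0)
    x <- simulate_traditional(noise = noise_spec(220, 0), cfg = cfg, seed = 1)
    sol <- deSolve::lsoda(numeric(6), times = seq_len(length(x)) * dt,
                          func = rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-10)
    max(abs(x$values - (sol[, 3] - sol[, 4])))
  }, numeric(1))
  # 32x smaller step, ~32x smaller error (first order); allow slack
  expect_lt(err[2], err[1] / 10)
  expect_lt(err[2], 0.1)
})

test_that("simulation output respects length, seeding and zero variance", {
  cfg <- short_cfg()
  x1 <- simulate_traditional(noise = noise_spec(220, 100), cfg = cfg, seed = 3)
  x2 <- simulate_traditional(noise = noise_spec(220, 100), cfg = cfg, seed = 3)
  x3 <- simulate_traditional(noise = noise_spec(220, 100), cfg = cfg, seed = 4)
  expect_identical(x1$values, x2$values)
  expect_false(identical(x1$values, x3$values))
  expect_length(x1, round((cfg$duration - cfg$burn_in) / cfg$dt))
  expect_equal(x1$fs, 1 / cfg$dt)
  # zero variance: deterministic regardless of seed
  d1 <- simulate_traditional(noise = noise_spec(220, 0), cfg = cfg, seed = 1)
  d2 <- simulate_traditional(noise = noise_spec(220, 0), cfg = cfg, seed = 99)
  expect_identical(d1$values, d2$values)
})

test_that("divergent parameters are flagged with the offending step", {
  ke <- synaptic_kernel(3.25, 5000)  # dt*omega > 2: unstable Euler poles
  expect_error(
    simulate_traditional(ke = ke, noise = noise_spec(220, 100),
                         cfg = short_cfg(duration = 1, burn_in = 0), seed = 1),
    "divergence.*step")
})

test_that("alpha rhythm emerges for the stated input regime", {
  hits <- vapply(1:10, function(s) {
    x <- simulate_traditional(noise = noise_spec(220, 75), seed = s)
    ps <- compute_psd(x)
    f <- ps$freqs[which.max(ps$power)]
    f >= 9 && f <= 11
  }, logical(1))
  expect_gte(sum(hits), 8)
})
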