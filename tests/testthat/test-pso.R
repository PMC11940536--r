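test_that("spectrum MSE matches hand arithmetic and resampling rules", {
  f <- 1:3
  expect_identical(spectrum_mse(nmm_spectrum(f, c(1, 2, 3)),
                                nmm_spectrum(f, c(1, 2, 3))), 0)
  expect_equal(spectrum_mse(nmm_spectrum(f, c(1, 2, 3)),
                            nmm_spectrum(f, c(3, 4, 5))), 4)  # offset d^2
  expect_equal(spectrum_mse(nmm_spectrum(f, c(1, 2, 3)),
                            nmm_spectrum(f, c(0, 0, 0))), 14 / 3)
  # linear resampling onto the target grid
  target <- nmm_spectrum(c(1.5, 2.5), c(0, 0))
  model <- nmm_spectrum(1:3, c(2, 4, 8))
  expect_equal(spectrum_mse(target, model), mean(c(3, 6)^2))
  # a model grid not covering the target is an error
  expect_error(spectrum_mse(nmm_spectrum(c(0.5, 1), c(0, 0)), model), "cover")
})

test_that("a lone particle at its own best with zero velocity stays put", {
  cfg <- pso_config(n_particles = 1, n_iters = 1,
                    bounds = cbind(lo = c(-1, -1), hi = c(1, 1)), seed = 1)
  obj <- function(x) sum(x^2)
  set.seed(1)
  swarm <- pso_init(obj, cfg)
  swarm$X[1, ] <- c(0.5, -0.25)
  swarm$pbest <- swarm$X
  swarm$pbest_val <- obj(swarm$X[1, ])
  swarm$gbest <- swarm$X[1, ]
  swarm$gbest_val <- swarm$pbest_val
  out <- pso_step(swarm, obj, cfg)
  expect_equal(out$X[1, ], swarm$X[1, ])
  expect_equal(unname(out$V[1, ]), c(0, 0))
})

test_that("global best is monotone and bounds are respected throughout", {
  b <- cbind(lo = c(-5, -5), hi = c(5, 5))
  obj <- function(x) (x[1] - 1)^2 + 10 * (x[2] + 2)^2
  cfg <- pso_config(n_particles = 15, n_iters = 25, bounds = b, seed = 3)
  set.seed(cfg$seed)
  swarm <- pso_init(obj, cfg)
  g <- swarm$gbest_val
  for (i in 1:25) {
    swarm <- pso_step(swarm, obj, cfg)
    expect_lte(swarm$gbest_val, g)
    g <- swarm$gbest_val
    expect_true(all(swarm$X >= matrix(b[, 1], 15, 2, byrow = TRUE) &
                    swarm$X <= matrix(b[, 2], 15, 2, byrow = TRUE)))
  }
  expect_lt(g, 1e-2)
})

test_that("the sphere benchmark converges at the study swarm settings", {
  vals <- vapply(1:10, function(s) {
    cfg <- pso_config(bounds = cbind(lo = c(-5, -5), hi = c(5, 5)), seed = s)
    fit <- pso_optimize(function(x) sum(x^2), cfg)
    expect_length(fit$trajectory, cfg$n_iters + 1L)
    expect_true(all(diff(fit$trajectory) <= 0))
    fit$value
  }, numeric(1))
  expect_gte(sum(vals < 1e-3), 9)
})

test_that("non-finite objective evaluations are quarantined as +Inf", {
  cfg <- pso_config(n_particles = 8, n_iters = 5,
                    bounds = cbind(lo = -2, hi = 2), seed = 2)
  obj <- function(x) if (x[1] > 0) NaN else x[1]^2
  expect_warning(fit <- pso_optimize(obj, cfg), regexp = NA)
  expect_true(is.finite(fit$value))
})

test_that("fitting only the coupling gains recovers a self-generated spectrum", {
  cfgs <- short_cfg()
  tmpl <- coupled_model_spec(
    occipital = region_params(weights = oscillator_weights(0.10, 0.90, 0)),
    parietal = region_params(weights = oscillator_weights(0.40, 0.30, 0.30)),
    coupling = coupling_params(o_p = 150, p_o = 150), cfg = cfgs)
  target <- compute_psd(simulate_coupled(tmpl, seed = 42)$occipital)
  reduction <- vapply(1:10, function(s) {
    cfg <- pso_config(n_particles = 12, n_iters = 10,
                      bounds = cbind(lo = c(0, 0), hi = c(400, 400)), seed = s)
    fit <- fit_model(target, tmpl, free = c("o_p", "p_o"), cfg = cfg)
    expect_length(fit$trajectory, 11L)
    expect_true(all(diff(fit$trajectory) <= 0))
    fit$value / fit$trajectory[1]
  }, numeric(1))
  expect_lte(median(reduction), 0.5)
})

test_that("an empty free set returns the template objective untouched", {
  cfgs <- short_cfg(duration = 1, burn_in = 0.25)
  tmpl <- coupled_model_spec(cfg = cfgs)
  target <- compute_psd(simulate_coupled(tmpl, seed = 8)$occipital)
  fit <- fit_model(target, tmpl, free = character(0),
                   cfg = pso_config(seed = 8), sim_seed = 77)
  expect_identical(fit$n_evals, 1L)
  expect_length(fit$trajectory, 1L)
  # the value equals the directly computed template MSE at the same seed
  direct <- spectrum_mse(target,
                         compute_psd(simulate_coupled(tmpl, seed = 77)$occipital))
  expect_equal(fit$value, direct)
})

test_that("softmax weight logits stay on the simplex when fitted", {
  spec <- coupled_model_spec()
  th <- c(eta_o_delta = 1, eta_o_alpha = 0.5, eta_o_gamma = -2)
  out <- ssvepnmm:::apply_theta(spec, th)
  w <- out$occipital$weights
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
  expect_gt(w[[1]], w[[2]])  # larger logit, larger weight
})
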