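test_that("coupling signal follows gain * S(x - running mean)", {
  st <- region_state()
  w <- oscillator_weights()
  sg <- sigmoid_params()
  expect_identical(coupling_signal(st, w, gain = 0), 0)
  # constant signal history: RM(x) = 0, so the drive is gain * S(0)
  expect_equal(coupling_signal(st, w, gain = 200),
               200 * 5 / (1 + exp(0.56 * 6)), tolerance = 1e-12)
  expect_equal(coupling_signal(st, w, gain = 200), 33.57,
               tolerance = 1e-3)
  # linear in the gain
  st2 <- region_state(y = rbind(c(0, 0, 0), c(3, 3, 3), c(1, 1, 1)))
  expect_equal(coupling_signal(st2, w, gain = 400, history_mean = 1),
               2 * coupling_signal(st2, w, gain = 200, history_mean = 1))
})

test_that("zero coupling factorizes into two independent region runs", {
  cfg <- short_cfg()
  spec <- coupled_model_spec(
    occipital = region_params(weights = oscillator_weights(0.1, 0.9, 0)),
    parietal = region_params(weights = oscillator_weights(0.4, 0.3, 0.3)),
    coupling = coupling_params(o_p = 0, p_o = 0), cfg = cfg)
  out <- simulate_coupled(spec, seed = 9)
  sub <- derive_subseeds(9, 2)
  occ <- simulate_region(spec$occipital, cfg = cfg, seed = sub[1])
  par <- simulate_region(spec$parietal, cfg = cfg, seed = sub[2])
  expect_identical(out$occipital$values, occ$values)
  expect_identical(out$parietal$values, par$values)
})

test_that("relabelling regions, gains and sub-seeds swaps outputs exactly", {
  cfg <- short_cfg(duration = 1, burn_in = 0.25)
  po <- region_params(weights = oscillator_weights(0.1, 0.9, 0),
                      noise = noise_spec(220, 100))
  pp <- region_params(weights = oscillator_weights(0.4, 0.3, 0.3),
                      noise = noise_spec(200, 50))
  a <- simulate_coupled(coupled_model_spec(po, pp,
         coupling_params(o_p = 120, p_o = 60), cfg), seed = c(101, 202))
  b <- simulate_coupled(coupled_model_spec(pp, po,
         coupling_params(o_p = 60, p_o = 120), cfg), seed = c(202, 101))
  expect_identical(a$occipital$values, b$parietal$values)
  expect_identical(a$parietal$values, b$occipital$values)
})

test_that("coupled outputs share length and rate and obey the seed", {
  spec <- coupled_model_spec(cfg = short_cfg(duration = 1, burn_in = 0.25))
  o1 <- simulate_coupled(spec, seed = 4)
  o2 <- simulate_coupled(spec, seed = 4)
  expect_identical(o1$occipital$values, o2$occipital$values)
  expect_identical(length(o1$occipital), length(o1$parietal))
  expect_identical(o1$occipital$fs, o1$parietal$fs)
})

test_that("divergence in the coupled model names the region", {
  bad_bank <- kernel_bank(
    excitatory = list(delta = synaptic_kernel(3.25, 20),
                      alpha = synaptic_kernel(3.25, 5000),
                      gamma = synaptic_kernel(13, 400)),
    inhibitory = kernel_bank()$inhibitory)
  spec <- coupled_model_spec(
    parietal = region_params(bank = bad_bank),
    cfg = short_cfg(duration = 1, burn_in = 0))
  expect_error(simulate_coupled(spec, seed = 1), "parietal.*step")
})

test_that("unidirectional parietal drive raises occipital amplitude, not frequency", {
  tab <- sweep_coupling_unidirectional(p_o_values = c(0, 100, 200), seeds = 1:10)
  expect_true(all(diff(tab$rms) > 0))
  bin <- 1 / 3  # 3 s analysed at 1024 Hz
  expect_true(all(abs(tab$argmax_hz - tab$argmax_hz[1]) <= bin + 1e-9))
})

test_that("bidirectional coupling to a delta-heavy parietal region lowers the occipital centroid", {
  tab <- sweep_coupling_bidirectional(gain_values = c(0, 100, 200), seeds = 1:10)
  expect_true(all(diff(tab$centroid_hz) < 0))
})

test_that("a conduction delay changes the trajectory but not determinism", {
  cfg <- short_cfg(duration = 1, burn_in = 0.25)
  base <- coupled_model_spec(coupling = coupling_params(o_p = 100, p_o = 100),
                             cfg = cfg)
  lag <- coupled_model_spec(coupling = coupling_params(o_p = 100, p_o = 100,
                                                       delay = 10L), cfg = cfg)
  x <- simulate_coupled(base, seed = 6)
  y <- simulate_coupled(lag, seed = 6)
  z <- simulate_coupled(lag, seed = 6)
  expect_false(identical(x$occipital$values, y$occipital$values))
  expect_identical(y$occipital$values, z$occipital$values)
})
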