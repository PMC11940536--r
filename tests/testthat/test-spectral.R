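test_that("periodogram localizes a pure tone and kills a constant", {
  fs <- 1024
  tt <- (0:4095) / fs
  s <- compute_psd(nmm_ts(sin(2 * pi * 10 * tt), fs = fs))
  expect_equal(s$freqs[which.max(s$power)], 10)
  s0 <- compute_psd(nmm_ts(rep(3.7, 256), fs = fs))
  expect_true(all(s0$power == 0))
  expect_error(compute_psd(nmm_ts(1, fs = fs)), "at least 2")
})

test_that("periodogram satisfies Parseval against the population variance", {
  for (n in c(255, 256, 1024)) {
    set.seed(n)
    v <- rnorm(n, sd = 2)
    s <- compute_psd(v, fs = 100)
    df <- 100 / n
    expect_equal(sum(s$power) * df, mean((v - mean(v))^2),
                 tolerance = 1e-6)
  }
})

test_that("periodogram equals a brute-force DFT and spec.pgram cross-checks", {
  set.seed(42)
  v <- rnorm(64)
  s <- compute_psd(v, fs = 32)
  ref <- ref_psd(v, fs = 32)
  expect_equal(s$freqs, ref$freqs)
  expect_equal(s$power, ref$power, tolerance = 1e-9)
  # independent library periodogram: identical bin ordering up to its
  # one-sided normalization (it drops DC and divides by fs differently)
  sp <- stats::spec.pgram(stats::ts(v, frequency = 32), taper = 0,
                          fast = FALSE, detrend = FALSE, plot = FALSE)
  keep <- s$freqs > 0 & s$freqs < 16
  ratio <- s$power[keep] / sp$spec[match(round(s$freqs[keep], 9),
                                         round(sp$freq, 9))]
  expect_lt(stats::sd(ratio) / mean(ratio), 1e-9)
})

test_that("band energies match a naive per-bin loop on random spectra", {
  bt <- band_table()
  for (rep in 1:5) {
    set.seed(rep)
    s <- random_spectrum()
    e <- band_energies(s)
    manual <- sapply(seq_len(nrow(bt)), function(i) {
      tot <- 0
      for (j in seq_along(s$freqs))
        if (s$freqs[j] >= bt$lo[i] && s$freqs[j] < bt$hi[i])
          tot <- tot + s$power[j]
      tot
    })
    expect_equal(unname(e), manual)
  }
  expect_error(band_energies(nmm_spectrum(seq(0, 30), runif(31))), "cover")
})

test_that("flat and concentrated spectra give the expected band split", {
  flat <- nmm_spectrum(seq(0, 64, by = 0.5), rep(2, 129))
  e <- band_energies(flat)
  expect_equal(unname(e / sum(e)), c(4, 4, 8, 16, 32) / 64)
  spike <- nmm_spectrum(seq(0, 64, by = 0.5), c(rep(0, 20), 5, rep(0, 108)))
  es <- band_energies(spike)  # 10 Hz bin
  expect_equal(unname(es), c(0, 0, 5, 0, 0))
})

test_that("identified weights are the delta/alpha/gamma energy ratios", {
  flat <- nmm_spectrum(seq(0, 64, by = 0.5), rep(1, 129))
  w <- identify_weights(flat)
  expect_equal(as.numeric(w), c(4, 8, 32) / 44, tolerance = 1e-12)
  spike <- nmm_spectrum(seq(0, 64, by = 0.5), c(rep(0, 20), 5, rep(0, 108)))
  expect_equal(as.numeric(identify_weights(spike)), c(0, 1, 0))
  theta_only <- nmm_spectrum(seq(0, 64, by = 0.5), c(rep(0, 10), 3, rep(0, 118)))
  expect_error(identify_weights(theta_only), "zero total energy")
})

test_that("identified weights satisfy the simplex constraints on random spectra", {
  set.seed(123)
  for (i in 1:100) {
    w <- identify_weights(random_spectrum())
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("dominant frequency accepts near peaks and rejects far ones", {
  fs <- 1024
  tt <- (0:4095) / fs
  s11 <- compute_psd(nmm_ts(sin(2 * pi * 11 * tt) + 0.1 * rnorm(4096), fs))
  expect_equal(dominant_frequency(s11, c(10, 11, 12), tol = 0.5), 11)
  s12 <- compute_psd(nmm_ts(sin(2 * pi * 12 * tt), fs))
  expect_equal(dominant_frequency(s12, c(10, 11, 12), tol = 0.5), 12)
  # broadband noise rarely peaks within 0.1 Hz of a candidate
  rejections <- vapply(1:20, function(s) {
    set.seed(s)
    ps <- compute_psd(nmm_ts(rnorm(4096), fs))
    is.na(dominant_frequency(ps, c(10, 11, 12), tol = 0.1))
  }, logical(1))
  expect_gte(sum(rejections), 15)
})

test_that("spectral centroid weighs frequencies by power", {
  s <- nmm_spectrum(c(5, 10, 20), c(1, 2, 1))
  expect_equal(spectral_centroid(s), (5 + 20 + 10 * 2) / 4)
  expect_equal(spectral_centroid(s, fmin = 8, fmax = 16), 10)
})
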