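# Shared fixtures: short simulation configs and a pure-R reference
# integrator of the traditional model (independent of the compiled path).

short_cfg <- function(duration = 2, burn_in = 0.5) {
  sim_config(duration = duration, burn_in = burn_in)
}

# Reference Euler integrator for the traditional model, written against
# region_derivatives() only; same stepping convention as the package
# (record output after each update).
ref_simulate_traditional <- function(noise_vec, dt, n_burn,
                                     ke = synaptic_kernel(3.25, 100),
                                     ki = synaptic_kernel(22, 50, "inhibitory"),
                                     sg = sigmoid_params(),
                                     cc = connectivity_constants()) {
  state <- numeric(6)
  out <- numeric(length(noise_vec) - n_burn)
  for (i in seq_along(noise_vec)) {
    d <- region_derivatives(state, noise_vec[i], sigmoid = sg,
                            ke = ke, ki = ki, connectivity = cc)
    state <- state + dt * d
    if (i > n_burn) out[i - n_burn] <- state[2] - state[3]
  }
  out
}

# Brute-force one-sided periodogram by direct DFT summation (O(n^2)),
# normalized like compute_psd: density with Parseval against the
# population variance.
ref_psd <- function(v, fs) {
  n <- length(v)
  v <- v - mean(v)
  half <- floor(n / 2) + 1L
  p <- numeric(half)
  for (k in seq_len(half)) {
    m <- k - 1L
    re <- sum(v * cos(-2 * pi * m * (seq_len(n) - 1L) / n))
    im <- sum(v * sin(-2 * pi * m * (seq_len(n) - 1L) / n))
    p[k] <- (re^2 + im^2) / n^2
  }
  if (n %% 2 == 0) {
    if (half > 2L) p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
  } else {
    p[2:half] <- 2 * p[2:half]
  }
  df <- fs / n
  list(freqs = (seq_len(half) - 1L) * df, power = p / df)
}

random_spectrum <- function(n = 129, fmax = 64) {
  nmm_spectrum(seq(0, fmax, length.out = n), runif(n, 0, 10))
}
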