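#' Surrogate SSVEP specification
#'
#' A synthetic stand-in for stimulus-locked SSVEP recordings (which are
#' not publicly deposited): a fundamental plus its second and third
#' harmonics with random phases, on top of 1/f^beta colored broadband
#' noise. Band energies are exactly controllable, which is what the
#' weight-identification and demo pipelines need.
#'
#' @param f0 Stimulus frequency (Hz), e.g. 10, 11 or 12.
#' @param harmonic_amps Amplitudes (mV) of f0, 2 f0, 3 f0.
#' @param noise_exponent Spectral slope beta of the 1/f^beta noise.
#' @param noise_power Variance of the broadband noise component (mV^2).
#' @param duration Signal duration (s).
#' @param fs Sampling rate (Hz); must exceed twice the third harmonic.
#' @param seed RNG seed.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(f0 = 10, harmonic_amps = c(1, 0.5, 0.25),
                           noise_exponent = 1, noise_power = 0.5,
                           duration = 4, fs = 1024, seed = 1) {
  stopifnot(f0 > 0, length(harmonic_amps) == 3L, all(harmonic_amps >= 0),
            noise_power >= 0, duration > 0, fs > 2 * 3 * f0)
  structure(list(f0 = f0, harmonic_amps = harmonic_amps,
                 noise_exponent = noise_exponent, noise_power = noise_power,
                 duration = duration, fs = fs, seed = seed),
            class = "surrogate_spec")
}

#' Generate a surrogate SSVEP signal
#'
#' Sum of harmonic sinusoids (uniform random phases) plus colored noise
#' synthesized by spectral shaping of white Gaussian noise (amplitude
#' scaled by f^(-beta/2), DC removed, variance renormalized to
#' `noise_power`). Seed-deterministic.
#'
#' @param spec A [surrogate_spec()].
#' @return An [nmm_ts()] of `round(duration * fs)` samples.
#' @examples
#' x <- generate_surrogate(surrogate_spec(f0 = 11, seed = 2))
#' s <- compute_psd(x)
#' dominant_frequency(s, c(10, 11, 12))  # 11
#' @export
generate_surrogate <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  tt <- (seq_len(n) - 1L) / spec$fs
  v <- numeric(n)
  for (h in 1:3) {
    if (spec$harmonic_amps[h] > 0) {
      phi <- runif(1, 0, 2 * pi)
      v <- v + spec$harmonic_amps[h] * sin(2 * pi * h * spec$f0 * tt + phi)
    }
  }
  if (spec$noise_power > 0) {
    w <- rnorm(n)
    W <- fft(w)
    f <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L))) * spec$fs / n
    shape <- c(0, f[-1]^(-spec$noise_exponent / 2))
    cn <- Re(fft(W * shape, inverse = TRUE)) / n
    cn <- cn - mean(cn)
    cn <- cn * sqrt(spec$noise_power / mean(cn^2))
    v <- v + cn
  }
  structure(nmm_ts(v, fs = spec$fs), seed = spec$seed, f0 = spec$f0)
}
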