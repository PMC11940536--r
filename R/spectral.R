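#' Power spectrum container
#'
#' A one-sided power spectral density on a strictly increasing frequency
#' grid; the currency of oscillator-weight identification and of the
#' swarm-fitting objective.
#'
#' @param freqs Strictly increasing frequencies (Hz).
#' @param power Nonnegative PSD values, same length.
#' @return An object of class `nmm_spectrum`.
#' @export
nmm_spectrum <- function(freqs, power) {
  stopifnot(is.numeric(freqs), is.numeric(power),
            length(freqs) == length(power), length(freqs) >= 1L,
            all(is.finite(freqs)), all(is.finite(power)),
            all(diff(freqs) > 0), all(power >= 0))
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power)),
            class = "nmm_spectrum")
}

#' @export
print.nmm_spectrum <- function(x, ...) {
  i <- which.max(x$power)
  cat(sprintf("<nmm_spectrum> %d bins, %.3g-%.4g Hz (df=%.4g), peak %.4g at %.4g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              stats::median(diff(x$freqs)), x$power[i], x$freqs[i]))
  invisible(x)
}

#' One-sided periodogram PSD
#'
#' Plain rectangular-window periodogram of the de-meaned signal. The PSD
#' is a density (units mV^2/Hz) on the grid `0, fs/N, ..., fs/2`, scaled
#' so that `sum(power) * (fs/N)` equals the population variance of the
#' signal (Parseval).
#'
#' @param x An [nmm_ts()] object (or numeric vector with `fs` given).
#' @param fs Sampling rate (Hz), required when `x` is a bare vector.
#' @return An [nmm_spectrum()].
#' @examples
#' x <- nmm_ts(sin(2 * pi * 10 * (0:4095) / 1024), fs = 1024)
#' s <- compute_psd(x)
#' s$freqs[which.max(s$power)]  # 10
#' @export
compute_psd <- function(x, fs = NULL) {
  if (inherits(x, "nmm_ts")) {
    fs <- x$fs
    v <- x$values
  } else {
    stopifnot(is.numeric(x), !is.null(fs))
    v <- as.numeric(x)
  }
  n <- length(v)
  if (n < 2L) stop("need at least 2 samples for a periodogram")
  v <- v - mean(v)
  X <- fft(v)
  two_sided <- (Mod(X)^2) / n^2           # sums to the population variance
  half <- floor(n / 2) + 1L               # DC .. Nyquist (or near-Nyquist)
  p <- two_sided[seq_len(half)]
  # fold negative frequencies into the positive half
  if (n %% 2 == 0) {
    if (half > 2L) p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
  } else {
    if (half > 1L) p[2:half] <- 2 * p[2:half]
  }
  df <- fs / n
  nmm_spectrum(freqs = (seq_len(half) - 1L) * df, power = p / df)
}

#' EEG sub-band table
#'
#' The five contiguous half-open sub-bands used for band-energy analysis:
#' delta \[0,4), theta \[4,8), alpha \[8,16), beta \[16,32) and gamma
#' \[32,64) Hz. Half-open intervals make the shared printed boundaries
#' (4, 16, 32 Hz) unambiguous.
#'
#' @return A data.frame with columns `band`, `lo`, `hi`.
#' @export
band_table <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(0, 4, 8, 16, 32),
             hi = c(4, 8, 16, 32, 64),
             stringsAsFactors = FALSE)
}

#' Band energies of a spectrum
#'
#' Sums the PSD bins whose frequency falls in each half-open band
#' `[lo, hi)`.
#'
#' @param s An [nmm_spectrum()] covering all requested bands.
#' @param bands A band table as returned by [band_table()].
#' @return Named numeric vector of nonnegative band energies.
#' @export
band_energies <- function(s, bands = band_table()) {
  stopifnot(inherits(s, "nmm_spectrum"),
            all(c("band", "lo", "hi") %in% names(bands)))
  df <- stats::median(diff(s$freqs))
  if (min(s$freqs) > min(bands$lo) || max(s$freqs) < max(bands$hi) - df - 1e-9)
    stop("spectrum grid does not cover the requested bands (need ~[",
         min(bands$lo), ", ", max(bands$hi), ") Hz)")
  e <- vapply(seq_len(nrow(bands)), function(i) {
    sum(s$power[s$freqs >= bands$lo[i] & s$freqs < bands$hi[i]])
  }, 0)
  names(e) <- bands$band
  e
}

#' Identify oscillator weights from a spectrum
#'
#' Band-energy weight identification: the delta, alpha and gamma band
#' energies are normalized by their three-band total, giving weights on
#' the unit simplex (each in \[0,1\], summing to exactly 1 after
#' renormalization). Theta and beta energies are computed but excluded by
#' construction.
#'
#' @param s An [nmm_spectrum()] covering \[0, 64) Hz.
#' @return An [oscillator_weights()] object.
#' @examples
#' s <- nmm_spectrum(seq(0, 64, by = 0.5), rep(1, 129))  # flat spectrum
#' identify_weights(s)  # ~ (4/44, 8/44, 32/44)
#' @export
identify_weights <- function(s) {
  e <- band_energies(s)
  tot <- e[["delta"]] + e[["alpha"]] + e[["gamma"]]
  if (tot <= 0)
    stop("zero total energy in the delta/alpha/gamma bands; weights undefined")
  oscillator_weights(e[["delta"]] / tot, e[["alpha"]] / tot, e[["gamma"]] / tot)
}

#' Dominant-frequency classifier
#'
#' Picks the candidate stimulus frequency nearest to the global PSD
#' argmax, provided it lies within `tol`; otherwise returns `NA` (no
#' decision). Used by the demo pipeline in place of a trained classifier.
#'
#' @param s An [nmm_spectrum()].
#' @param candidates Candidate stimulus frequencies (Hz), non-empty.
#' @param tol Acceptance tolerance (Hz).
#' @return The chosen candidate frequency, or `NA_real_`.
#' @export
dominant_frequency <- function(s, candidates, tol = 0.5) {
  stopifnot(inherits(s, "nmm_spectrum"), length(candidates) >= 1L,
            is.numeric(candidates), tol >= 0)
  f_peak <- s$freqs[which.max(s$power)]
  i <- which.min(abs(candidates - f_peak))
  if (abs(candidates[i] - f_peak) <= tol) candidates[i] else NA_real_
}

#' Spectral centroid
#'
#' Power-weighted mean frequency `sum(f * P) / sum(P)`, optionally
#' restricted to a frequency window; the summary used for the weight- and
#' coupling-sweep trend analyses.
#'
#' @param s An [nmm_spectrum()].
#' @param fmin,fmax Window bounds (Hz); bins with `fmin <= f < fmax`.
#' @return Centroid frequency (Hz).
#' @export
spectral_centroid <- function(s, fmin = 0, fmax = 64) {
  stopifnot(inherits(s, "nmm_spectrum"))
  i <- s$freqs >= fmin & s$freqs < fmax
  if (!any(i) || sum(s$power[i]) <= 0) stop("no power in the requested window")
  sum(s$freqs[i] * s$power[i]) / sum(s$power[i])
}
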