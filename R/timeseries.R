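#' EEG-like time series
#'
#' A regularly sampled amplitude series with its sampling rate, the common
#' currency of the simulators, the spectral tools and the augmentation
#' operators.
#'
#' @param values Numeric vector of amplitudes (mV).
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample (s); simulators set this to the
#'   burn-in so time stamps line up with simulated time.
#' @return An object of class `nmm_ts`.
#' @examples
#' x <- nmm_ts(sin(2 * pi * 10 * seq(0, 1, by = 1 / 256)), fs = 256)
#' ts_time(x)[1:3]
#' @export
nmm_ts <- function(values, fs, t0 = 0) {
  stopifnot(is.numeric(values), length(values) >= 1L,
            is.numeric(fs), length(fs) == 1L, is.finite(fs), fs > 0,
            is.numeric(t0), length(t0) == 1L, is.finite(t0))
  structure(list(values = as.numeric(values), fs = fs, t0 = t0),
            class = "nmm_ts")
}

#' @describeIn nmm_ts time stamps (s) of each sample.
#' @param x An `nmm_ts` object.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "nmm_ts"))
  x$t0 + (seq_along(x$values) - 1L) / x$fs
}

#' @export
print.nmm_ts <- function(x, ...) {
  cat(sprintf("<nmm_ts> %d samples @ %g Hz (%.3f s), range [%.3g, %.3g] mV\n",
              length(x$values), x$fs, length(x$values) / x$fs,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.nmm_ts <- function(x) length(x$values)

#' @export
as.data.frame.nmm_ts <- function(x, ...) {
  data.frame(time_s = ts_time(x), amplitude_mV = x$values)
}

#' Root-mean-square amplitude of a time series
#'
#' @param x An [nmm_ts()] object or numeric vector.
#' @return RMS amplitude (mV).
#' @export
ts_rms <- function(x) {
  v <- if (inherits(x, "nmm_ts")) x$values else x
  sqrt(mean(v^2))
}
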