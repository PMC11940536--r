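#' Augmentation configuration
#'
#' Settings of the five stochastic signal-augmentation operators: circular
#' signal shifting, smooth amplitude distortion, temporal masking, global
#' scale transformation and additive Gaussian noise. Defaults are
#' conservative, label-preserving perturbations expressed relative to the
#' sampling rate and signal RMS.
#'
#' @param max_shift Maximum circular shift (samples); `NULL` = `fs/10`.
#' @param amp_distortion_range Multiplicative envelope range.
#' @param mask_len_range Masking window length range (samples);
#'   `NULL` = `[fs/20, fs/5]`.
#' @param scale_range Global gain range.
#' @param noise_sigma Additive noise standard deviation (mV); `NULL` = 5%
#'   of the signal's RMS, computed per signal.
#' @param ops_per_sample Augmentations generated per input sample
#'   (the study used 100).
#' @param compose_all If `TRUE` each augmentation applies all five
#'   operators in sequence instead of one sampled uniformly.
#' @param seed Seed used by [augment_dataset()].
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(max_shift = NULL,
                           amp_distortion_range = c(0.8, 1.2),
                           mask_len_range = NULL,
                           scale_range = c(0.7, 1.3),
                           noise_sigma = NULL,
                           ops_per_sample = 100,
                           compose_all = FALSE,
                           seed = 1) {
  stopifnot(length(amp_distortion_range) == 2L,
            amp_distortion_range[1] <= amp_distortion_range[2],
            length(scale_range) == 2L, scale_range[1] <= scale_range[2],
            ops_per_sample >= 1)
  if (!is.null(mask_len_range))
    stopifnot(length(mask_len_range) == 2L,
              mask_len_range[1] <= mask_len_range[2], mask_len_range[1] >= 1)
  structure(list(max_shift = max_shift,
                 amp_distortion_range = amp_distortion_range,
                 mask_len_range = mask_len_range,
                 scale_range = scale_range,
                 noise_sigma = noise_sigma,
                 ops_per_sample = as.integer(ops_per_sample),
                 compose_all = isTRUE(compose_all),
                 seed = seed),
            class = "augment_config")
}

augment_operators <- c("shift", "amplitude", "mask", "scale", "noise")

# Resolve fs/RMS-relative defaults against a concrete signal.
resolve_augment_cfg <- function(cfg, x) {
  fs <- x$fs
  if (is.null(cfg$max_shift)) cfg$max_shift <- max(1L, round(fs / 10))
  if (is.null(cfg$mask_len_range))
    cfg$mask_len_range <- c(max(1L, round(fs / 20)), max(1L, round(fs / 5)))
  if (is.null(cfg$noise_sigma)) cfg$noise_sigma <- 0.05 * ts_rms(x)
  cfg
}

# uniform integer in [lo, hi]; sample() on a length-1 vector would
# misread it as a population size
rint <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1L)

apply_operator <- function(x, op, cfg) {
  v <- x$values
  n <- length(v)
  v <- switch(op,
    shift = {
      u <- rint(-cfg$max_shift, cfg$max_shift)
      if (u == 0) v else {
        k <- ((seq_len(n) - 1L - u) %% n) + 1L
        v[k]
      }
    },
    amplitude = {
      # smooth sinusoidal gain envelope confined to the distortion range
      ctr <- mean(cfg$amp_distortion_range)
      amp <- runif(1, 0, diff(cfg$amp_distortion_range) / 2)
      f_env <- runif(1, 0.5, 2)
      phi <- runif(1, 0, 2 * pi)
      tt <- (seq_len(n) - 1L) / x$fs
      v * (ctr + amp * sin(2 * pi * f_env * tt + phi))
    },
    mask = {
      L <- rint(cfg$mask_len_range[1], cfg$mask_len_range[2])
      if (L > n) stop("mask window (", L, ") longer than signal (", n, ")")
      i <- rint(1L, n - L + 1L)
      v[i:(i + L - 1L)] <- 0
      v
    },
    scale = v * runif(1, cfg$scale_range[1], cfg$scale_range[2]),
    noise = v + rnorm(n, 0, cfg$noise_sigma),
    stop("unknown operator: ", op))
  out <- nmm_ts(v, fs = x$fs, t0 = x$t0)
  attr(out, "label") <- attr(x, "label")
  out
}

#' Apply one random augmentation
#'
#' Applies one operator sampled uniformly from the five (or all five in
#' sequence when `cfg$compose_all` is set) using the current RNG state.
#' Output length always equals input length.
#'
#' @param x An [nmm_ts()] object.
#' @param cfg An [augment_config()].
#' @param op Force a specific operator (`"shift"`, `"amplitude"`,
#'   `"mask"`, `"scale"`, `"noise"`) instead of sampling.
#' @return An augmented [nmm_ts()]; any `label` attribute is preserved,
#'   and the operator(s) applied are recorded in attribute `operator`.
#' @export
augment_once <- function(x, cfg = augment_config(), op = NULL) {
  stopifnot(inherits(x, "nmm_ts"), inherits(cfg, "augment_config"),
            length(x) >= 1L)
  cfg <- resolve_augment_cfg(cfg, x)
  ops <- if (!is.null(op)) match.arg(op, augment_operators)
         else if (cfg$compose_all) augment_operators
         else sample(augment_operators, 1L)
  out <- x
  for (o in ops) out <- apply_operator(out, o, cfg)
  attr(out, "operator") <- ops
  out
}

#' Augment a dataset of signals
#'
#' Expands each input signal into `ops_per_sample` random augmentations
#' (e.g. 270 inputs x 100 operations = 27,000 outputs), deterministically
#' under `cfg$seed`. Label attributes are carried over.
#'
#' @param samples A list of [nmm_ts()] objects.
#' @param cfg An [augment_config()].
#' @return A list of `length(samples) * ops_per_sample` augmented signals;
#'   attribute `manifest` is a data.frame mapping each output to its
#'   source index and operator(s).
#' @export
augment_dataset <- function(samples, cfg = augment_config()) {
  stopifnot(is.list(samples), length(samples) >= 1L,
            all(vapply(samples, inherits, TRUE, "nmm_ts")))
  set.seed(cfg$seed)
  out <- vector("list", length(samples) * cfg$ops_per_sample)
  src <- integer(length(out))
  opn <- character(length(out))
  j <- 0L
  for (i in seq_along(samples)) {
    for (k in seq_len(cfg$ops_per_sample)) {
      j <- j + 1L
      out[[j]] <- augment_once(samples[[i]], cfg)
      src[j] <- i
      opn[j] <- paste(attr(out[[j]], "operator"), collapse = "+")
    }
  }
  attr(out, "manifest") <- data.frame(output = seq_along(out), source = src,
                                      operator = opn, stringsAsFactors = FALSE)
  out
}
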