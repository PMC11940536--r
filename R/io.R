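#' Write/read a time series as delimited text
#'
#' Two tab-separated columns `time_s` and `amplitude_mV` with a one-line
#' header. A JSON sidecar (`<path>.json`) records the sampling rate, the
#' seed (if attached) and a parameter hash so that runs can be traced.
#'
#' @param x An [nmm_ts()] object.
#' @param path Output file path.
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, sidecar = TRUE) {
  stopifnot(inherits(x, "nmm_ts"))
  write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  if (sidecar) {
    meta <- list(fs = x$fs, t0 = x$t0, n = length(x),
                 seed = attr(x, "seed"),
                 params_hash = params_hash(attr(x, "cfg")))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null", digits = NA)
  }
  invisible(path)
}

#' @rdname write_timeseries
#' @param fs Sampling rate override; by default it is recovered from the
#'   time stamps (or the sidecar, if present).
#' @export
read_timeseries <- function(path, fs = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (ncol(df) < 2L) stop("expected 2 columns (time_s, amplitude_mV)")
  if (is.null(fs)) {
    dtm <- stats::median(diff(df[[1]]))
    if (!is.finite(dtm) || dtm <= 0) stop("cannot infer sampling rate")
    fs <- 1 / dtm
  }
  nmm_ts(df[[2]], fs = fs, t0 = df[[1]][1])
}

#' Write/read a spectrum as delimited text
#'
#' Two tab-separated columns `freq_Hz` and `psd` with a one-line header.
#'
#' @param s An [nmm_spectrum()] object.
#' @param path File path.
#' @return `path` (write) or an [nmm_spectrum()] (read).
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "nmm_spectrum"))
  write.table(data.frame(freq_Hz = s$freqs, psd = s$power), path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  nmm_spectrum(df[[1]], df[[2]])
}

#' Write a coupled output as 3-column delimited text
#'
#' Columns `time_s`, `occipital_mV`, `parietal_mV`.
#'
#' @param out A `coupled_output` from [simulate_coupled()].
#' @param path File path.
#' @export
write_coupled_output <- function(out, path) {
  stopifnot(inherits(out, "coupled_output"))
  df <- data.frame(time_s = ts_time(out$occipital),
                   occipital_mV = out$occipital$values,
                   parietal_mV = out$parietal$values)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stable hash of a parameter object
#'
#' MD5 of the canonical JSON serialization; used in sidecars and run
#' manifests so outputs can be matched to the exact configuration that
#' produced them.
#'
#' @param x Any R object (lists of parameters, specs); `NULL` gives `NA`.
#' @return A character MD5 digest, or `NA_character_`.
#' @export
params_hash <- function(x) {
  if (is.null(x)) return(NA_character_)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass_deep(x), tf, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(x, unclass_deep) else if (is.object(x)) unclass(x) else x
}

#' Read a region or coupled-model configuration from YAML/JSON
#'
#' The schema mirrors the constructor arguments: top-level blocks
#' `occipital`, `parietal`, `coupling`, `cfg` (coupled model) or the
#' single-region blocks `sigmoid`, `bank`, `weights`, `connectivity`,
#' `noise`. Kernels are given as `{G, omega}` pairs under
#' `bank$excitatory/inhibitory$delta/alpha/gamma`; weights as
#' `{w_delta, w_alpha, w_gamma}`. Omitted blocks fall back to package
#' defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A [region_params()] or [coupled_model_spec()], depending on the
#'   top-level keys.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$occipital) || !is.null(cfg$parietal)) {
    coupled_model_spec(
      occipital = region_params_from_list(cfg$occipital),
      parietal = region_params_from_list(cfg$parietal),
      coupling = coupling_params_from_list(cfg$coupling),
      cfg = sim_config_from_list(cfg$cfg))
  } else {
    region_params_from_list(cfg)
  }
}

region_params_from_list <- function(x) {
  if (is.null(x)) return(region_params())
  region_params(
    sigmoid = if (is.null(x$sigmoid)) sigmoid_params()
              else do.call(sigmoid_params, x$sigmoid),
    bank = bank_from_list(x$bank),
    weights = if (is.null(x$weights)) oscillator_weights()
              else do.call(oscillator_weights, as.list(x$weights)),
    connectivity = if (is.null(x$connectivity)) connectivity_constants()
                   else do.call(connectivity_constants, x$connectivity),
    noise = if (is.null(x$noise)) noise_spec()
            else do.call(noise_spec, x$noise))
}

bank_from_list <- function(x) {
  if (is.null(x)) return(kernel_bank())
  mk <- function(side, pol) {
    defaults <- kernel_bank()[[side]]
    out <- lapply(c("delta", "alpha", "gamma"), function(b) {
      k <- x[[side]][[b]]
      if (is.null(k)) defaults[[b]]
      else synaptic_kernel(k$G, k$omega, pol)
    })
    names(out) <- c("delta", "alpha", "gamma")
    out
  }
  kernel_bank(mk("excitatory", "excitatory"), mk("inhibitory", "inhibitory"))
}

coupling_params_from_list <- function(x) {
  if (is.null(x)) return(coupling_params())
  coupling_params(
    o_p = x$o_p %||% 0, p_o = x$p_o %||% 0,
    encoder_bank = if (is.null(x$encoder_bank)) NULL
                   else bank_from_list(x$encoder_bank),
    encoder_weights = if (is.null(x$encoder_weights)) NULL
                      else do.call(oscillator_weights,
                                   as.list(x$encoder_weights)),
    delay = x$delay %||% 0L,
    rm_mode = x$rm_mode %||% "running",
    rm_fixed = unlist(x$rm_fixed %||% c(0, 0)))
}

sim_config_from_list <- function(x) {
  if (is.null(x)) return(sim_config())
  sim_config(dt = x$dt %||% 4 / 4096, duration = x$duration %||% 4,
             burn_in = x$burn_in %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' JSON record of a command-line (or scripted) run: subcommand, arguments,
#' seed, package version and configuration hash — enough to reproduce the
#' outputs bit for bit.
#'
#' @param path Manifest file path.
#' @param subcommand Name of the operation.
#' @param args Named list of arguments as given.
#' @param seed The seed used.
#' @param outputs Character vector of files written.
#' @param config Optional parameter object to hash.
#' @export
write_manifest <- function(path, subcommand, args, seed, outputs,
                           config = NULL) {
  m <- list(subcommand = subcommand, args = args, seed = seed,
            outputs = outputs,
            config_hash = params_hash(config),
            package = "ssvepnmm",
            version = as.character(utils::packageVersion("ssvepnmm")))
  jsonlite::write_json(m, path, auto_unbox = TRUE, null = "null",
                       digits = NA, force = TRUE)
  invisible(path)
}
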