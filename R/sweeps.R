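#' Parameter sweep summaries
#'
#' Figure-ready tables summarizing how the simulated output changes along
#' one model parameter, averaged over seeds. Each row reports the
#' seed-averaged RMS amplitude, periodogram argmax frequency and spectral
#' centroid of the relevant output.
#'
#' `sweep_input_mean()` and `sweep_input_variance()` vary the external
#' input of the traditional model. `sweep_weight_delta()` moves weight
#' from the gamma to the delta branch of an uncoupled multi-dynamic region
#' at fixed alpha weight. `sweep_coupling_unidirectional()` raises the
#' parietal-to-occipital gain with no return coupling, and
#' `sweep_coupling_bidirectional()` raises a symmetric gain between
#' regions with differing weight matrices; both summarize the occipital
#' output.
#'
#' @param mu_values,sigma2_values,w_delta_values,p_o_values,gain_values
#'   Grid of swept values.
#' @param mu,sigma2 Fixed external-input moments where not swept.
#' @param w_alpha Fixed alpha weight of the weight sweep (the delta weight
#'   takes the swept value and gamma the remaining mass).
#' @param occipital_weights,parietal_weights Weight matrices of the
#'   coupling sweeps.
#' @param cfg A [sim_config()].
#' @param seeds Seeds averaged over.
#' @param centroid_window `c(fmin, fmax)` window (Hz) of the centroid.
#' @return A data.frame, one row per swept value: `value`, `rms`,
#'   `argmax_hz`, `centroid_hz` (seed means).
#' @name sweeps
NULL

summarize_runs <- function(xs, centroid_window) {
  stats_one <- function(x) {
    s <- compute_psd(x)
    c(rms = ts_rms(x),
      argmax_hz = s$freqs[which.max(s$power)],
      centroid_hz = spectral_centroid(s, centroid_window[1],
                                      centroid_window[2]))
  }
  colMeans(do.call(rbind, lapply(xs, stats_one)))
}

sweep_row <- function(value, xs, centroid_window) {
  data.frame(value = value, t(summarize_runs(xs, centroid_window)))
}

#' @rdname sweeps
#' @export
sweep_input_mean <- function(mu_values = c(50, 100, 150, 200), sigma2 = 100,
                             cfg = sim_config(), seeds = 1:10,
                             centroid_window = c(0, 64)) {
  do.call(rbind, lapply(mu_values, function(mu) {
    xs <- lapply(seeds, function(s)
      simulate_traditional(noise = noise_spec(mu, sigma2), cfg = cfg, seed = s))
    sweep_row(mu, xs, centroid_window)
  }))
}

#' @rdname sweeps
#' @export
sweep_input_variance <- function(sigma2_values = c(50, 100, 3000, 6000, 20000),
                                 mu = 220, cfg = sim_config(), seeds = 1:10,
                                 centroid_window = c(0, 64)) {
  do.call(rbind, lapply(sigma2_values, function(s2) {
    xs <- lapply(seeds, function(s)
      simulate_traditional(noise = noise_spec(mu, s2), cfg = cfg, seed = s))
    sweep_row(s2, xs, centroid_window)
  }))
}

#' @rdname sweeps
#' @export
sweep_weight_delta <- function(w_delta_values = seq(0, 0.10, by = 0.025),
                               w_alpha = 0.90, noise = noise_spec(),
                               cfg = sim_config(), seeds = 1:10,
                               centroid_window = c(0, 64)) {
  stopifnot(all(w_delta_values <= 1 - w_alpha + 1e-12))
  do.call(rbind, lapply(w_delta_values, function(wd) {
    p <- region_params(weights = oscillator_weights(wd, w_alpha,
                                                    max(0, 1 - w_alpha - wd)),
                       noise = noise)
    xs <- lapply(seeds, function(s) simulate_region(p, cfg = cfg, seed = s))
    sweep_row(wd, xs, centroid_window)
  }))
}

#' @rdname sweeps
#' @export
sweep_coupling_unidirectional <- function(p_o_values = c(0, 100, 200),
                                          occipital_weights =
                                            oscillator_weights(0.10, 0.90, 0),
                                          cfg = sim_config(), seeds = 1:10,
                                          centroid_window = c(0, 64)) {
  do.call(rbind, lapply(p_o_values, function(g) {
    spec <- coupled_model_spec(
      occipital = region_params(weights = occipital_weights),
      parietal = region_params(weights = occipital_weights),
      coupling = coupling_params(o_p = 0, p_o = g),
      cfg = cfg)
    xs <- lapply(seeds, function(s) simulate_coupled(spec, seed = s)$occipital)
    sweep_row(g, xs, centroid_window)
  }))
}

#' @rdname sweeps
#' @export
sweep_coupling_bidirectional <- function(gain_values = c(0, 100, 200),
                                         occipital_weights =
                                           oscillator_weights(0.10, 0.90, 0),
                                         parietal_weights =
                                           oscillator_weights(0.40, 0.30, 0.30),
                                         cfg = sim_config(), seeds = 1:10,
                                         centroid_window = c(0, 64)) {
  do.call(rbind, lapply(gain_values, function(g) {
    spec <- coupled_model_spec(
      occipital = region_params(weights = occipital_weights),
      parietal = region_params(weights = parietal_weights),
      coupling = coupling_params(o_p = g, p_o = g),
      cfg = cfg)
    xs <- lapply(seeds, function(s) simulate_coupled(spec, seed = s)$occipital)
    sweep_row(g, xs, centroid_window)
  }))
}
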