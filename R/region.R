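#' State of a multi-dynamic region
#'
#' Explicit R-level representation of the integrator state of one region:
#' three subpopulations (pyramidal, excitatory interneurons, inhibitory
#' interneurons) times three parallel branches (delta, alpha, gamma), each
#' carrying a postsynaptic potential and its first derivative.
#'
#' @param y,ydot 3 x 3 numeric matrices (rows: pyramidal, excitatory,
#'   inhibitory; columns: delta, alpha, gamma). Default all-zero.
#' @return An object of class `region_state`.
#' @export
region_state <- function(y = matrix(0, 3, 3), ydot = matrix(0, 3, 3)) {
  stopifnot(is.matrix(y), all(dim(y) == c(3, 3)), all(is.finite(y)),
            is.matrix(ydot), all(dim(ydot) == c(3, 3)), all(is.finite(ydot)))
  dimnames(y) <- dimnames(ydot) <-
    list(c("pyramidal", "excitatory", "inhibitory"),
         c("delta", "alpha", "gamma"))
  structure(list(y = y, ydot = ydot), class = "region_state")
}

#' Weighted regional output
#'
#' The region's EEG-like output: the weighted sum of the excitatory
#' interneuron branch potentials minus the weighted sum of the inhibitory
#' ones, `sum_i w_i y1_i - sum_i w_i y2_i`. Because the weights sum to one,
#' identical branch states make the output weight-independent.
#'
#' @param state A [region_state()] object.
#' @param weights An [oscillator_weights()] object.
#' @return Membrane potential (mV).
#' @examples
#' st <- region_state(y = rbind(0, c(1, 2, 3), c(0, 0, 1)))
#' region_output(st, oscillator_weights(0.4, 0.3, 0.3))  # 1.6
#' @export
region_output <- function(state, weights) {
  stopifnot(inherits(state, "region_state"),
            inherits(weights, "oscillator_weights"))
  w <- as.numeric(weights)
  sum(w * state$y["excitatory", ]) - sum(w * state$y["inhibitory", ])
}

#' Simulate one multi-dynamic region
#'
#' Each subpopulation's presynaptic firing-rate drive is computed once per
#' step from the weighted branch outputs (so the per-step noise realization
#' is shared across the three branches of a subpopulation), and every
#' branch integrates that same drive through its own second-order kernel.
#' The returned signal is the weighted output [region_output()] per step.
#'
#' With one-hot alpha weights and the alpha kernels set to the traditional
#' constants this reproduces [simulate_traditional()] to machine precision.
#'
#' @param params A [region_params()] object.
#' @param cfg A [sim_config()] object.
#' @param seed RNG seed for the external input draws.
#' @param external_drive Optional extra input-rate series (one value per
#'   integration step, or a scalar).
#' @param noise_site Injection site of the external input
#'   (`"excitatory"` by default).
#' @return An [nmm_ts()] after burn-in, `fs = 1/dt`.
#' @examples
#' x <- simulate_region(region_params(weights = oscillator_weights(0.1, 0.9, 0)),
#'                      cfg = sim_config(duration = 2), seed = 1)
#' @export
simulate_region <- function(params = region_params(),
                            cfg = sim_config(),
                            seed = 1,
                            external_drive = NULL,
                            noise_site = "excitatory") {
  stopifnot(inherits(params, "region_params"), inherits(cfg, "sim_config"))
  st <- sim_steps(cfg)
  cpp <- region_cpp_pars(params)
  nz <- draw_noise(params$noise, st$n, seed)
  drv <- expand_drive(external_drive, st$n)
  out <- .sim_region_cpp(cpp, nz, drv, cfg$dt, st$n_burn,
                         noise_injection_code(noise_site))
  structure(nmm_ts(out, fs = 1 / cfg$dt, t0 = cfg$burn_in),
            seed = seed, cfg = cfg)
}
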