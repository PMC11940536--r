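#' Sigmoid (potential-to-rate) parameters
#'
#' Parameters of the static nonlinearity that converts a subpopulation's
#' average membrane potential into its mean firing rate,
#' \deqn{S(v) = \frac{2 e_0}{1 + e^{r (v_0 - v)}}.}
#'
#' @param e0 Half-maximum firing rate (s^-1); the sigmoid saturates at
#'   `2 * e0`.
#' @param v0 Membrane potential (mV) at which the firing rate equals `e0`.
#' @param r Steepness of the sigmoid (mV^-1).
#' @return An object of class `sigmoid_params`.
#' @examples
#' sigmoid_params()            # standard Jansen values
#' sigmoid(6, sigmoid_params()) # equals e0 = 2.5
#' @export
sigmoid_params <- function(e0 = 2.5, v0 = 6, r = 0.56) {
  stopifnot(is.numeric(e0), length(e0) == 1L, is.finite(e0), e0 > 0,
            is.numeric(v0), length(v0) == 1L, is.finite(v0),
            is.numeric(r), length(r) == 1L, is.finite(r), r > 0)
  structure(list(e0 = e0, v0 = v0, r = r), class = "sigmoid_params")
}

#' Second-order synaptic kernel
#'
#' A synaptic impulse response `h(t) = G * omega * t * exp(-omega * t)` for
#' `t >= 0` (zero before), the building block of the model's postsynaptic
#' transformations.
#'
#' @param G Average synaptic gain (mV).
#' @param omega Inverse membrane time constant (s^-1).
#' @param polarity `"excitatory"` or `"inhibitory"`; informational tag used
#'   when kernels are assembled into a bank.
#' @return An object of class `synaptic_kernel`.
#' @examples
#' k <- synaptic_kernel(3.25, 100)
#' impulse_response(k, 1 / 100)  # kernel maximum G / e
#' @export
synaptic_kernel <- function(G, omega, polarity = c("excitatory", "inhibitory")) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(G), length(G) == 1L, is.finite(G), G > 0,
            is.numeric(omega), length(omega) == 1L, is.finite(omega), omega > 0)
  structure(list(G = G, omega = omega, polarity = polarity),
            class = "synaptic_kernel")
}

#' Intra-regional connectivity constants
#'
#' Dimensionless synaptic connectivity coefficients C1..C4 between the
#' pyramidal population and the excitatory/inhibitory interneuron
#' populations. Defaults follow the standard Jansen parameterization
#' C1 = C, C2 = 0.8 C, C3 = C4 = 0.25 C with C = 135.
#'
#' @param C1,C2,C3,C4 Nonnegative connectivity coefficients.
#' @return An object of class `connectivity_constants`.
#' @export
connectivity_constants <- function(C1 = 135, C2 = 0.8 * 135,
                                   C3 = 0.25 * 135, C4 = 0.25 * 135) {
  v <- c(C1, C2, C3, C4)
  stopifnot(is.numeric(v), length(v) == 4L, all(is.finite(v)), all(v >= 0))
  structure(list(C1 = C1, C2 = C2, C3 = C3, C4 = C4),
            class = "connectivity_constants")
}

#' External input noise specification
#'
#' External (sub-cortical plus unmodelled) input to a region, drawn
#' independently at every integration step from a Gaussian N(mu, sigma2)
#' in firing-rate units.
#'
#' @param mu Mean input rate (s^-1).
#' @param sigma2 Variance of the input rate.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mu = 220, sigma2 = 100) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma2), length(sigma2) == 1L, is.finite(sigma2),
            sigma2 >= 0)
  structure(list(mu = mu, sigma2 = sigma2), class = "noise_spec")
}

#' Simulation configuration
#'
#' Fixed-step integration settings. The integration step doubles as the
#' sampling interval of the returned signal; the default step of 4/4096 s
#' gives a 1024 Hz sampling rate.
#'
#' @param dt Integration/sampling step (s).
#' @param duration Total simulated time (s), burn-in included.
#' @param burn_in Initial interval (s) discarded from the output to remove
#'   the integration transient.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 4 / 4096, duration = 4, burn_in = 1) {
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0,
            is.numeric(duration), length(duration) == 1L, is.finite(duration),
            is.numeric(burn_in), length(burn_in) == 1L, is.finite(burn_in),
            burn_in >= 0, duration > burn_in)
  structure(list(dt = dt, duration = duration, burn_in = burn_in),
            class = "sim_config")
}

#' Oscillator mixing weights
#'
#' Weights of the delta, alpha and gamma parallel synaptic branches of a
#' multi-dynamic region. Each weight lies in \[0, 1\] and they sum to one
#' (checked to 1e-9 and renormalized exactly).
#'
#' @param w_delta,w_alpha,w_gamma Branch weights.
#' @return An object of class `oscillator_weights` (also a named numeric
#'   vector of length 3).
#' @examples
#' oscillator_weights(0.10, 0.90, 0.00)
#' @export
oscillator_weights <- function(w_delta = 0, w_alpha = 1, w_gamma = 0) {
  w <- c(w_delta = w_delta, w_alpha = w_alpha, w_gamma = w_gamma)
  stopifnot(is.numeric(w), all(is.finite(w)), all(w >= 0), all(w <= 1))
  if (abs(sum(w) - 1) > 1e-9)
    stop("oscillator weights must sum to 1 (got ", format(sum(w)), ")")
  w <- w / sum(w)
  structure(w, class = "oscillator_weights")
}

#' Kernel bank of a multi-dynamic region
#'
#' Three excitatory and three inhibitory synaptic kernels, one pair per
#' oscillatory branch (delta, alpha, gamma). The default alpha pair is the
#' classic Jansen pair (Ge = 3.25 mV, we = 100 s^-1; Gi = 22 mV,
#' wi = 50 s^-1); the delta and gamma pairs rescale the inverse time
#' constants so that each branch alone resonates near 2 Hz and 40 Hz,
#' with gains rescaled to preserve the gain x time-constant product
#' (G' = G * omega' / omega_alpha).
#'
#' @param excitatory List of three excitatory [synaptic_kernel()] objects
#'   named `delta`, `alpha`, `gamma`.
#' @param inhibitory List of three inhibitory kernels, same names.
#' @return An object of class `kernel_bank`.
#' @export
kernel_bank <- function(excitatory = NULL, inhibitory = NULL) {
  if (is.null(excitatory))
    excitatory <- list(
      delta = synaptic_kernel(3.25 * 20 / 100, 20),
      alpha = synaptic_kernel(3.25, 100),
      gamma = synaptic_kernel(3.25 * 400 / 100, 400))
  if (is.null(inhibitory))
    inhibitory <- list(
      delta = synaptic_kernel(22 * 10 / 50, 10, "inhibitory"),
      alpha = synaptic_kernel(22, 50, "inhibitory"),
      gamma = synaptic_kernel(22 * 200 / 50, 200, "inhibitory"))
  nm <- c("delta", "alpha", "gamma")
  stopifnot(identical(names(excitatory), nm), identical(names(inhibitory), nm),
            all(vapply(excitatory, inherits, TRUE, "synaptic_kernel")),
            all(vapply(inhibitory, inherits, TRUE, "synaptic_kernel")))
  structure(list(excitatory = excitatory, inhibitory = inhibitory),
            class = "kernel_bank")
}

#' Parameters of one multi-dynamic cortical region
#'
#' @param sigmoid A [sigmoid_params()] object.
#' @param bank A [kernel_bank()] object (three excitatory + three
#'   inhibitory kernels).
#' @param weights An [oscillator_weights()] object.
#' @param connectivity A [connectivity_constants()] object.
#' @param noise A [noise_spec()] object for the region's external input.
#' @return An object of class `region_params`.
#' @examples
#' region_params(weights = oscillator_weights(0.10, 0.90, 0.00))
#' @export
region_params <- function(sigmoid = sigmoid_params(),
                          bank = kernel_bank(),
                          weights = oscillator_weights(),
                          connectivity = connectivity_constants(),
                          noise = noise_spec()) {
  stopifnot(inherits(sigmoid, "sigmoid_params"),
            inherits(bank, "kernel_bank"),
            inherits(weights, "oscillator_weights"),
            inherits(connectivity, "connectivity_constants"),
            inherits(noise, "noise_spec"))
  structure(list(sigmoid = sigmoid, bank = bank, weights = weights,
                 connectivity = connectivity, noise = noise),
            class = "region_params")
}

#' Cross-regional coupling parameters
#'
#' Gains and encoder of the bidirectional occipital-parietal pathway. The
#' coupling signal of a source region is `gain * S(RM(x))` where `x` is the
#' weighted excitatory-minus-inhibitory membrane potential and `RM`
#' subtracts its running mean; the resulting firing rate is filtered by the
#' cross-regional encoder (a weighted bank of excitatory kernels) and added
#' to the target region's external input.
#'
#' @param o_p Occipital-to-parietal coupling gain (dimensionless, >= 0).
#' @param p_o Parietal-to-occipital coupling gain.
#' @param encoder_bank A [kernel_bank()] whose excitatory kernels form the
#'   encoder; `NULL` (the default) uses each source region's excitatory
#'   time constants normalized to unit DC gain (`G = omega`), so the
#'   encoder is a rate-to-rate filter and the coupling gain is carried
#'   entirely by `o_p`/`p_o`.
#' @param encoder_weights Encoder mixing weights; `NULL` means "use each
#'   source region's own weights".
#' @param delay Conduction delay between regions in integration steps
#'   (integer, default 0).
#' @param rm_mode `"running"` (causal running mean over the simulation so
#'   far, burn-in included) or `"fixed"` (subtract the user-supplied
#'   `rm_fixed` values, e.g. a whole-signal mean from a previous run).
#' @param rm_fixed Length-2 numeric `(occipital, parietal)` used when
#'   `rm_mode = "fixed"`.
#' @return An object of class `coupling_params`.
#' @export
coupling_params <- function(o_p = 0, p_o = 0, encoder_bank = NULL,
                            encoder_weights = NULL, delay = 0L,
                            rm_mode = c("running", "fixed"),
                            rm_fixed = c(0, 0)) {
  rm_mode <- match.arg(rm_mode)
  stopifnot(is.numeric(o_p), length(o_p) == 1L, is.finite(o_p), o_p >= 0,
            is.numeric(p_o), length(p_o) == 1L, is.finite(p_o), p_o >= 0,
            length(delay) == 1L, delay >= 0, delay == as.integer(delay),
            is.numeric(rm_fixed), length(rm_fixed) == 2L, all(is.finite(rm_fixed)))
  if (!is.null(encoder_bank)) stopifnot(inherits(encoder_bank, "kernel_bank"))
  if (!is.null(encoder_weights))
    stopifnot(inherits(encoder_weights, "oscillator_weights"))
  structure(list(o_p = o_p, p_o = p_o, encoder_bank = encoder_bank,
                 encoder_weights = encoder_weights, delay = as.integer(delay),
                 rm_mode = rm_mode, rm_fixed = rm_fixed),
            class = "coupling_params")
}

#' Specification of the two-region coupled model
#'
#' @param occipital,parietal [region_params()] for the two regions.
#' @param coupling A [coupling_params()] object.
#' @param cfg A [sim_config()] shared by both regions.
#' @return An object of class `coupled_model_spec`.
#' @examples
#' spec <- coupled_model_spec(
#'   occipital = region_params(weights = oscillator_weights(0.10, 0.90, 0.00)),
#'   parietal  = region_params(weights = oscillator_weights(0.40, 0.30, 0.30)),
#'   coupling  = coupling_params(o_p = 100, p_o = 100))
#' @export
coupled_model_spec <- function(occipital = region_params(),
                               parietal = region_params(),
                               coupling = coupling_params(),
                               cfg = sim_config()) {
  stopifnot(inherits(occipital, "region_params"),
            inherits(parietal, "region_params"),
            inherits(coupling, "coupling_params"),
            inherits(cfg, "sim_config"))
  structure(list(occipital = occipital, parietal = parietal,
                 coupling = coupling, cfg = cfg),
            class = "coupled_model_spec")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("<sigmoid_params> e0=%g s^-1, v0=%g mV, r=%g mV^-1\n",
              x$e0, x$v0, x$r))
  invisible(x)
}

#' @export
print.synaptic_kernel <- function(x, ...) {
  cat(sprintf("<synaptic_kernel> %s: G=%g mV, omega=%g s^-1 (peak G/e=%.4g mV at t=%.4g s)\n",
              x$polarity, x$G, x$omega, x$G / exp(1), 1 / x$omega))
  invisible(x)
}

#' @export
print.oscillator_weights <- function(x, ...) {
  cat(sprintf("<oscillator_weights> delta=%.4f alpha=%.4f gamma=%.4f\n",
              x[[1]], x[[2]], x[[3]]))
  invisible(x)
}

#' @export
print.region_params <- function(x, ...) {
  cat("<region_params>\n")
  cat(sprintf("  weights: delta=%.3f alpha=%.3f gamma=%.3f\n",
              x$weights[[1]], x$weights[[2]], x$weights[[3]]))
  cat(sprintf("  noise:   N(mu=%g, sigma2=%g)\n", x$noise$mu, x$noise$sigma2))
  cat(sprintf("  alpha kernels: Ge=%g/we=%g, Gi=%g/wi=%g\n",
              x$bank$excitatory$alpha$G, x$bank$excitatory$alpha$omega,
              x$bank$inhibitory$alpha$G, x$bank$inhibitory$alpha$omega))
  invisible(x)
}

#' @export
print.coupled_model_spec <- function(x, ...) {
  cat(sprintf("<coupled_model_spec> o_p=%g, p_o=%g, delay=%d steps, dt=%g s, %g s (%g s burn-in)\n",
              x$coupling$o_p, x$coupling$p_o, x$coupling$delay,
              x$cfg$dt, x$cfg$duration, x$cfg$burn_in))
  invisible(x)
}
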