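#' Potential-to-rate sigmoid
#'
#' Converts an average membrane potential into the subpopulation's mean
#' firing rate, `S(v) = 2 e0 / (1 + exp(r (v0 - v)))`. Strictly increasing
#' in `v`, bounded in `(0, 2 e0)`.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param p A [sigmoid_params()] object.
#' @return Firing rate(s) in s^-1.
#' @examples
#' sigmoid(0, sigmoid_params())  # ~0.1678 s^-1
#' @export
sigmoid <- function(v, p = sigmoid_params()) {
  stopifnot(inherits(p, "sigmoid_params"), is.numeric(v))
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  2 * p$e0 / (1 + exp(p$r * (p$v0 - v)))
}

#' Synaptic impulse response
#'
#' Evaluates the kernel `h(t) = G * omega * t * exp(-omega * t)` for
#' `t >= 0`, zero for negative times. The kernel peaks at `t = 1/omega`
#' with value `G/e` and integrates to `G/omega`.
#'
#' @param k A [synaptic_kernel()] object.
#' @param t Time (s); vectorized, negative values allowed.
#' @return Postsynaptic potential contribution (mV).
#' @export
impulse_response <- function(k, t) {
  stopifnot(inherits(k, "synaptic_kernel"), is.numeric(t))
  ifelse(t < 0, 0, k$G * k$omega * t * exp(-k$omega * t))
}

#' Derivatives of the traditional three-subpopulation model
#'
#' The right-hand side of the traditional single-kernel neural mass model.
#' Each subpopulation obeys `y'' = G w x - 2 w y' - w^2 y` with `x` its
#' presynaptic firing-rate input: the pyramidal branch is driven by
#' `S(y1 - y2)`, the excitatory-interneuron branch by
#' `input_rate + C2 S(C1 y0)`, and the inhibitory branch by `C4 S(C3 y0)`
#' through the inhibitory kernel.
#'
#' @param state Numeric vector `c(y0, y1, y2, y3, y4, y5)` of the three
#'   postsynaptic potentials and their first derivatives.
#' @param input_rate External input firing rate (s^-1).
#' @param sigmoid A [sigmoid_params()] object.
#' @param ke,ki Excitatory and inhibitory [synaptic_kernel()] objects.
#' @param connectivity A [connectivity_constants()] object.
#' @return Numeric vector `c(y3, y4, y5, ydd0, ydd1, ydd2)` (the state
#'   derivative), suitable for generic ODE solvers.
#' @export
region_derivatives <- function(state, input_rate,
                               sigmoid = sigmoid_params(),
                               ke = synaptic_kernel(3.25, 100),
                               ki = synaptic_kernel(22, 50, "inhibitory"),
                               connectivity = connectivity_constants()) {
  stopifnot(is.numeric(state), length(state) == 6L, all(is.finite(state)))
  y <- state[1:3]; yd <- state[4:6]
  cc <- connectivity
  s_pyr <- sigmoid(y[2] - y[3], sigmoid)
  s_exc <- input_rate + cc$C2 * sigmoid(cc$C1 * y[1], sigmoid)
  s_inh <- cc$C4 * sigmoid(cc$C3 * y[1], sigmoid)
  ydd <- c(ke$G * ke$omega * s_pyr - 2 * ke$omega * yd[1] - ke$omega^2 * y[1],
           ke$G * ke$omega * s_exc - 2 * ke$omega * yd[2] - ke$omega^2 * y[2],
           ki$G * ki$omega * s_inh - 2 * ki$omega * yd[3] - ki$omega^2 * y[3])
  c(yd, ydd)
}

# Flatten region parameters into the list layout the C++ integrator reads.
# `single_kernel` collapses the bank to one branch (the traditional model).
region_cpp_pars <- function(params, single_ke = NULL, single_ki = NULL) {
  sg <- params$sigmoid
  cc <- params$connectivity
  if (!is.null(single_ke)) {
    Ge <- single_ke$G; we <- single_ke$omega
    Gi <- single_ki$G; wi <- single_ki$omega
    w <- 1
  } else {
    bk <- params$bank
    Ge <- vapply(bk$excitatory, `[[`, 0, "G")
    we <- vapply(bk$excitatory, `[[`, 0, "omega")
    Gi <- vapply(bk$inhibitory, `[[`, 0, "G")
    wi <- vapply(bk$inhibitory, `[[`, 0, "omega")
    w <- as.numeric(params$weights)
  }
  list(sigmoid = c(sg$e0, sg$v0, sg$r),
       connectivity = c(cc$C1, cc$C2, cc$C3, cc$C4),
       Ge = unname(Ge), we = unname(we), Gi = unname(Gi), wi = unname(wi),
       w = unname(w))
}

noise_injection_code <- function(site = c("excitatory", "pyramidal", "inhibitory")) {
  site <- match.arg(site)
  c(pyramidal = 0L, excitatory = 1L, inhibitory = 2L)[[site]]
}

sim_steps <- function(cfg) {
  n <- round(cfg$duration / cfg$dt)
  n_burn <- round(cfg$burn_in / cfg$dt)
  list(n = n, n_burn = n_burn)
}

# Per-step external input draws; rnorm(n, mu, 0) is exactly mu, so a zero
# variance yields a deterministic trajectory regardless of seed.
draw_noise <- function(noise, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rnorm(n, mean = noise$mu, sd = sqrt(noise$sigma2))
}

#' Simulate the traditional single-kernel neural mass model
#'
#' Fixed-step explicit Euler integration of the three-subpopulation model:
#' at each step the external input is an independent Gaussian draw
#' N(mu, sigma2) injected (by default) into the excitatory-interneuron
#' branch. The EEG-like output is `E(t) = y1(t) - y2(t)` after burn-in.
#' The integration step doubles as the sampling interval. Identical seeds
#' give identical outputs.
#'
#' @param ke,ki Excitatory and inhibitory [synaptic_kernel()] objects
#'   (defaults: Ge = 3.25 mV, we = 100 s^-1; Gi = 22 mV, wi = 50 s^-1).
#' @param noise A [noise_spec()] object.
#' @param cfg A [sim_config()] object.
#' @param seed RNG seed for the input draws.
#' @param sigmoid A [sigmoid_params()] object.
#' @param connectivity A [connectivity_constants()] object.
#' @param noise_site Subpopulation whose presynaptic drive receives the
#'   external input (`"excitatory"`, the classic wiring, by default).
#' @param external_drive Optional extra input-rate series (numeric or
#'   [nmm_ts()]) added to the noise at every step; must have one value per
#'   integration step.
#' @return An [nmm_ts()] with `round((duration - burn_in)/dt)` samples at
#'   `fs = 1/dt`; the seed and parameters are attached as attributes.
#' @examples
#' x <- simulate_traditional(noise = noise_spec(220, 100),
#'                           cfg = sim_config(duration = 2), seed = 1)
#' print(x)
#' @export
simulate_traditional <- function(ke = synaptic_kernel(3.25, 100),
                                 ki = synaptic_kernel(22, 50, "inhibitory"),
                                 noise = noise_spec(),
                                 cfg = sim_config(),
                                 seed = 1,
                                 sigmoid = sigmoid_params(),
                                 connectivity = connectivity_constants(),
                                 noise_site = "excitatory",
                                 external_drive = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(noise, "noise_spec"))
  st <- sim_steps(cfg)
  params <- list(sigmoid = sigmoid, connectivity = connectivity)
  cpp <- region_cpp_pars(params, single_ke = ke, single_ki = ki)
  nz <- draw_noise(noise, st$n, seed)
  drv <- expand_drive(external_drive, st$n)
  out <- .sim_region_cpp(cpp, nz, drv, cfg$dt, st$n_burn,
                         noise_injection_code(noise_site))
  structure(nmm_ts(out, fs = 1 / cfg$dt, t0 = cfg$burn_in),
            seed = seed, cfg = cfg)
}

expand_drive <- function(external_drive, n) {
  if (is.null(external_drive)) return(numeric(n))
  v <- if (inherits(external_drive, "nmm_ts")) external_drive$values
       else as.numeric(external_drive)
  if (length(v) == 1L) v <- rep(v, n)
  if (length(v) != n)
    stop("external_drive must supply one value per integration step (",
         n, "), got ", length(v))
  v
}
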