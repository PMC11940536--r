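#' Particle swarm configuration
#'
#' Swarm settings for spectrum fitting. Defaults are the study settings:
#' 50 particles, 70 iterations, inertia weight `k = 0.5` and learning
#' factors `c1 = c2 = 1.5` (so `0 < c1 + c2 < 4`).
#'
#' @param n_particles Swarm size (>= 1).
#' @param n_iters Number of velocity/position update iterations.
#' @param k Inertia weight retained from the previous velocity.
#' @param c1 Cognitive (personal-best) learning factor.
#' @param c2 Social (global-best) learning factor.
#' @param bounds Numeric matrix with columns `lo`, `hi` and one row per
#'   dimension (row names = dimension names), `lo < hi`.
#' @param seed Seed for swarm initialization and the per-step uniform
#'   draws.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 50, n_iters = 70, k = 0.5,
                       c1 = 1.5, c2 = 1.5, bounds = NULL, seed = 1) {
  stopifnot(n_particles >= 1, n_iters >= 0, is.finite(k),
            c1 >= 0, c2 >= 0, c1 + c2 > 0, c1 + c2 < 4)
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    stopifnot(ncol(bounds) == 2L, all(bounds[, 1] < bounds[, 2]))
    colnames(bounds) <- c("lo", "hi")
  }
  structure(list(n_particles = as.integer(n_particles),
                 n_iters = as.integer(n_iters), k = k, c1 = c1, c2 = c2,
                 bounds = bounds, seed = seed),
            class = "pso_config")
}

#' Default fitting bounds for the coupled model's free parameters
#'
#' Noise means are bounded in \[22, 2200\] and variances in \[2, 20000\];
#' coupling coefficients default to \[0, 2000\] (wide enough to contain
#' all fitted values reported for 10-12 Hz stimulation). Softmax logits of
#' the optional oscillator-weight extension are bounded in \[-5, 5\].
#'
#' @param dims Character vector of dimension names; any of
#'   `o_p, p_o, mu_o, sigma2_o, mu_p, sigma2_p` and the weight logits
#'   `eta_{o,p}_{delta,alpha,gamma}`.
#' @return Bounds matrix (rows = dims, columns `lo`, `hi`).
#' @export
default_fit_bounds <- function(dims = c("o_p", "p_o", "mu_o", "sigma2_o",
                                        "mu_p", "sigma2_p")) {
  known <- rbind(
    o_p = c(0, 2000), p_o = c(0, 2000),
    mu_o = c(22, 2200), sigma2_o = c(2, 20000),
    mu_p = c(22, 2200), sigma2_p = c(2, 20000),
    eta_o_delta = c(-5, 5), eta_o_alpha = c(-5, 5), eta_o_gamma = c(-5, 5),
    eta_p_delta = c(-5, 5), eta_p_alpha = c(-5, 5), eta_p_gamma = c(-5, 5))
  bad <- setdiff(dims, rownames(known))
  if (length(bad)) stop("no default bounds for dimension(s): ",
                        paste(bad, collapse = ", "))
  b <- known[dims, , drop = FALSE]
  colnames(b) <- c("lo", "hi")
  b
}

#' Mean squared error between two spectra
#'
#' The fitting objective `(1/n) * sum((Y(f_i) - S(f_i))^2)` over a common
#' frequency grid. If the model spectrum sits on a different grid it is
#' resampled onto the target grid by linear interpolation; target
#' frequencies outside the model's range are an error.
#'
#' @param target,model [nmm_spectrum()] objects.
#' @return Nonnegative scalar; zero iff the spectra are identical on the
#'   target grid.
#' @examples
#' a <- nmm_spectrum(1:3, c(1, 2, 3))
#' b <- nmm_spectrum(1:3, c(0, 0, 0))
#' spectrum_mse(a, b)  # 14/3
#' @export
spectrum_mse <- function(target, model) {
  stopifnot(inherits(target, "nmm_spectrum"), inherits(model, "nmm_spectrum"))
  p <- if (length(model$freqs) == length(target$freqs) &&
           max(abs(model$freqs - target$freqs)) < 1e-9) {
    model$power
  } else {
    out <- approx(model$freqs, model$power, xout = target$freqs, rule = 1)$y
    if (anyNA(out))
      stop("model spectrum does not cover the target frequency grid")
    out
  }
  mean((target$power - p)^2)
}

#' Initialize a particle swarm
#'
#' Positions uniform within bounds, velocities zero; personal and global
#' bests from one evaluation sweep. Non-finite objective values are
#' treated as +Inf.
#'
#' @param objective Function mapping a named parameter vector to a scalar.
#' @param cfg A [pso_config()] with `bounds` set.
#' @return A `pso_swarm` list: `X`, `V`, `pbest`, `pbest_val`, `gbest`,
#'   `gbest_val`, `n_evals`.
#' @export
pso_init <- function(objective, cfg) {
  stopifnot(inherits(cfg, "pso_config"), !is.null(cfg$bounds))
  b <- cfg$bounds
  d <- nrow(b)
  n <- cfg$n_particles
  X <- matrix(runif(n * d, rep(b[, 1], each = n), rep(b[, 2], each = n)),
              n, d, dimnames = list(NULL, rownames(b)))
  V <- matrix(0, n, d, dimnames = dimnames(X))
  val <- apply(X, 1, function(x) safe_objective(objective, x))
  i <- which.min(val)
  structure(list(X = X, V = V, pbest = X, pbest_val = val,
                 gbest = X[i, ], gbest_val = val[i], n_evals = n),
            class = "pso_swarm")
}

safe_objective <- function(objective, x) {
  v <- tryCatch(objective(x), error = function(e) {
    warning("objective evaluation failed (treated as +Inf): ",
            conditionMessage(e), call. = FALSE)
    Inf
  })
  if (!is.finite(v)) Inf else v
}

#' One particle swarm iteration
#'
#' Velocity update `V <- k V + c1 r1 (pbest - X) + c2 r2 (gbest - X)` with
#' fresh `r1, r2 ~ U(0,1)` per particle-dimension, position update
#' `X <- X + V`, clipping to bounds with the offending velocity component
#' zeroed, then personal/global best bookkeeping. The global best value is
#' non-increasing by construction.
#'
#' @param swarm A `pso_swarm` from [pso_init()].
#' @param objective Objective function.
#' @param cfg The [pso_config()] used at initialization.
#' @return The updated `pso_swarm`.
#' @export
pso_step <- function(swarm, objective, cfg) {
  stopifnot(inherits(swarm, "pso_swarm"), inherits(cfg, "pso_config"))
  b <- cfg$bounds
  n <- nrow(swarm$X)
  d <- ncol(swarm$X)
  r1 <- matrix(runif(n * d), n, d)
  r2 <- matrix(runif(n * d), n, d)
  gb <- matrix(swarm$gbest, n, d, byrow = TRUE)
  V <- cfg$k * swarm$V + cfg$c1 * r1 * (swarm$pbest - swarm$X) +
    cfg$c2 * r2 * (gb - swarm$X)
  X <- swarm$X + V
  lo <- matrix(b[, 1], n, d, byrow = TRUE)
  hi <- matrix(b[, 2], n, d, byrow = TRUE)
  out <- X < lo | X > hi
  X <- pmin(pmax(X, lo), hi)
  V[out] <- 0
  val <- apply(X, 1, function(x) safe_objective(objective, x))
  better <- val < swarm$pbest_val
  swarm$pbest[better, ] <- X[better, , drop = FALSE]
  swarm$pbest_val[better] <- val[better]
  i <- which.min(swarm$pbest_val)
  swarm$X <- X
  swarm$V <- V
  swarm$gbest <- swarm$pbest[i, ]
  swarm$gbest_val <- swarm$pbest_val[i]
  swarm$n_evals <- swarm$n_evals + n
  swarm
}

#' Run a full particle swarm optimization
#'
#' @param objective Function from a named parameter vector to a scalar.
#' @param cfg A [pso_config()] with bounds.
#' @return An object of class `fit_result`: `par` (best position),
#'   `value` (best objective), `trajectory` (global best per iteration,
#'   length `n_iters + 1`, non-increasing), `n_evals`, `swarm`.
#' @export
pso_optimize <- function(objective, cfg) {
  set.seed(cfg$seed)
  swarm <- pso_init(objective, cfg)
  traj <- numeric(cfg$n_iters + 1L)
  traj[1] <- swarm$gbest_val
  if (cfg$n_iters > 0) {
    for (t in seq_len(cfg$n_iters)) {
      swarm <- pso_step(swarm, objective, cfg)
      traj[t + 1L] <- swarm$gbest_val
    }
  }
  structure(list(par = swarm$gbest, value = swarm$gbest_val,
                 trajectory = traj, n_evals = swarm$n_evals, swarm = swarm),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> best objective %.6g after %d evaluations\n",
              x$value, x$n_evals))
  if (length(x$par)) {
    cat("  parameters:\n")
    for (nm in names(x$par))
      cat(sprintf("    %-10s %.6g\n", nm, x$par[[nm]]))
  }
  invisible(x)
}

# Apply a named parameter vector to a coupled model spec. Softmax logits
# eta_* reparameterize a region's oscillator weights onto the simplex.
apply_theta <- function(spec, theta) {
  for (nm in names(theta)) {
    v <- theta[[nm]]
    spec <- switch(nm,
      o_p = { spec$coupling$o_p <- v; spec },
      p_o = { spec$coupling$p_o <- v; spec },
      mu_o = { spec$occipital$noise$mu <- v; spec },
      sigma2_o = { spec$occipital$noise$sigma2 <- v; spec },
      mu_p = { spec$parietal$noise$mu <- v; spec },
      sigma2_p = { spec$parietal$noise$sigma2 <- v; spec },
      if (grepl("^eta_[op]_", nm)) spec else stop("unknown fit dimension: ", nm))
  }
  eta_o <- theta[grep("^eta_o_", names(theta))]
  if (length(eta_o) == 3L) {
    w <- exp(eta_o - max(eta_o)); w <- w / sum(w)
    spec$occipital$weights <- oscillator_weights(w[["eta_o_delta"]],
                                                 w[["eta_o_alpha"]],
                                                 w[["eta_o_gamma"]])
  }
  eta_p <- theta[grep("^eta_p_", names(theta))]
  if (length(eta_p) == 3L) {
    w <- exp(eta_p - max(eta_p)); w <- w / sum(w)
    spec$parietal$weights <- oscillator_weights(w[["eta_p_delta"]],
                                                w[["eta_p_alpha"]],
                                                w[["eta_p_gamma"]])
  }
  spec
}

#' Fit the coupled model to a target spectrum
#'
#' Particle swarm optimization of the free parameters of a coupled model
#' against a target power spectrum. Each evaluation simulates the coupled
#' model at the candidate parameters with ONE fixed simulation seed shared
#' by all evaluations of the fit (so the objective is deterministic and
#' the personal-best bookkeeping well defined; set `n_sim_seeds > 1` to
#' average the spectrum over several seeds per evaluation), computes the
#' occipital output's periodogram and returns its MSE against the target.
#'
#' @param target An [nmm_spectrum()]; the model spectrum is linearly
#'   resampled onto its grid.
#' @param spec_template A [coupled_model_spec()] supplying every parameter
#'   not being fitted.
#' @param free Character vector of free dimension names (see
#'   [default_fit_bounds()]). Empty: no optimization, the template's MSE
#'   is returned after a single evaluation.
#' @param cfg A [pso_config()]; `cfg$bounds` rows must cover `free`
#'   (defaults filled in from [default_fit_bounds()]).
#' @param sim_seed Simulation seed shared by all objective evaluations
#'   (default: derived from `cfg$seed`).
#' @param n_sim_seeds Number of simulation seeds averaged per evaluation.
#' @return A `fit_result`; `$par` is the best parameter vector, and
#'   `$spectrum` the fitted occipital spectrum on the target grid.
#' @export
fit_model <- function(target, spec_template, free = c("o_p", "p_o"),
                      cfg = pso_config(), sim_seed = NULL, n_sim_seeds = 1) {
  stopifnot(inherits(target, "nmm_spectrum"),
            inherits(spec_template, "coupled_model_spec"))
  if (is.null(sim_seed)) sim_seed <- derive_subseeds(cfg$seed, 3L)[3]
  sim_seeds <- if (n_sim_seeds > 1)
    derive_subseeds(sim_seed, n_sim_seeds) else sim_seed

  model_spectrum <- function(theta) {
    spec <- apply_theta(spec_template, theta)
    acc <- NULL
    for (s in sim_seeds) {
      out <- simulate_coupled(spec, seed = s)
      ps <- compute_psd(out$occipital)
      acc <- if (is.null(acc)) ps$power else acc + ps$power
    }
    nmm_spectrum(ps$freqs, acc / length(sim_seeds))
  }
  objective <- function(theta) spectrum_mse(target, model_spectrum(theta))

  if (length(free) == 0L) {
    val <- safe_objective(objective, numeric(0))
    fit <- structure(list(par = numeric(0), value = val, trajectory = val,
                          n_evals = 1L, swarm = NULL), class = "fit_result")
    fit$spectrum <- model_spectrum(numeric(0))
    return(fit)
  }
  if (is.null(cfg$bounds)) {
    cfg$bounds <- default_fit_bounds(free)
  } else {
    miss <- setdiff(free, rownames(cfg$bounds))
    if (length(miss))
      cfg$bounds <- rbind(cfg$bounds, default_fit_bounds(miss))
    cfg$bounds <- cfg$bounds[free, , drop = FALSE]
  }
  fit <- pso_optimize(objective, cfg)
  fit$spectrum <- model_spectrum(fit$par)
  fit
}
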