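#' Linear stochastic system container
#'
#' Bundles a coupling matrix (Jacobian, in Hz), diffusion amplitudes, a
#' spatial geometry and an (optional) input matrix into a single object
#' describing the Langevin system `dx/dt = J x + C u + omega`, with noise
#' convention `E[omega(t) omega(s)'] = 2 Gamma delta(t - s)` so that the
#' scalar Ornstein-Uhlenbeck stationary variance is `Gamma / kappa`.
#'
#' @param J N x N real Jacobian (Hz).
#' @param Gamma length-N nonnegative diffusion amplitudes (diagonal).
#' @param geometry a [grid_geometry()] or `NULL`.
#' @param C N x K input matrix (effect of each exogenous input on each
#'   state's flow), or `NULL`.
#' @return An object of class `lss`.
#' @export
lss <- function(J, Gamma = NULL, geometry = NULL, C = NULL) {
  stopifnot_square(J, "J")
  n <- nrow(J)
  if (!all(is.finite(J))) stop("J must be finite")
  Gamma <- Gamma %||% rep(0.5, n)
  if (length(Gamma) == 1) Gamma <- rep(Gamma, n)
  if (any(Gamma < 0)) stop("Gamma must be nonnegative")
  if (!is.null(C)) C <- as.matrix(C)
  ev <- eigen(J, only.values = TRUE)$values
  structure(
    list(J = J, Gamma = Gamma, geometry = geometry, C = C,
         stable = max(Re(ev)) < 0, max_re_eig = max(Re(ev))),
    class = "lss")
}

#' @export
print.lss <- function(x, ...) {
  n <- nrow(x$J)
  ne <- sum(abs(x$J) > 1e-12) - sum(abs(diag(x$J)) > 1e-12)
  cat(sprintf("Linear stochastic system: %d states, %d directed couplings\n", n, ne))
  cat(sprintf("  max Re(eig(J)) = %.4f Hz (%s)\n", x$max_re_eig,
              if (x$stable) "stable" else "UNSTABLE"))
  cat(sprintf("  diffusion Gamma in [%.3g, %.3g]\n", min(x$Gamma), max(x$Gamma)))
  if (!is.null(x$C)) cat(sprintf("  %d exogenous input(s)\n", ncol(x$C)))
  invisible(x)
}

#' Draw a sparse, distance-dependent Jacobian
#'
#' Samples a spatially embedded coupling matrix with a Mexican-hat profile:
#' short-range connections are excitatory (positive) and connections in an
#' inhibitory annulus are negative; couplings beyond the annulus are exactly
#' zero. Edges are predominantly reciprocal. The diagonal is set to
#' `-self_decay` and then uniformly shifted, if necessary, until
#' `max Re(eig(J)) <= -eps_stab`, which preserves the sparsity pattern.
#'
#' @param geometry a [grid_geometry()].
#' @param coupling list with elements `excit_scale`, `inhib_scale` (Hz),
#'   `excit_range`, `inhib_range` (mm), `density` in (0, 1], `self_decay`
#'   (Hz). Missing elements take the defaults below.
#' @param seed integer seed.
#' @param reciprocal_prob probability that an edge is accompanied by its
#'   reciprocal (default 0.96, so only a few percent of connections are
#'   one-directional).
#' @param symmetric if `TRUE`, force `J` symmetric (each reciprocal edge has
#'   equal weight both ways); useful for detailed-balance fixtures.
#' @param eps_stab stability margin in Hz (default 0.01).
#' @param Gamma diffusion amplitude(s) passed to [lss()].
#' @param n_inputs if > 0, attach a random sparse input matrix `C`.
#' @return An [lss()] with `$geometry` set.
#' @export
sample_jacobian <- function(geometry,
                            coupling = list(),
                            seed = NULL,
                            reciprocal_prob = 0.96,
                            symmetric = FALSE,
                            eps_stab = 0.01,
                            Gamma = 0.5,
                            n_inputs = 0L) {
  cp <- utils::modifyList(
    list(excit_scale = 0.3, inhib_scale = 0.25,
         excit_range = 8, inhib_range = 16,
         density = 0.25, self_decay = 0.5), coupling)
  if (cp$self_decay <= 0) stop("self_decay must be positive")
  if (cp$excit_range <= 0 || cp$inhib_range <= cp$excit_range)
    stop("need 0 < excit_range < inhib_range")
  if (cp$density < 0 || cp$density > 1) stop("density must be in [0, 1]")
  n <- nrow(geometry$positions)
  D <- mirrored_distances(geometry)
  with_seed(seed, {
    J <- matrix(0, n, n)
    reach <- D <= cp$inhib_range & upper.tri(D)
    idx <- which(reach, arr.ind = TRUE)
    if (nrow(idx) > 0 && cp$density > 0) {
      keep <- stats::runif(nrow(idx)) < cp$density
      idx <- idx[keep, , drop = FALSE]
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        d <- D[i, j]
        excit <- d <= cp$excit_range
        scale <- if (excit) cp$excit_scale else cp$inhib_scale
        sgn <- if (excit) 1 else -1
        ## magnitudes bounded away from zero: detectable effective
        ## connections are of order 0.1-1 Hz
        w1 <- sgn * scale * (0.5 + abs(stats::rnorm(1)))
        if (symmetric) {
          J[i, j] <- J[j, i] <- w1
        } else if (stats::runif(1) < reciprocal_prob) {
          w2 <- sgn * scale * (0.5 + abs(stats::rnorm(1)))
          J[i, j] <- w1; J[j, i] <- w2
        } else {
          if (stats::runif(1) < 0.5) J[i, j] <- w1 else J[j, i] <- w1
        }
      }
    }
    diag(J) <- -cp$self_decay
    ## uniform diagonal shift to enforce stability
    for (iter in seq_len(8)) {
      m <- max(Re(eigen(J, only.values = TRUE)$values))
      if (m <= -eps_stab) break
      J <- J - (m + eps_stab) * diag(n)
    }
    m <- max(Re(eigen(J, only.values = TRUE)$values))
    if (m > -eps_stab + 1e-10)
      stop("stabilization by diagonal shift failed")
    C <- NULL
    if (n_inputs > 0) {
      C <- matrix(0, n, n_inputs)
      for (k in seq_len(n_inputs)) {
        tgt <- sample.int(n, max(1L, round(n / 4)))
        C[tgt, k] <- stats::rnorm(length(tgt), 0, 0.25)
      }
    }
    lss(J, Gamma = Gamma, geometry = geometry, C = C)
  })
}

#' Simulate latent dynamics by Euler-Maruyama integration
#'
#' Integrates `dx = (J x + C u) dt + sqrt(2 Gamma dt) z`, `z ~ N(0, I)`, and
#' discards a burn-in (default ten characteristic times of the slowest mode)
#' so the retained trajectory is effectively stationary.
#'
#' @param system an [lss()].
#' @param duration length of the retained trajectory in seconds.
#' @param dt integration step (s).
#' @param seed integer seed.
#' @param inputs optional T x K matrix of exogenous inputs sampled at `dt`
#'   (applied after burn-in; zero input during burn-in).
#' @param burn_in burn-in time in seconds; default `10 / min(-Re(eig(J)))`.
#' @param x0 initial state (default 0).
#' @param allow_unstable permit integration of an unstable system.
#' @return A `timeseries_matrix`: list with `values` (T x N), `sampling_interval`,
#'   `channel_ids`.
#' @export
simulate_latent <- function(system, duration, dt = 0.1, seed = NULL,
                            inputs = NULL, burn_in = NULL, x0 = NULL,
                            allow_unstable = FALSE) {
  stopifnot(inherits(system, "lss"))
  if (dt <= 0) stop("dt must be positive")
  if (duration < 10 * dt) stop("duration must be at least 10*dt")
  if (!system$stable && !allow_unstable)
    stop("system is unstable; pass allow_unstable = TRUE to integrate anyway")
  J <- system$J; n <- nrow(J)
  ev <- eigen(J, only.values = TRUE)$values
  if (is.null(burn_in)) {
    slowest <- min(abs(Re(ev)))
    burn_in <- if (slowest > 0) 10 / slowest else 0
  }
  nb <- ceiling(burn_in / dt)
  nt <- ceiling(duration / dt)
  sd_step <- sqrt(2 * system$Gamma * dt)
  if (!is.null(inputs)) {
    inputs <- as.matrix(inputs)
    if (nrow(inputs) < nt) stop("inputs must cover the full duration")
    if (is.null(system$C)) stop("system has no input matrix C")
  }
  with_seed(seed, {
    x <- if (is.null(x0)) rep(0, n) else x0
    out <- matrix(NA_real_, nt, n)
    total <- nb + nt
    noise <- matrix(stats::rnorm(total * n), total, n)
    for (t in seq_len(total)) {
      drift <- J %*% x
      if (t > nb && !is.null(inputs))
        drift <- drift + system$C %*% inputs[t - nb, ]
      x <- x + dt * drift + sd_step * noise[t, ]
      if (!all(is.finite(x)))
        stop(sprintf("integration blew up (NaN/Inf) at step %d", t))
      if (t > nb) out[t - nb, ] <- x
    }
    structure(list(values = out, sampling_interval = dt,
                   channel_ids = paste0("s", seq_len(n))),
              class = "timeseries_matrix")
  })
}

#' @export
#' @method simulate lss
#' @rdname simulate_latent
#' @param object,nsim,... standard [stats::simulate()] arguments; `nsim` is
#'   the number of retained samples (`duration = nsim * dt`).
simulate.lss <- function(object, nsim = 1000, seed = NULL, dt = 0.1, ...) {
  simulate_latent(object, duration = nsim * dt, dt = dt, seed = seed, ...)
}

#' @export
print.timeseries_matrix <- function(x, ...) {
  cat(sprintf("timeseries_matrix: %d samples x %d channels at %.4g s\n",
              nrow(x$values), ncol(x$values), x$sampling_interval))
  invisible(x)
}

#' Hemodynamic-like convolution kernel basis
#'
#' Two unit-sum gamma-density kernels peaking at `peaks` seconds, sampled at
#' `dt`; a crude stand-in for a hemodynamic response basis in the synthetic
#' observation model.
#'
#' @param dt sampling interval (s).
#' @param peaks kernel peak times (s).
#' @param len kernel support (s).
#' @return List of numeric kernels (each sums to 1).
#' @export
gamma_kernel_basis <- function(dt, peaks = c(6, 16), len = 32) {
  tt <- seq(0, len, by = dt)
  lapply(peaks, function(p) {
    shape <- 6
    k <- stats::dgamma(tt, shape = shape, rate = shape / p)
    k / sum(k)
  })
}

#' Observation model for synthetic measurements
#'
#' @param kernel_basis list of discrete convolution kernels (each unit-sum),
#'   sampled at the latent step `dt`.
#' @param kernel_coefficients mixing weights `kappa_k`.
#' @param observation_noise observation noise variance (>= 0).
#' @param TR repetition time of the recorded series (s).
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(kernel_basis, kernel_coefficients = NULL,
                              observation_noise = 0, TR = 1) {
  if (TR <= 0) stop("TR must be positive")
  if (!length(kernel_basis)) stop("need at least one basis kernel")
  kernel_coefficients <- kernel_coefficients %||%
    (if (length(kernel_basis) == 1) 1
     else c(0.8, rep(0.2 / (length(kernel_basis) - 1),
                     length(kernel_basis) - 1)))
  if (length(kernel_coefficients) != length(kernel_basis))
    stop("one coefficient per basis kernel required")
  if (observation_noise < 0) stop("observation_noise must be nonnegative")
  structure(list(kernel_basis = kernel_basis,
                 kernel_coefficients = kernel_coefficients,
                 observation_noise = observation_noise, TR = TR),
            class = "observation_model")
}

#' Observe a latent trajectory through a convolution kernel
#'
#' Convolves each channel with `K = sum_k kappa_k K_k` (causal FIR),
#' decimates to the repetition time, and adds white observation noise. With
#' a delta kernel, zero noise and `TR = dt` this is the identity.
#'
#' @param latent a `timeseries_matrix` from [simulate_latent()].
#' @param obs_model an [observation_model()].
#' @param seed integer seed for the observation noise.
#' @return A `timeseries_matrix` sampled at `TR`.
#' @export
observe <- function(latent, obs_model, seed = NULL) {
  stopifnot(inherits(latent, "timeseries_matrix"),
            inherits(obs_model, "observation_model"))
  dt <- latent$sampling_interval
  m <- obs_model$TR / dt
  if (abs(m - round(m)) > 1e-8)
    stop("TR must be an integer multiple of the latent sampling interval")
  m <- as.integer(round(m))
  K <- Reduce(`+`, Map(`*`, obs_model$kernel_coefficients, obs_model$kernel_basis))
  x <- latent$values
  if (nrow(x) < length(K)) stop("latent duration shorter than kernel length")
  conv <- apply(x, 2, function(col)
    stats::filter(col, filter = K, method = "convolution", sides = 1))
  ## causal FIR leaves NA in the first length(K)-1 samples; drop them
  keep <- which(stats::complete.cases(conv))
  conv <- conv[keep, , drop = FALSE]
  dec <- conv[seq(1, nrow(conv), by = m), , drop = FALSE]
  with_seed(seed, {
    if (obs_model$observation_noise > 0)
      dec <- dec + matrix(stats::rnorm(length(dec), 0,
                                       sqrt(obs_model$observation_noise)),
                          nrow(dec), ncol(dec))
    structure(list(values = dec, sampling_interval = obs_model$TR,
                   channel_ids = latent$channel_ids),
              class = "timeseries_matrix")
  })
}
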