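## circulant matrix from its first column
circulant <- function(col) {
  n <- length(col)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) M[, j] <- col[((seq_len(n) - j) %% n) + 1]
  M
}

#' Matrix derivative and convolution operators for the linearized GLM
#'
#' Builds the temporal-derivative operator `D` (central differences scaled
#' by `1/TR`) and the convolution-kernel basis matrices `K_k` as circulant
#' operators on `T` samples, together with the spectra that diagonalize
#' them in the discrete Fourier basis. Circulant operators commute exactly
#' (`K D = D K`), annihilate constants, and make the noise covariance
#' components `K_i K_j'`, `D D'` and `I` jointly diagonal in frequency,
#' which is what the variational scheme exploits.
#'
#' @param T_samples number of samples (>= 8).
#' @param TR sampling interval (s).
#' @param basis_count number of convolution kernels (>= 1); kernels are the
#'   gamma-shaped hemodynamic-like basis of [gamma_kernel_basis()].
#' @param kernel_peaks peak times (s) of the basis kernels.
#' @param scheme difference scheme: `"forward"` (default) or `"central"`.
#'   For diffusion-driven series the forward (one-sided) difference is the
#'   Ito-consistent choice: regressing a *central* difference on the
#'   instantaneous state cancels the dissipative (symmetric) part of the
#'   Jacobian against the within-window noise correlation, leaving only
#'   solenoidal flow identifiable.
#' @param dense also materialize the dense component matrices `K_i K_j'`,
#'   `D D'` (default for small `T_samples`).
#' @return A `glm_operators`: `D`, `kernels` (list of dense matrices),
#'   `spectra` (`d`, `k` list), `components` (named list with `spectrum`
#'   and optional `matrix` per covariance component), `T`, `TR`.
#' @export
build_operators <- function(T_samples, TR, basis_count = 2,
                            kernel_peaks = c(6, 16),
                            scheme = c("forward", "central"),
                            dense = T_samples <= 512) {
  scheme <- match.arg(scheme)
  if (T_samples < 8) stop("need at least 8 samples")
  if (basis_count < 1) stop("basis_count must be >= 1")
  if (TR <= 0) stop("TR must be positive")
  Ts <- as.integer(T_samples)
  dcol <- numeric(Ts)
  if (scheme == "central") {
    ## central difference, periodic boundary: (x[t+1] - x[t-1]) / (2 TR)
    dcol[2] <- -1 / (2 * TR); dcol[Ts] <- 1 / (2 * TR)
  } else {
    ## forward difference, periodic boundary: (x[t+1] - x[t]) / TR
    dcol[1] <- -1 / TR; dcol[Ts] <- 1 / TR
  }
  D <- circulant(dcol)
  dspec <- stats::fft(dcol)
  kp <- rep_len(kernel_peaks, basis_count)
  basis <- gamma_kernel_basis(TR, peaks = kp[seq_len(basis_count)],
                              len = min(32, (Ts - 1) * TR))
  kcols <- lapply(basis, function(k) { v <- numeric(Ts); v[seq_along(k)] <- k; v })
  kernels <- lapply(kcols, circulant)
  kspec <- lapply(kcols, stats::fft)
  comps <- list()
  for (i in seq_len(basis_count)) for (j in i:basis_count) {
    nm <- sprintf("K%dK%d", i, j)
    spec <- if (i == j) Mod(kspec[[i]])^2
            else 2 * Re(kspec[[i]] * Conj(kspec[[j]]))
    comps[[nm]] <- list(
      spectrum = spec,
      matrix = if (dense) {
        M <- kernels[[i]] %*% t(kernels[[j]])
        if (i != j) M <- M + t(M)
        M
      } else NULL)
  }
  comps[["DD"]] <- list(spectrum = Mod(dspec)^2,
                        matrix = if (dense) tcrossprod(D) else NULL)
  comps[["I"]] <- list(spectrum = rep(1, Ts),
                       matrix = if (dense) diag(1, Ts) else NULL)
  structure(list(T = Ts, TR = TR, D = D, kernels = kernels,
                 spectra = list(d = dspec, k = kspec),
                 components = comps, basis_count = basis_count),
            class = "glm_operators")
}

#' @export
print.glm_operators <- function(x, ...) {
  cat(sprintf("glm_operators: T = %d, TR = %g s, %d kernel(s), %d covariance components\n",
              x$T, x$TR, x$basis_count, length(x$components)))
  invisible(x)
}

#' Assemble the linearized general linear model
#'
#' Arranges observed series into the regression `D y = y J' + omega`, whose
#' row-wise solution gives the Jacobian: the response is the temporal
#' derivative of each channel and the design is the (undifferentiated)
#' series itself, optionally augmented with exogenous input regressors. The
#' noise covariance is a mixture of the operator components
#' (`gamma_1 K K' + gamma_2 D D' + gamma_3 I`).
#'
#' @param series `timeseries_matrix` or T x N matrix of observations.
#' @param operators a [build_operators()] object matching `T` and `TR`.
#' @param inputs optional T x K matrix of exogenous inputs (appended to the
#'   design; their coefficients are input effects, not Jacobian entries).
#' @return A `glm_problem` with dense and frequency-domain forms of the
#'   response and design.
#' @export
build_glm_problem <- function(series, operators, inputs = NULL) {
  y <- if (inherits(series, "timeseries_matrix")) series$values else as.matrix(series)
  if (nrow(y) != operators$T) stop("series length does not match operators")
  n <- ncol(y)
  response <- operators$D %*% y
  X <- y
  k <- 0
  if (!is.null(inputs)) {
    inputs <- as.matrix(inputs)
    if (nrow(inputs) != nrow(y)) stop("inputs must have one row per sample")
    X <- cbind(X, inputs)
    k <- ncol(inputs)
  }
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[1] / max(sv[length(sv)], .Machine$double.xmin) > 1e10)
    stop("ill-conditioned design (condition number > 1e10)")
  sq <- sqrt(operators$T)
  structure(list(response = response, design = X,
                 rtilde = stats::mvfft(response) / sq,
                 xtilde = stats::mvfft(X) / sq,
                 n_states = n, n_inputs = k, operators = operators),
            class = "glm_problem")
}

#' Prior specification for row-wise Jacobian estimation
#'
#' Gaussian shrinkage priors: diagonal coupling prior mean `-0.5` Hz
#' (encouraging stability), off-diagonal mean 0, coupling variance 1. The
#' coupling prior is kept diffuse relative to plausible couplings (0.1-1
#' Hz) so that pruning by Bayesian model reduction retains its
#' discriminative power: with a tightly shrunk prior the evidence gain
#' from removing a redundant coupling is bounded by
#' `log(prior sd / posterior sd)` and the 3-nat removal rule could never
#' fire;
#' input-effect priors are zero-mean with unit variance; log-hyperparameter
#' (covariance component scale) priors are Gaussian with mean `-2`,
#' variance 4 (a lognormal prior over the nonnegative scales).
#'
#' @param diag_mean,coupling_var,input_var,hyper_mean,hyper_var prior
#'   moments (see description for defaults).
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(diag_mean = -0.5, coupling_var = 1,
                       input_var = 1, hyper_mean = -2, hyper_var = 4) {
  if (coupling_var <= 0 || input_var <= 0 || hyper_var <= 0)
    stop("prior variances must be positive")
  structure(list(diag_mean = diag_mean, coupling_var = coupling_var,
                 input_var = input_var, hyper_mean = hyper_mean,
                 hyper_var = hyper_var),
            class = "prior_spec")
}

## expand a prior_spec to the moments for one row's coefficient vector
row_prior <- function(priors, n_states, n_inputs, row_index) {
  mu0 <- numeric(n_states + n_inputs)
  mu0[row_index] <- priors$diag_mean
  v0 <- c(rep(priors$coupling_var, n_states), rep(priors$input_var, n_inputs))
  list(mean = mu0, cov = diag(v0, length(v0)), var = v0)
}
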