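#' Modal transfer functions
#'
#' Each eigenvalue `lambda` of a stable linear stochastic system maps random
#' fluctuations to its eigenstate's response with Lorentzian gain
#' `T(f) = 1/(2*pi*i*f - lambda)`; the spectral power transferred is
#' `|T|^2 * 2 Gamma`. Underdamped modes peak at `f = Im(lambda)/(2*pi)`.
#'
#' @param x eigenvalue vector, or a square Jacobian (its eigenvalues are
#'   used).
#' @param freq_grid positive, sorted frequency grid (Hz).
#' @param Gamma per-mode fluctuation amplitude (recycled; default 1).
#' @return A `transfer_function`: list with `freq`, `gain` (modes x freq,
#'   complex), `power`, `peak_freq`, `lambda`.
#' @export
transfer_functions <- function(x, freq_grid, Gamma = 1) {
  lam <- if (is.matrix(x)) eigen_sorted(x)$values else x
  if (any(freq_grid < 0) || is.unsorted(freq_grid))
    stop("freq_grid must be nonnegative and sorted")
  Gamma <- rep_len(Gamma, length(lam))
  gain <- t(vapply(lam, function(l) 1 / (2i * pi * freq_grid - l),
                   complex(length(freq_grid))))
  if (any(!is.finite(Mod(gain))))
    stop("infinite gain: a grid frequency coincides with an undamped mode")
  power <- Mod(gain)^2 * (2 * Gamma)
  structure(list(freq = freq_grid, gain = gain, power = power,
                 peak_freq = pmax(0, Im(lam)) / (2 * pi), lambda = lam),
            class = "transfer_function")
}

#' @export
plot.transfer_function <- function(x, ...) {
  graphics::matplot(x$freq, t(x$power), type = "l", log = "y",
                    xlab = "frequency (Hz)", ylab = "spectral power", ...)
  invisible(x)
}

## Lyapunov solve J S + S J^dagger + 2 Gamma = 0 via the eigenbasis of J,
## with a Kronecker fallback for near-defective J.
solve_lyapunov <- function(J, Gamma) {
  n <- nrow(J)
  G2 <- if (is.matrix(Gamma)) 2 * Gamma else diag(2 * rep_len(Gamma, n), n)
  e <- eigen(J)
  V <- e$vectors
  ok <- tryCatch(cond_svd(V) < 1e10, error = function(e) FALSE)
  if (ok) {
    Vi <- solve(V)
    M <- Vi %*% G2 %*% Conj(t(Vi))
    den <- outer(e$values, Conj(e$values), `+`)
    S <- V %*% (-M / den) %*% Conj(t(V))
  } else {
    A <- diag(1, n) %x% J + Conj(J) %x% diag(1, n)
    S <- matrix(solve(A, -as.vector(G2)), n, n)
  }
  S <- (S + Conj(t(S))) / 2
  if (is.numeric(J) && max(abs(Im(S))) < 1e-10 * max(1, max(abs(Re(S))))) S <- Re(S)
  S
}

#' Stationary covariance of a stable linear stochastic system
#'
#' Solves the Lyapunov equation `J Sigma + Sigma J' + 2 Gamma = 0` for the
#' stationary covariance of `dx = J x dt + sqrt(2 Gamma) dW`, returning the
#' covariance, its inverse (the precision, i.e. the Hessian of the Gaussian
#' surprisal `0.5 x' Pi x`), and the equation residual.
#'
#' @param J stable square Jacobian (`max Re(eig) < 0`).
#' @param Gamma diffusion amplitudes: scalar, vector (diagonal), or matrix.
#' @return A `stationary_covariance`: list with `Sigma`, `Pi`, `residual`.
#' @export
stationary_covariance <- function(J, Gamma = 1) {
  stopifnot_square(J, "J")
  if (max(Re(eigen(J, only.values = TRUE)$values)) >= 0)
    stop("J is not stable: no stationary covariance exists")
  S <- solve_lyapunov(J, Gamma)
  n <- nrow(J)
  G2 <- if (is.matrix(Gamma)) 2 * Gamma else diag(2 * rep_len(Gamma, n), n)
  res <- max(Mod(J %*% S + S %*% Conj(t(J)) + G2)) / max(1, max(Mod(S)))
  if (res > 1e-8)
    warning(sprintf("Lyapunov residual %.2e exceeds 1e-8", res))
  structure(list(Sigma = S, Pi = solve(S), residual = res),
            class = "stationary_covariance")
}

#' @export
print.stationary_covariance <- function(x, ...) {
  cat(sprintf("stationary covariance: %d states, Lyapunov residual %.2e\n",
              nrow(x$Sigma), x$residual))
  invisible(x)
}

#' Stationary cross-covariance functions
#'
#' Computes `C(tau) = E[x(t + tau) x(t)'] = expm(J tau) Sigma` for
#' `tau >= 0` (with `C(-tau) = C(tau)'` at stationarity), either directly
#' through the matrix exponential in the eigenbasis (`"expm"`) or by
#' Wiener-Khinchin inversion of the spectral density
#' `S(w) = (iwI - J)^-1 2Gamma (-iwI - J')^-1` on a dense frequency grid
#' (`"fft"`). The two routes agree to grid resolution; the `"fft"` route
#' subtracts a matched `1/(w^2 + c^2)` asymptote (whose transform is known
#' in closed form) so that truncating the frequency grid costs O(W^-2).
#'
#' @param J stable square Jacobian.
#' @param Gamma diffusion amplitudes.
#' @param lag_grid nonnegative lags (s).
#' @param method `"expm"` or `"fft"`.
#' @param n_freq,omega_max FFT-route grid controls.
#' @return A `cross_covariance`: list with `lags`, `C` (N x N x L array),
#'   `Sigma`, `peak_lag` (N x N matrix of lag of maximum |C_ij|).
#' @export
cross_covariance <- function(J, Gamma = 1, lag_grid = seq(0, 10, by = 0.1),
                             method = c("expm", "fft"),
                             n_freq = 2^17, omega_max = 2048) {
  method <- match.arg(method)
  stopifnot_square(J, "J")
  if (any(lag_grid < 0)) stop("lag_grid must be nonnegative (use C(-tau) = C(tau)')")
  if (max(Re(eigen(J, only.values = TRUE)$values)) >= 0)
    stop("J is not stable: no stationary cross-covariance")
  n <- nrow(J)
  S0 <- solve_lyapunov(J, Gamma)
  e <- eigen(J); V <- e$vectors; Vi <- solve(V)
  L <- length(lag_grid)
  C <- array(0, c(n, n, L))
  if (method == "expm") {
    for (k in seq_len(L)) {
      Ek <- V %*% diag(exp(e$values * lag_grid[k]), n) %*% Vi
      Ck <- Ek %*% S0
      C[, , k] <- Re(Ck)
    }
  } else {
    G2 <- if (is.matrix(Gamma)) 2 * Gamma else diag(2 * rep_len(Gamma, n), n)
    M <- Vi %*% G2 %*% Conj(t(Vi))
    dw <- 2 * omega_max / n_freq
    omega <- -omega_max + dw * (0:(n_freq - 1))
    cc <- 1                                      # asymptote pole (rad/s)
    tau_fft <- (0:(n_freq - 1)) * pi / omega_max # FFT lag grid
    phase <- exp(-1i * omega_max * tau_fft)
    Ct <- array(0 + 0i, c(n, n, L))
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (M[a, b] == 0) next
      f <- 1 / (omega^2 + 1i * omega * (e$values[a] - Conj(e$values[b])) +
                  e$values[a] * Conj(e$values[b]))
      g <- 1 / (omega^2 + cc^2)
      resid_t <- (dw / (2 * pi)) * phase * stats::fft(f - g, inverse = TRUE)
      ## interpolate the FFT lags onto the requested grid, add analytic part
      re <- stats::approx(tau_fft, Re(resid_t), xout = lag_grid)$y
      im <- stats::approx(tau_fft, Im(resid_t), xout = lag_grid)$y
      fab <- complex(real = re, imaginary = im) + exp(-cc * lag_grid) / (2 * cc)
      for (k in seq_len(L)) Ct[a, b, k] <- M[a, b] * fab[k]
    }
    for (k in seq_len(L))
      C[, , k] <- Re(V %*% Ct[, , k] %*% Conj(t(V)))
  }
  peak <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    peak[i, j] <- lag_grid[which.max(abs(C[i, j, ]))]
  structure(list(lags = lag_grid, C = C, Sigma = Re(S0), peak_lag = peak,
                 method = method),
            class = "cross_covariance")
}

#' @export
print.cross_covariance <- function(x, ...) {
  cat(sprintf("cross_covariance (%s): %d states, lags %g..%g s\n",
              x$method, nrow(x$Sigma), min(x$lags), max(x$lags)))
  invisible(x)
}

#' Solenoidal/dissipative decomposition of modal dynamics
#'
#' For each complex eigenvalue `lambda` with fluctuation amplitude `Gamma`,
#' computes the Helmholtz decomposition of the flow at nonequilibrium
#' steady state in the eigenbasis: the dissipation rate
#' `kappa = -Re(lambda)`, the (imaginary) solenoidal operator
#' `Q = -i Im(lambda)/Re(lambda) * Gamma`, the precision `Pi = kappa/Gamma`
#' (positive for stable modes), and the kinetic-energy split
#' `Re(lambda)^2/(2 kappa)` (dissipative) + `Im(lambda)^2/(2 kappa)`
#' (solenoidal) = `|lambda|^2/(2 kappa)` (total, negative for unstable
#' modes). The identities `lambda = (Q - Gamma) Pi` and
#' `lambda Q + Q lambda' = lambda' Gamma - Gamma lambda` are verified to
#' 1e-10.
#'
#' @param lambda complex eigenvalue(s) with nonzero real part.
#' @param Gamma per-mode fluctuation amplitude (> 0, recycled).
#' @return A `helmholtz_summary` data frame with one row per mode.
#' @export
helmholtz <- function(lambda, Gamma = 1) {
  lam <- as.complex(lambda)
  if (any(Re(lam) == 0))
    stop("Re(lambda) = 0: the decomposition divides by the dissipation rate; ",
         "perturb the mode or exclude it")
  G <- rep_len(Gamma, length(lam))
  if (any(G <= 0)) stop("Gamma must be positive")
  kappa <- -Re(lam)
  Q <- -1i * Im(lam) / Re(lam) * G
  Pi <- kappa / G
  id1 <- Mod(lam - (Q - G) * Pi)
  id2 <- Mod(lam * Q + Q * Conj(lam) - (Conj(lam) * G - G * lam))
  if (max(id1) > 1e-10 || max(id2) > 1e-10)
    stop("Helmholtz identities violated beyond 1e-10 (ill-posed input?)")
  out <- data.frame(
    lambda = lam, kappa = kappa, Gamma = G,
    Q_im = Im(Q), Pi = Pi,
    E_dissipative = Re(lam)^2 / (2 * kappa),
    E_solenoidal = Im(lam)^2 / (2 * kappa),
    E_total = Mod(lam)^2 / (2 * kappa),
    identity_residual = pmax(id1, id2))
  class(out) <- c("helmholtz_summary", "data.frame")
  out
}

#' @export
print.helmholtz_summary <- function(x, ...) {
  cat("Helmholtz (solenoidal/dissipative) decomposition per eigenstate:\n")
  df <- data.frame(lambda = format(x$lambda, digits = 3),
                   kappa = signif(x$kappa, 3),
                   E_diss = signif(x$E_dissipative, 3),
                   E_sol = signif(x$E_solenoidal, 3),
                   E_total = signif(x$E_total, 3))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Distance power laws of excitatory and inhibitory coupling
#'
#' Separates positive (excitatory) and negative (inhibitory) real couplings,
#' bins them in equal-width bins of log distance, and regresses the bin
#' means of `log |coupling|` on log distance per sign class; the slopes are
#' the distance scaling exponents. Also tabulates reciprocity: among
#' reciprocal pairs, the fractions that are excitatory both ways,
#' inhibitory both ways, or mixed (antisymmetric).
#'
#' @param J coupling matrix (real part used).
#' @param distances N x N distance matrix (e.g. [mirrored_distances()]).
#' @param n_bins number of log-distance bins (default 8).
#' @param min_per_bin minimum edges for a bin to be reported (default 5).
#' @param tol coupling threshold.
#' @return A `distance_power_law`: per-class exponents, bin tables, and
#'   reciprocity fractions.
#' @export
distance_power_law <- function(J, distances, n_bins = 8, min_per_bin = 5,
                               tol = 1e-6) {
  stopifnot_square(J, "J")
  Jr <- Re(J)
  n <- nrow(Jr)
  off <- which(abs(Jr) > tol & row(Jr) != col(Jr) & distances > 0)
  if (!length(off)) stop("no couplings to bin")
  d <- distances[off]; w <- Jr[off]
  fit_class <- function(sel) {
    if (sum(sel) < 2) return(list(exponent = NA_real_, bins = NULL))
    ld <- log(d[sel]); lw <- log(abs(w[sel]))
    if (max(ld) - min(ld) < 1e-9) {
      bin <- rep(1L, length(ld))
    } else {
      br <- seq(min(ld), max(ld), length.out = n_bins + 1)
      br[1] <- br[1] - 1e-9
      bin <- cut(ld, br, labels = FALSE)
    }
    tab <- do.call(rbind, lapply(unique(bin), function(b) {
      k <- bin == b
      data.frame(bin = b, n = sum(k), log_dist = mean(ld[k]),
                 log_coupling = mean(lw[k]))
    }))
    tab <- tab[tab$n >= min_per_bin, , drop = FALSE]
    if (nrow(tab) < 2) return(list(exponent = NA_real_, bins = tab))
    fit <- stats::lm(log_coupling ~ log_dist, data = tab)
    list(exponent = unname(stats::coef(fit)[2]), bins = tab)
  }
  ex <- fit_class(w > 0)
  ih <- fit_class(w < 0)
  ## reciprocity among pairs coupled in both directions
  recip <- c(ee = 0, ii = 0, mixed = 0)
  npairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(Jr[i, j]) > tol && abs(Jr[j, i]) > tol) {
      npairs <- npairs + 1
      s <- sign(Jr[i, j]) + sign(Jr[j, i])
      if (s == 2) recip["ee"] <- recip["ee"] + 1
      else if (s == -2) recip["ii"] <- recip["ii"] + 1
      else recip["mixed"] <- recip["mixed"] + 1
    }
  }
  structure(list(exponent_excitatory = ex$exponent,
                 exponent_inhibitory = ih$exponent,
                 bins_excitatory = ex$bins, bins_inhibitory = ih$bins,
                 reciprocity = if (npairs) recip / npairs else recip,
                 n_reciprocal_pairs = npairs),
            class = "distance_power_law")
}

#' @export
print.distance_power_law <- function(x, ...) {
  cat(sprintf("distance power law: excitatory exponent %.3f, inhibitory %.3f\n",
              x$exponent_excitatory, x$exponent_inhibitory))
  cat(sprintf("reciprocity: %.0f%% ++, %.0f%% --, %.0f%% mixed (%d pairs)\n",
              100 * x$reciprocity["ee"], 100 * x$reciprocity["ii"],
              100 * x$reciprocity["mixed"], x$n_reciprocal_pairs))
  invisible(x)
}

#' Input-induced responses: impulse kernels, induced variance, F-tests
#'
#' First-order (Volterra) kernels `k(t) = expm(J t) C` quantify the effect
#' of an impulse in each exogenous input on every state over time; the
#' variance induced per state and input is the sum of squared kernel values
#' times `dt`. When an eigenstate series and a design matrix are supplied,
#' each series column is tested against the input block with a standard
#' linear-model F test (constant-only null).
#'
#' @param J stable square Jacobian.
#' @param C N x K input matrix.
#' @param t_grid nonnegative time grid (s) for the kernels.
#' @param series optional T x M matrix of (eigen)state time series.
#' @param design optional T x P design matrix of inputs (a constant column
#'   is appended if absent).
#' @return An `induced_response`: `kernels` (N x K x T array),
#'   `induced_variance` (N x K), and if tested an `ftest` data frame with
#'   `F`, `df1`, `df2`, `p` per series column.
#' @export
induced_responses <- function(J, C, t_grid = seq(0, 60, by = 0.25),
                              series = NULL, design = NULL) {
  stopifnot_square(J, "J")
  C <- as.matrix(C)
  ev <- eigen(J)
  if (max(Re(ev$values)) >= 0)
    warning("J is not stable: kernels will not decay")
  tc <- 1 / abs(Re(ev$values))
  if (max(t_grid) < 5 * max(tc[is.finite(tc)]))
    warning("t_grid shorter than 5 slowest time constants: induced variance truncated")
  Vi <- solve(ev$vectors)
  n <- nrow(J); K <- ncol(C); L <- length(t_grid)
  kern <- array(0, c(n, K, L))
  CiV <- Vi %*% C
  for (k in seq_len(L)) {
    Ek <- ev$vectors %*% (exp(ev$values * t_grid[k]) * CiV)
    kern[, , k] <- Re(Ek)
  }
  dt <- if (L > 1) mean(diff(t_grid)) else 1
  iv <- apply(kern^2, c(1, 2), sum) * dt
  ft <- NULL
  if (!is.null(series)) {
    series <- as.matrix(series); design <- as.matrix(design)
    ## an intercept is always included; constant design columns would be
    ## aliased with it, so drop them
    keep <- apply(design, 2, function(cl) stats::sd(cl) > 0)
    design <- design[, keep, drop = FALSE]
    ft <- do.call(rbind, lapply(seq_len(ncol(series)), function(m) {
      y <- series[, m]
      full <- stats::lm(y ~ design)
      null <- stats::lm(y ~ 1)
      a <- stats::anova(null, full)
      data.frame(state = m, F = a$F[2], df1 = a$Df[2],
                 df2 = a$Res.Df[2], p = a$`Pr(>F)`[2])
    }))
  }
  structure(list(kernels = kern, t_grid = t_grid, induced_variance = iv,
                 ftest = ft),
            class = "induced_response")
}
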