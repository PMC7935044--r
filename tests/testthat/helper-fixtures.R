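## Shared fixture builders. Everything is generated in code; no files.

## small default system on a bilateral grid
quick_system <- function(seed = 1, n_per_hemisphere = 10, spacing = 8,
                         eps_stab = 0.1, ...) {
  g <- make_geometry(n_per_hemisphere, spacing, "grid", seed = seed)
  sample_jacobian(g, seed = seed + 40, eps_stab = eps_stab, ...)
}

## symmetric (detailed-balance) system with scalar diffusion: the stationary
## precision then shares the sparsity pattern of J, so graph separation is
## exact Gaussian conditional independence
symmetric_system <- function(seed, n_max = 12) {
  set.seed(seed)
  n2 <- sample(3:(n_max %/% 2), 1)
  g <- make_geometry(n2, 6, "random", seed = seed)
  sample_jacobian(g, seed = seed + 500, symmetric = TRUE, Gamma = 0.5)
}

## worst absolute partial correlation between internal and external states
## given the particle blankets, from the exact stationary covariance
max_partial_correlation <- function(J, Gamma, partition) {
  S <- stationary_covariance(J, Gamma)$Sigma
  n <- nrow(J)
  worst <- 0
  for (p in partition$particles) {
    mu <- p$internal
    b <- p$blanket
    ext <- setdiff(seq_len(n), c(mu, b))
    if (!length(mu) || !length(ext)) next
    A <- c(mu, ext)
    Sc <- if (length(b))
      S[A, A, drop = FALSE] -
        S[A, b, drop = FALSE] %*% solve(S[b, b, drop = FALSE],
                                        S[b, A, drop = FALSE])
    else S[A, A, drop = FALSE]
    cross <- Sc[seq_along(mu), length(mu) + seq_along(ext), drop = FALSE]
    dd <- sqrt(diag(Sc))
    pc <- cross / outer(dd[seq_along(mu)], dd[length(mu) + seq_along(ext)])
    worst <- max(worst, max(abs(pc)))
  }
  worst
}

## conjugate posterior for a linear-Gaussian model (oracle for bmr tests)
conjugate_posterior <- function(X, y, sigma2, mu0, S0) {
  P0 <- solve(S0)
  P <- crossprod(X) / sigma2 + P0
  S <- solve(P)
  mu <- S %*% (crossprod(X, y) / sigma2 + P0 %*% mu0)
  list(mean = as.numeric(mu), cov = S)
}

## exact log evidence of the same model (for the bmr refit oracle)
log_evidence_lm <- function(X, y, sigma2, mu0, S0) {
  m <- as.numeric(X %*% mu0)
  V <- sigma2 * diag(length(y)) + X %*% S0 %*% t(X)
  -0.5 * (length(y) * log(2 * pi) +
            determinant(V, logarithm = TRUE)$modulus[1] +
            sum((y - m) * solve(V, y - m)))
}

## hand-made posterior object (for reduction edge cases)
manual_posterior <- function(mean_mat, sd = 0.1, prior_var = 1,
                             diag_mean = -0.5, geometry = NULL) {
  n <- nrow(mean_mat)
  rows <- lapply(seq_len(n), function(i) {
    mu0 <- numeric(n); mu0[i] <- diag_mean
    list(mean = mean_mat[i, ], Sigma = diag(sd^2, n), free_energy = 0,
         prior = list(mean = mu0, cov = diag(prior_var, n)),
         converged = TRUE, row_index = i)
  })
  post <- structure(list(mean = mean_mat, rows = rows,
                         support = matrix(TRUE, n, n),
                         input_effects = NULL, free_energy = 0,
                         geometry = geometry,
                         operators = list(T = NA, TR = NA, basis_count = NA),
                         provenance = list()),
                    class = "jacobian_posterior")
  post
}
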