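test_that("derivative operator differentiates and commutes with the kernels", {
  for (scheme in c("forward", "central")) {
    ops <- build_operators(64, 0.5, scheme = scheme)
    cst <- (ops$D %*% rep(3, 64))[2:63]
    expect_lt(max(abs(cst)), 1e-12)                 # constants annihilated
    ramp <- (ops$D %*% (seq_len(64) * 0.5))[5:60]
    expect_lt(max(abs(ramp - 1)), 1e-10)            # d/dt t = 1
    ## commutation with the convolution operators (exact for circulants)
    s <- sin(2 * pi * seq_len(64) / 16)
    K <- ops$kernels[[1]]
    expect_lt(max(abs((K %*% ops$D - ops$D %*% K) %*% s)) / max(abs(s)), 1e-10)
  }
  expect_error(build_operators(4, 1), "8")
  expect_error(build_operators(64, 1, basis_count = 0), "basis_count")
})

test_that("component spectra diagonalize the dense component matrices", {
  ops <- build_operators(32, 1, basis_count = 2)
  Fm <- stats::mvfft(diag(32)) / sqrt(32)           # unitary DFT
  for (nm in names(ops$components)) {
    comp <- ops$components[[nm]]
    Md <- Fm %*% comp$matrix %*% Conj(t(Fm))
    expect_lt(max(Mod(Md - diag(comp$spectrum))), 1e-8)
  }
})

test_that("variational Laplace handles null data and matches GLS when noiseless", {
  set.seed(2)
  n <- 10
  y <- matrix(rnorm(600 * n), 600, n)
  ops <- build_operators(600, 1)
  prob <- build_glm_problem(y, ops)
  ## null response with zero prior means: posterior mean ~ 0, finite F
  prob0 <- prob
  prob0$response <- prob$response * 0
  prob0$rtilde <- prob$rtilde * 0
  f0 <- fit_glm_vl(prob0, priors = prior_spec(diag_mean = 0), row_index = 1)
  expect_lt(max(abs(f0$mean)), 1e-3)
  expect_true(is.finite(f0$free_energy))

  ## noiseless response y J': posterior mean equals the GLS solution
  J <- matrix(rnorm(n * n, 0, 0.2), n, n); diag(J) <- -1
  resp <- y %*% t(J)
  probJ <- prob
  probJ$response <- resp
  probJ$rtilde <- stats::mvfft(resp) / sqrt(600)
  fit <- suppressWarnings(fit_glm_vl(probJ, row_index = 2))
  gls <- qr.solve(y, resp[, 2])
  expect_lt(max(abs(fit$mean[seq_len(n)] - gls)), 0.05)
  ## free energy nondecreasing over accepted iterations
  expect_false(is.unsorted(fit$F_trajectory))
})

test_that("ill-conditioned designs are rejected", {
  y <- matrix(rnorm(100), 100, 1)
  y <- cbind(y, y)                                   # exactly collinear
  ops <- build_operators(100, 1)
  expect_error(build_glm_problem(y, ops), "ill-conditioned")
})

test_that("bmr reproduces closed-form evidence changes", {
  prior <- list(mean = c(0, 0), cov = diag(1, 2))
  set.seed(1)
  X <- matrix(rnorm(80 * 2), 80, 2)
  ## strong support for beta1, none for beta2
  yy <- X %*% c(1.2, 0) + rnorm(80, 0, 0.5)
  post <- conjugate_posterior(X, yy, 0.25, prior$mean, prior$cov)

  ## identity reduction
  id <- bmr(post, prior, prior)
  expect_equal(id$dF, 0, tolerance = 1e-10)
  expect_equal(id$mean, post$mean, tolerance = 1e-10)

  shrink <- function(k) {
    rp <- prior
    rp$cov[k, k] <- 1e-8
    bmr(post, prior, rp)
  }
  expect_gt(shrink(2)$dF, 0)        # redundant parameter: removal favored
  expect_lt(shrink(1)$dF, -3)       # well-supported parameter: removal opposed

  ## refit oracle: dF equals the direct log-evidence difference
  for (k in 1:2) {
    rp <- prior; rp$cov[k, k] <- 1e-8
    direct <- log_evidence_lm(X, yy, 0.25, rp$mean, rp$cov) -
      log_evidence_lm(X, yy, 0.25, prior$mean, prior$cov)
    expect_lt(abs(shrink(k)$dF - direct), 0.1)
  }
  expect_error(bmr(list(mean = 0, cov = matrix(0, 1, 1)), prior, prior),
               "singular")
})

test_that("reciprocal pruning removes planted-zero pairs and keeps strong ones", {
  ## posterior means: pair (1,2) strongly coupled, pair (3,4) zero
  n <- 4
  M <- diag(-0.5, n)
  M[1, 2] <- M[2, 1] <- 0.5
  M[3, 4] <- 0.01; M[4, 3] <- -0.01
  post <- manual_posterior(M, sd = 0.05)
  pruned <- prune_reciprocal(post)
  expect_true(pruned$support[1, 2] && pruned$support[2, 1])
  expect_false(pruned$support[3, 4] || pruned$support[4, 3])
  expect_identical(pruned$mean[3, 4], 0)
  ## retained strong couplings do not flip sign
  expect_gt(pruned$mean[1, 2], 0)
  ## infinite threshold: nothing removed
  expect_equal(sum(prune_reciprocal(post, Inf)$support), n * n)
})

test_that("distance model search finds a planted coupling radius", {
  set.seed(3)
  g <- make_geometry(10, 6, "grid", seed = 2)
  D <- mirrored_distances(g)
  n <- nrow(D)
  ## plant couplings only within 18 mm
  M <- diag(-0.5, n)
  M[D > 0 & D <= 18] <- 0.4
  post <- manual_posterior(M, sd = 0.04, geometry = g)
  ds <- distance_model_search(post, g, radii = seq(10, 32, by = 2),
                              apply = FALSE)
  expect_gte(ds$best_radius, 18)
  expect_lte(ds$best_radius, 22)
  expect_equal(min(ds$profile), 0)

  ## single radius: trivially the best
  one <- distance_model_search(post, g, radii = 32, apply = FALSE)
  expect_equal(one$best_radius, 32)
  expect_error(distance_model_search(post, g, radii = numeric(0)), "nonempty")
  expect_error(distance_model_search(post, g, radii = c(8, 40)), "hard bound")

  ## posterior equal to the prior: flat profile (nothing to prune)
  flat <- manual_posterior(matrix(0, n, n), sd = 1, prior_var = 1,
                           diag_mean = 0, geometry = g)
  for (i in seq_len(n)) flat$rows[[i]]$Sigma <- diag(1, n)
  dsf <- distance_model_search(flat, g, radii = seq(10, 30, by = 10),
                               apply = FALSE)
  expect_lt(max(abs(dsf$evidence)), 1e-6)
})

test_that("estimate_jacobian validates inputs and tracks input effects", {
  expect_error(estimate_jacobian(matrix(1, 100, 1)), "at least 2 states")
  sys <- quick_system(seed = 2, n_per_hemisphere = 3)
  x <- simulate_latent(sys, duration = 30, dt = 0.1, seed = 1)
  u <- matrix(rep(c(0, 1), each = 150), 300, 1)
  post <- suppressWarnings(
    estimate_jacobian(x$values, sys$geometry, inputs = u,
                      config = list(TR = 0.1, passes = 1)))
  expect_equal(dim(post$mean), c(6, 6))
  expect_equal(dim(post$input_effects), c(6, 1))    # inputs kept out of J
  expect_true(is.finite(post$free_energy))
})

test_that("the full estimator recovers a small system's coupling pattern", {
  r <- jacobian_recovery_study(seeds = 1, n_per_hemisphere = 5,
                               T_samples = 600)
  expect_gt(r$correlation, 0.8)
  expect_gt(r$f1, 0.6)
})

test_that("recovery degrades gracefully with heavier measurement noise", {
  r_clean <- jacobian_recovery_study(seeds = 2, n_per_hemisphere = 5,
                                     T_samples = 600, snr = 20)
  r_noisy <- jacobian_recovery_study(seeds = 2, n_per_hemisphere = 5,
                                     T_samples = 600, snr = 1)
  expect_gt(r_clean$correlation, r_noisy$correlation)
  expect_gt(r_noisy$correlation, 0.3)
})
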