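test_that("make_geometry produces mirror-symmetric, deterministic layouts", {
  g <- make_geometry(1, 2, "grid")
  expect_equal(nrow(g$positions), 2L)
  folded <- g$positions
  folded[, 1] <- abs(folded[, 1])
  expect_equal(folded[1, ], folded[2, ])          # homologous pair folds to 0

  g1 <- make_geometry(8, 3, "grid", seed = 1)
  g2 <- make_geometry(8, 3, "grid", seed = 1)
  expect_identical(g1$positions, g2$positions)

  gr <- make_geometry(50, 3, "random", seed = 7)
  d <- plain_distances(gr)
  expect_true(all(d[upper.tri(d)] > 0))
  expect_error(make_geometry(4, -1), "spacing")
})

test_that("sample_jacobian respects the Mexican-hat sign rule and range cutoff", {
  ## two same-hemisphere nodes 5 mm apart, within the excitatory range
  g <- grid_geometry(rbind(c(2, 0, 0), c(2, 5, 0), c(-2, 0, 0), c(-2, 5, 0)),
                     voxel_volume = 27)
  sys <- sample_jacobian(g, coupling = list(density = 1), seed = 3)
  expect_gte(sys$J[1, 2], 0)
  expect_gte(sys$J[2, 1], 0)

  ## density 0: diagonal system with eigenvalues -self_decay
  g2 <- make_geometry(5, 8, "grid", seed = 1)
  d0 <- sample_jacobian(g2, coupling = list(density = 0, self_decay = 0.7))
  expect_equal(d0$J, diag(-0.7, 10))
  expect_equal(eigen(d0$J, only.values = TRUE)$values, rep(-0.7, 10))

  ## stability enforced by dense eigendecomposition on a 100-node system
  g3 <- make_geometry(50, 6, "grid", seed = 2)
  s3 <- sample_jacobian(g3, seed = 9)
  expect_lte(max(Re(eigen(s3$J, only.values = TRUE)$values)), -0.01 + 1e-10)

  ## couplings beyond the inhibitory annulus are exactly zero
  D <- mirrored_distances(g3)
  expect_true(all(s3$J[D > 16 & row(D) != col(D)] == 0))
})

test_that("simulate_latent matches Ornstein-Uhlenbeck closed forms", {
  ## zero noise, zero input, zero start: fixed point
  sys0 <- lss(matrix(-1, 1, 1), Gamma = 0)
  z <- simulate_latent(sys0, duration = 10, dt = 0.1)
  expect_true(all(z$values == 0))

  ## scalar OU: stationary variance Gamma/kappa = 1
  sys1 <- lss(matrix(-1, 1, 1), Gamma = 1)
  x <- simulate_latent(sys1, duration = 4000, dt = 0.02, seed = 5)
  expect_lt(abs(stats::var(x$values[, 1]) - 1), 0.1)

  ## determinism
  a <- simulate_latent(sys1, duration = 20, dt = 0.1, seed = 11)
  b <- simulate_latent(sys1, duration = 20, dt = 0.1, seed = 11)
  expect_identical(a$values, b$values)

  ## unstable systems refuse to integrate unless asked
  bad <- lss(matrix(0.1, 1, 1))
  expect_error(simulate_latent(bad, duration = 10, dt = 0.1), "unstable")
  expect_silent(simulate_latent(bad, duration = 1, dt = 0.01, seed = 1,
                                allow_unstable = TRUE, burn_in = 0))
})

test_that("channel variance is proportional to the characteristic time constant", {
  ## diagonal J: Sigma_nn = Gamma_n / kappa_n
  kap <- c(0.5, 1, 2, 4)
  sys <- lss(diag(-kap), Gamma = 0.5)
  x <- simulate_latent(sys, duration = 6000, dt = 0.02, seed = 2)
  v <- apply(x$values, 2, stats::var)
  expect_lt(max(abs(v - 0.5 / kap) / (0.5 / kap)), 0.15)
})

test_that("observe applies convolution, decimation and noise as specified", {
  sys <- lss(matrix(c(-1, 0.3, 0.2, -1.2), 2, 2), Gamma = 0.5)
  lat <- simulate_latent(sys, duration = 60, dt = 0.1, seed = 3)

  ## delta kernel, zero noise, TR = dt: identity
  om <- observation_model(list(1), observation_noise = 0, TR = 0.1)
  y <- observe(lat, om)
  expect_equal(y$values, lat$values, ignore_attr = TRUE)

  ## constant latent through a unit-sum kernel: same constant (DC gain 1)
  const <- structure(list(values = matrix(2.5, 400, 1), sampling_interval = 0.1,
                          channel_ids = "s1"), class = "timeseries_matrix")
  omk <- observation_model(gamma_kernel_basis(0.1), kernel_coefficients = c(0.8, 0.2),
                           observation_noise = 0, TR = 0.5)
  yc <- observe(const, omk)
  expect_lt(max(abs(yc$values - 2.5)), 1e-8)

  ## TR not a multiple of dt is rejected
  expect_error(observe(lat, observation_model(list(1), TR = 0.25)), "multiple")
})

test_that("white noise through a kernel has the kernel's autocorrelation", {
  set.seed(4)
  Tn <- 40000
  wn <- structure(list(values = matrix(rnorm(Tn), Tn, 1), sampling_interval = 1,
                       channel_ids = "s1"), class = "timeseries_matrix")
  om <- observation_model(gamma_kernel_basis(1), kernel_coefficients = c(0.7, 0.3),
                          observation_noise = 0, TR = 1)
  y <- observe(wn, om)$values[, 1]
  K <- 0.7 * gamma_kernel_basis(1)[[1]] + 0.3 * gamma_kernel_basis(1)[[2]]
  ## FFT oracle: theoretical autocovariance = autocorrelation of the kernel
  theo <- as.numeric(stats::convolve(K, K, type = "open"))[length(K):(length(K) + 5)]
  emp <- stats::acf(y, lag.max = 5, type = "covariance", plot = FALSE)$acf[, 1, 1]
  expect_lt(max(abs(emp - theo)) / theo[1], 0.1)
})

test_that("hierarchical fixture has the planted blanket structure", {
  expect_error(make_hierarchical_system(c(2, 4)), ">= 3")
  expect_error(make_hierarchical_system(c(4, 4), within_strength = 1,
                                        between_strength = 2), "smaller")

  ## disconnected cliques: 2 particles, no sensory states fed externally
  hs0 <- make_hierarchical_system(c(3, 3), between_strength = 0, seed = 1)
  A0 <- adjacency(hs0$system$J)
  expect_equal(length(hs0$partition$particles), 2L)
  relabeled <- classify_blanket(hs0$partition, A0)
  expect_equal(sum(lengths(lapply(relabeled$particles, `[[`, "sensory"))), 0L)

  ## planted internal nodes have no edges outside their particle
  hs <- make_hierarchical_system(c(5, 5), between_strength = 0.2, seed = 2)
  v <- verify_partition(hs$partition, adjacency(hs$system$J))
  expect_true(v$ok)
})

test_that("simulated stationary covariance converges to the Lyapunov solution", {
  sys <- quick_system(seed = 3, n_per_hemisphere = 10)
  S <- stationary_covariance(sys$J, sys$Gamma)$Sigma
  x <- simulate_latent(sys, duration = 4000, dt = 0.1, seed = 8)
  emp <- stats::cov(x$values)
  expect_lt(norm(emp - S, "F") / norm(S, "F"), 0.2)
})
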