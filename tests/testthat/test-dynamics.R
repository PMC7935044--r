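test_that("transfer functions are Lorentzian with the expected peaks", {
  f <- seq(0, 0.2, by = 0.001)
  ## underdamped mode peaks at Im(lambda)/2pi
  tf <- transfer_functions(complex(real = -1, imaginary = 2 * pi * 0.05), f)
  expect_equal(f[which.max(Mod(tf$gain[1, ]))], 0.05, tolerance = 0.002)
  ## overdamped: monotone decreasing from f = 0
  tr <- transfer_functions(-0.5 + 0i, f)
  expect_true(all(diff(Mod(tr$gain[1, ])) < 0))
  ## halving |Re| doubles the peak gain
  g1 <- max(Mod(transfer_functions(-1 + 0i, f)$gain))
  g2 <- max(Mod(transfer_functions(-0.5 + 0i, f)$gain))
  expect_equal(g2 / g1, 2, tolerance = 1e-10)
})

test_that("stationary covariance solves the Lyapunov equation", {
  ## scalar OU closed form
  s1 <- stationary_covariance(matrix(-1, 1, 1), 1)
  expect_equal(s1$Sigma[1, 1], 1, tolerance = 1e-12)
  ## diagonal: variance proportional to the time constant
  kap <- c(0.5, 1, 4); gam <- c(1, 2, 0.5)
  sd <- stationary_covariance(diag(-kap), gam)
  expect_equal(diag(sd$Sigma), gam / kap, tolerance = 1e-12)
  ## random stable system: residual tiny, simulation agrees
  sys <- quick_system(seed = 6, n_per_hemisphere = 5)
  S <- stationary_covariance(sys$J, sys$Gamma)
  expect_lt(S$residual, 1e-8)
  x <- simulate_latent(sys, duration = 5000, dt = 0.05, seed = 2)
  expect_lt(norm(cov(x$values) - S$Sigma, "F") / norm(S$Sigma, "F"), 0.15)
  expect_error(stationary_covariance(matrix(0.1, 1, 1)), "stable")
})

test_that("detailed balance: symmetric coupling gives J = -Gamma Pi and no lag asymmetry", {
  sys <- symmetric_system(5)
  S <- stationary_covariance(sys$J, 0.5)
  expect_lt(max(abs(sys$J + 0.5 * S$Pi)), 1e-8)
  cc <- cross_covariance(sys$J[1:3, 1:3] - diag(0.2, 3), 0.5,
                         lag_grid = seq(0, 8, by = 0.1))
  asym <- max(abs(cc$C - aperm(cc$C, c(2, 1, 3))))
  expect_lt(asym, 1e-10)
})

test_that("cross-covariance matches closed forms and both routes agree", {
  lags <- seq(0, 6, by = 0.05)
  ## scalar OU: C(tau) = exp(-|tau|)
  co <- cross_covariance(matrix(-1, 1, 1), 1, lags)
  expect_lt(max(abs(co$C[1, 1, ] - exp(-lags))), 1e-12)
  ## solenoidal 2x2: peak cross-covariance at nonzero, direction-asymmetric lag
  J <- matrix(c(-1, 0.6, -0.6, -0.8), 2, 2)
  cx <- cross_covariance(J, 1, lags)
  expect_gt(max(cx$peak_lag[1, 2], cx$peak_lag[2, 1]), 0)
  expect_false(isTRUE(all.equal(cx$C[1, 2, ], cx$C[2, 1, ])))
  ## FFT (Wiener-Khinchin) route agrees with the matrix-exponential route
  cf <- cross_covariance(J, 1, lags, method = "fft")
  expect_lt(max(abs(cx$C - cf$C)), 1e-6)
  ## C(0) equals the stationary covariance
  expect_equal(cx$C[, , 1], stationary_covariance(J, 1)$Sigma,
               tolerance = 1e-10)
})

test_that("helmholtz decomposition satisfies the NESS identities", {
  ## direct substitution: lambda = -1 + i, Gamma = 1
  h <- helmholtz(complex(real = -1, imaginary = 1), 1)
  expect_equal(h$Q_im, 1)
  expect_equal(h$Pi, 1)
  expect_equal(h$E_total, 1)
  expect_equal(h$E_dissipative, 0.5)
  expect_equal(h$E_solenoidal, 0.5)
  ## real eigenvalue: no solenoidal flow (detailed balance)
  hr <- helmholtz(-2 + 0i, 0.5)
  expect_equal(hr$Q_im, 0)
  expect_equal(hr$E_solenoidal, 0)
  ## unstable mode: negative kinetic energy
  hu <- helmholtz(0.1 + 0i, 1)
  expect_lt(hu$E_total, 0)
  expect_equal(hu$E_total, 0.01 / (2 * -0.1))
  expect_error(helmholtz(1i, 1), "Re")
})

test_that("modal uncertainty identity: flow variance x state variance = Gamma^2", {
  sys <- symmetric_system(7)
  lam <- eigen(sys$J, only.values = TRUE)$values
  ## in the eigenbasis of a symmetric J with scalar Gamma: Sigma_mode =
  ## Gamma/kappa and E[f f'] = lambda^2 Sigma_mode, so the product is Gamma^2
  gam <- 0.5
  sig_mode <- gam / (-Re(lam))
  flow_var <- Re(lam)^2 * sig_mode
  expect_lt(max(abs(flow_var * sig_mode - gam^2)), 1e-10)
})

test_that("distance power laws are recovered from planted couplings", {
  set.seed(8)
  n <- 40
  pos <- cbind(runif(n, 0, 40), runif(n, 0, 40), runif(n, 0, 40))
  g <- grid_geometry(pos, voxel_volume = 27)
  D <- mirrored_distances(g)
  J <- matrix(0, n, n)
  ## excitatory couplings follow d^-1.14 exactly; inhibitory d^-0.52
  ex <- D > 1 & D <= 15 & row(D) != col(D)
  ih <- D > 15 & D <= 35
  J[ex] <- D[ex]^-1.14
  J[ih] <- -D[ih]^-0.52
  dpl <- distance_power_law(J, D, n_bins = 6)
  expect_equal(dpl$exponent_excitatory, -1.14, tolerance = 1e-6)
  expect_equal(dpl$exponent_inhibitory, -0.52, tolerance = 1e-6)
  ## distance-independent couplings: exponent 0
  J0 <- matrix(0, n, n); J0[ex] <- 0.3
  expect_equal(distance_power_law(J0, D, n_bins = 6)$exponent_excitatory, 0,
               tolerance = 1e-10)
  ## sign classes match a brute-force per-edge scan
  Jm <- J; Jm[2, 1] <- -Jm[1, 2]
  dm <- distance_power_law(Jm, D)
  off <- row(Jm) != col(Jm)
  both <- abs(Jm) > 1e-6 & t(abs(Jm)) > 1e-6 & off
  pairs <- which(both & upper.tri(both), arr.ind = TRUE)
  ss <- sign(Jm[pairs]) + sign(t(Jm)[pairs])
  expect_equal(unname(dm$reciprocity),
               as.numeric(c(mean(ss == 2), mean(ss == -2), mean(abs(ss) < 2))))
})

test_that("reciprocity tabulation reflects the generator's reciprocal probability", {
  sys <- quick_system(seed = 10, n_per_hemisphere = 24, spacing = 6)
  dpl <- distance_power_law(sys$J, mirrored_distances(sys$geometry))
  ## Mexican-hat rule: no mixed-sign reciprocal pairs by construction
  expect_equal(unname(dpl$reciprocity["mixed"]), 0)
  expect_gt(dpl$n_reciprocal_pairs, 10)
})

test_that("induced responses integrate kernels and detect input effects", {
  ## J = -I, impulse on state 1: kernel exp(-t), induced variance 1/2
  J <- diag(-1, 3)
  C <- matrix(c(1, 0, 0), 3, 1)
  ir <- induced_responses(J, C, t_grid = seq(0, 12, by = 0.001))
  expect_equal(ir$kernels[1, 1, 1:3], exp(-c(0, 0.001, 0.002)),
               tolerance = 1e-6)
  expect_equal(ir$induced_variance[1, 1], 0.5, tolerance = 5e-3)
  expect_lt(max(ir$induced_variance[2:3, 1]), 1e-12)

  ## a series equal to a regressor: F off the charts
  set.seed(2)
  u <- cbind(rnorm(100))
  ir2 <- induced_responses(J, C, t_grid = seq(0, 12, by = 0.1),
                           series = cbind(u[, 1], rnorm(100)), design = u)
  expect_gt(ir2$ftest$F[1], qf(1 - 1e-6, 1, 98))
  expect_lt(ir2$ftest$F[2], 10)
})

test_that("input F-tests are calibrated under the null", {
  set.seed(6)
  J <- diag(-1, 2); C <- matrix(1, 2, 1)
  pvals <- replicate(200, {
    y <- rnorm(60)
    u <- cbind(rnorm(60), rnorm(60))
    suppressWarnings(
      induced_responses(J, C, t_grid = seq(0, 8, by = 0.5),
                        series = cbind(y), design = u)$ftest$p[1])
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.125)
})
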