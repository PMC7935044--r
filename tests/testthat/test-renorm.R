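test_that("adiabatic reduction keeps slow modes, pairs, and a fallback", {
  ## diagonal: only the slow mode survives the 1 Hz threshold
  r <- adiabatic_reduce(diag(c(-0.5, -2, -10)))
  expect_equal(r$values, -0.5)
  expect_equal(dim(r$xi), c(3L, 1L))
  expect_lt(max(Mod(r$xi_inv %*% r$xi - diag(1, 1))), 1e-8)

  ## conjugate pair never split at the cap
  rot <- matrix(c(-0.2, 1.3, -1.3, -0.2), 2, 2)
  rp <- adiabatic_reduce(rot, max_modes = 1)
  expect_equal(length(rp$values), 2L)
  expect_equal(rp$values[1], Conj(rp$values[2]))

  ## all modes fast: single slowest mode retained
  rf <- adiabatic_reduce(diag(c(-3, -5, -9)))
  expect_equal(rf$values, -3)
})

test_that("coarse-graining reproduces the eigen-identity on intrinsic blocks", {
  ## single particle holding everything: next scale = retained eigenvalues
  sys <- quick_system(seed = 7, n_per_hemisphere = 4)
  n <- nrow(sys$J)
  whole <- blanketrg:::new_partition(
    list(list(internal = integer(0), sensory = integer(0),
              active = integer(0), blanket = seq_len(n))), n)
  cg <- coarse_grain(sys$J, whole)
  expect_true(all(cg$J_next[row(cg$J_next) != col(cg$J_next)] == 0))
  ## intrinsic identity xi^- J_bb xi = diag(lambda)
  e <- cg$eigens[[1]]
  expect_lt(max(Mod(e$xi_inv %*% sys$J %*% e$xi - diag(e$values,
                                                       length(e$values)))),
            1e-8)

  ## two uncoupled particles: zero extrinsic blocks
  blk <- matrix(0.4, 3, 3); diag(blk) <- -1
  J <- matrix(0, 6, 6); J[1:3, 1:3] <- blk; J[4:6, 4:6] <- blk
  p <- particular_partition(J, n_internal = 1)
  cg2 <- coarse_grain(J, p)
  r1 <- length(cg2$eigens[[1]]$values)
  expect_true(all(Mod(cg2$J_next[seq_len(r1), -seq_len(r1)]) < 1e-12))
})

test_that("run_rg reduces dimension, slows dynamics and is deterministic", {
  sys <- quick_system(seed = 4, n_per_hemisphere = 32, spacing = 6)
  m <- suppressWarnings(run_rg(sys, n_scales = 3, n_internal = 2))
  dims <- vapply(m$scales, `[[`, integer(1), "n_states")
  expect_true(all(diff(dims) < 0))
  expect_true(all(diff(m$provenance$mean_re_lambda) >= -1e-8))
  m2 <- suppressWarnings(run_rg(sys, n_scales = 3, n_internal = 2))
  expect_identical(m$scales[[length(m$scales)]]$J,
                   m2$scales[[length(m2$scales)]]$J)
})

test_that("eigenmode projection chains eigenvectors down to base space", {
  ms <- make_multiscale_system(seed = 2)
  m <- run_rg(ms$system, n_scales = 3, n_internal = ms$n_internal)
  modes <- project_eigenmodes(m)
  expect_equal(length(modes), 3L)
  ## norms bounded by products of block norms (unit-normalized eigenvectors)
  for (i in 2:3) {
    nrm <- apply(Mod(modes[[i]]), 2, function(v) sqrt(sum(v^2)))
    expect_true(all(nrm <= 1 + 1e-8))
  }
  ## disjoint particles have disjoint voxel support at scale 2
  supp <- lapply(seq_len(ncol(modes[[2]])), function(j)
    which(Mod(modes[[2]][, j]) > 1e-10))
  idx <- m$scales[[1]]$reduction$index
  for (a in seq_along(supp)) for (b in seq_along(supp))
    if (idx[a] != idx[b])
      expect_length(intersect(supp[[a]], supp[[b]]), 0)
  ## identity eigenvectors: top-scale modes equal the base loadings
  m_id <- m
  for (i in seq_along(m_id$scales))
    if (!is.null(m_id$scales[[i]]$reduction))
      m_id$scales[[i]]$reduction$eigens <- lapply(
        m_id$scales[[i]]$reduction$eigens, function(e) {
          k <- nrow(e$xi)
          list(values = rep(-1, k), xi = diag(1, k), xi_inv = diag(1, k))
        })
  ## with identity blocks each scale just reindexes the previous support
  modes_id <- project_eigenmodes(m_id, base_modes = diag(1, 80))
  expect_equal(Mod(modes_id[[2]][, 1]),
               as.numeric(seq_len(80) %in% m$scales[[1]]$reduction$supports[[1]][1]) * 1)
})

test_that("particle centers follow the softmax rule and mirror correctly", {
  pos <- rbind(c(2, 0, 0), c(2, 10, 0), c(-2, 0, 0), c(-2, 10, 0))
  g <- grid_geometry(pos, voxel_volume = 8)
  ## equal loading on two voxels: center at the midpoint
  m1 <- matrix(c(1, 1, 0, 0), 4, 1)
  ctr <- particle_centers(m1, g, temperature = 0.02)
  expect_equal(ctr$centers[1, ], c(2, 5, 0), tolerance = 1e-6)
  ## temperature -> 0: argmax voxel
  m2 <- matrix(c(1, 1.2, 0.3, 0), 4, 1)
  ctr2 <- particle_centers(m2, g, temperature = 1e-4)
  expect_equal(ctr2$centers[1, ], pos[2, ])
  ## mirror-symmetric homologous modes: mirrored distance ~ 0
  mh <- cbind(c(1, 0.4, 0, 0), c(0, 0, 1, 0.4))
  ch <- particle_centers(mh, g, temperature = 0.5)
  expect_lt(ch$distances[1, 2], 1e-10)
  expect_error(particle_centers(matrix(0, 4, 1), g), "zero")
})

test_that("scale summaries report time constants and effective extents", {
  ## diagonal system lambda = -2: sigma_tau = 0.5 s
  g <- make_geometry(4, 2, "grid", seed = 1)
  m <- run_rg(diag(-2, 8), geometry = g, n_scales = 1)
  ss <- scale_summaries(m)
  expect_equal(ss$sigma_tau, 0.5)
  ## mode uniform over 8 voxels of 1 mm^3: sigma_len = 2 mm
  g1 <- grid_geometry(cbind(seq_len(8), 0, 0), voxel_volume = 1)
  m1 <- run_rg(diag(-1, 8), geometry = g1, n_scales = 1,
               base_modes = matrix(1 / sqrt(8), 8, 8))
  expect_equal(scale_summaries(m1)$sigma_len, 2)
  ## planted two-scale system: sigma_tau increases with scale
  ms <- make_multiscale_system(seed = 4)
  mm <- run_rg(ms$system, n_scales = 2, n_internal = ms$n_internal)
  sm <- scale_summaries(mm)
  expect_gt(sm$sigma_tau[2], sm$sigma_tau[1])
})

test_that("voxel seeding groups by variance and radius", {
  set.seed(9)
  pos <- cbind(runif(60, 0, 30), runif(60, 0, 30), 0)
  x <- matrix(rnorm(200 * 60), 200, 60)
  x[, 1:10] <- x[, 1:10] * 3
  ## radius larger than the field: a single particle, first PC
  all1 <- seed_particles_from_voxels(x, pos, radius = 100)
  expect_equal(length(all1$groups), 1L)
  pc <- svd(scale(x, scale = FALSE), nu = 1, nv = 0)$u[, 1]
  expect_gt(abs(stats::cor(all1$series[, 1], pc)), 1 - 1e-10)

  ## duplicate columns: the eigenvariate explains all group variance
  dup <- cbind(x[, 1], x[, 1], x[, 1])
  d <- seed_particles_from_voxels(dup, pos[1:3, ], radius = 100)
  expect_equal(d$explained[1], 1, tolerance = 1e-10)

  ## greedy seeding: eigenvariate variance bounded by total voxel variance
  parts <- seed_particles_from_voxels(x, pos, radius = 8)
  expect_lte(sum(apply(parts$series, 2, stats::var)),
             sum(apply(x, 2, stats::var)) + 1e-8)
  ## groups partition the voxels
  expect_setequal(unlist(parts$groups), seq_len(60))
})
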