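#' Block-structured system with a known particular partition
#'
#' Builds a sparse Jacobian whose ground-truth partition is known by
#' construction: each block contributes one particle with one internal
#' state, sensory states that receive the block's external input, and
#' active states that broadcast to the next block. Within a block, sensory
#' states drive the internal state, the internal state drives the active
#' states, and active states feed back onto sensory states; between blocks,
#' active states project to the next block's sensory states (a ring), so
#' internal states touch nothing outside their block and the Markov-blanket
#' condition holds exactly.
#'
#' @param block_sizes integer vector (>= 2 blocks, each size >= 3).
#' @param within_strength coupling scale inside a block (> between).
#' @param between_strength coupling scale of the block-to-block edges; 0
#'   yields disconnected blocks.
#' @param seed integer seed (jitters edge weights).
#' @param self_decay diagonal decay rate (Hz).
#' @return List with `system` (an [lss()]) and `partition` (the planted
#'   ground truth).
#' @export
make_hierarchical_system <- function(block_sizes, within_strength = 1,
                                     between_strength = 0.2, seed = NULL,
                                     self_decay = 2) {
  if (length(block_sizes) < 2) stop("need at least 2 blocks")
  if (any(block_sizes < 3)) stop("each block needs >= 3 states (internal + blanket)")
  if (between_strength >= within_strength)
    stop("between_strength must be smaller than within_strength")
  n <- sum(block_sizes)
  offsets <- cumsum(c(0, block_sizes[-length(block_sizes)]))
  nb <- length(block_sizes)
  with_seed(seed, {
    J <- matrix(0, n, n)
    jit <- function(k) 1 + 0.1 * stats::runif(k, -1, 1)
    particles <- vector("list", nb)
    roles <- vector("list", nb)
    for (b in seq_len(nb)) {
      s <- block_sizes[b]; o <- offsets[b]
      mu <- o + 1L
      ns <- ceiling((s - 1) / 2)
      sens <- o + 1L + seq_len(ns)
      act <- o + 1L + ns + seq_len(s - 1 - ns)
      roles[[b]] <- list(mu = mu, sens = sens, act = act)
      w <- within_strength
      J[mu, sens] <- 1.5 * w * jit(length(sens))   # sensory -> internal
      J[act, mu] <- 1.5 * w * jit(length(act))     # internal -> active
      for (a in act) J[sens, a] <- 0.5 * w * jit(length(sens))  # active -> sensory
      particles[[b]] <- list(internal = mu, sensory = sort(sens),
                             active = sort(act), blanket = sort(c(sens, act)))
    }
    if (between_strength > 0) {
      for (b in seq_len(nb)) {
        nxt <- roles[[b %% nb + 1L]]
        for (a in roles[[b]]$act)
          J[nxt$sens, a] <- between_strength * jit(length(nxt$sens))
      }
    }
    diag(J) <- -self_decay
    for (iter in seq_len(8)) {
      m <- max(Re(eigen(J, only.values = TRUE)$values))
      if (m <= -0.01) break
      J <- J - (m + 0.01) * diag(n)
    }
    ## simple synthetic embedding: blocks spaced far apart on a line
    pos <- matrix(0, n, 3)
    for (b in seq_len(nb)) {
      o <- offsets[b]; s <- block_sizes[b]
      pos[o + seq_len(s), ] <- cbind(5 + (seq_len(s) - 1) * 2, b * 40, 0)
    }
    geom <- grid_geometry(pos, voxel_volume = 8)
    list(system = lss(J, Gamma = 0.5, geometry = geom),
         partition = new_partition(particles, n))
  })
}

#' Planted multiscale system with known scaling behaviour
#'
#' Constructs a spatially embedded system whose renormalization-group
#' decomposition is known analytically: `n_blocks` blocks, each with
#' `n_internal` internal states and a fully coupled 8-state blanket whose
#' slowest eigenmode is uniform with decay rate `kappa1 / 2^alpha`; the
#' blocks' blanket states are mutually coupled so that the next
#' coarse-graining yields a single slow mode with decay rate
#' `kappa1 / (2^alpha * 7^(alpha/3))`. Since the spatial support grows by
#' factors of exactly `8^(1/3) = 2` and `7^(1/3)` per scale (uniform modes
#' over 8 and then 56 voxels), the three per-scale points
#' `(log sigma_ell, log sigma_tau)` are collinear with slope `alpha`:
#' the planted spatiotemporal scaling exponent.
#'
#' @param alpha planted scaling exponent.
#' @param kappa1 base-scale decay rate (Hz); every diagonal entry is
#'   `-kappa1`.
#' @param n_blocks number of blocks (default 8).
#' @param seed integer seed; relative jitter of the couplings makes each
#'   realization distinct while leaving the planted values approximately
#'   intact.
#' @param jitter relative coupling jitter (default 0.03).
#' @return List with `system`, the recommended `n_internal` schedule for
#'   [run_rg()], `alpha` and the planted per-scale `sigma_tau`/`sigma_len`.
#' @export
make_multiscale_system <- function(alpha = 1.2, kappa1 = 4, n_blocks = 8,
                                   seed = NULL, jitter = 0.03) {
  nb <- 8L                    # blanket states per block (4 sensory + 4 active)
  ni <- 2L                    # internal states per block
  spb <- nb + ni
  n <- n_blocks * spb
  kappa2 <- kappa1 / 2^alpha                 # slow rate after first reduction
  kappa3 <- kappa2 / 7^(alpha / 3)           # after second (7 blanket states)
  w_bb <- (kappa1 - kappa2) / (nb - 1)       # within-blanket uniform coupling
  a_x <- (kappa2 - kappa3) / (nb - 2)        # scale-2 extrinsic coupling
  w_x <- a_x * nb / 16                       # per-edge cross-block weight
  with_seed(seed, {
    jit <- function(k) 1 + jitter * stats::rnorm(k)
    J <- matrix(0, n, n)
    for (b in seq_len(n_blocks)) {
      o <- (b - 1L) * spb
      mu <- o + 1:2
      bl <- o + 2L + seq_len(nb)
      sens <- bl[1:4]; act <- bl[5:8]
      ## blanket block: -kappa1 I + w_bb (11' - I), slow uniform mode -kappa2
      Jb <- matrix(w_bb, nb, nb) * matrix(jit(nb * nb), nb, nb)
      Jb <- (Jb + t(Jb)) / 2
      diag(Jb) <- -kappa1
      J[bl, bl] <- Jb
      ## internal circuitry: sensory -> internal -> active, internal pair coupled
      J[mu, sens] <- 1.2 * jit(2 * 4)
      J[act, mu] <- 1.2 * jit(4 * 2)
      J[mu[1], mu[2]] <- 1.2; J[mu[2], mu[1]] <- 1.2
      diag(J)[mu] <- -kappa1
    }
    ## cross-block coupling: active states of m -> sensory states of n, all pairs
    for (b1 in seq_len(n_blocks)) for (b2 in seq_len(n_blocks)) {
      if (b1 == b2) next
      o1 <- (b1 - 1L) * spb; o2 <- (b2 - 1L) * spb
      sens1 <- o1 + 2L + 1:4; act2 <- o2 + 2L + 5:8
      J[sens1, act2] <- w_x * jit(16)
    }
    ## embedding: clustered blocks, unit voxel spacing within a cluster
    pos <- matrix(0, n, 3)
    for (b in seq_len(n_blocks)) {
      o <- (b - 1L) * spb
      th <- 2 * pi * b / n_blocks
      center <- c(40 * cos(th), 40 * sin(th), 0)
      local <- cbind((seq_len(spb) - 1) %% 5, (seq_len(spb) - 1) %/% 5, 0) * 3
      pos[o + seq_len(spb), ] <- sweep(local, 2, center, `+`)
    }
    geom <- grid_geometry(pos, voxel_volume = 27)
    sys <- lss(J, Gamma = 0.5, geometry = geom)
    v13 <- geom$voxel_volume^(1 / 3)
    list(system = sys,
         n_internal = c(2L, 1L),
         alpha = alpha,
         sigma_tau = c(1 / kappa1, 1 / kappa2, 1 / kappa3),
         sigma_len = v13 * c(1, 8^(1 / 3), 56^(1 / 3)))
  })
}
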