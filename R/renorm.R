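## Moore-Penrose pseudo-inverse via SVD (fallback for defective eigenbases)
pinv <- function(M, tol = NULL) {
  s <- svd(M)
  tol <- tol %||% (max(dim(M)) * max(s$d) * .Machine$double.eps)
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * Conj(t(s$u[, pos, drop = FALSE])))
}

#' Adiabatic reduction of a blanket Jacobian
#'
#' Eigendecomposes the Jacobian of a particle's blanket states and retains
#' the slow modes: eigenvalues with `Re(lambda) > -dissipation_threshold`
#' (decay time longer than `1/dissipation_threshold` seconds), sorted by
#' descending real part and capped at `max_modes`. Complex-conjugate pairs
#' are never split at the cap (the cap is relaxed by one if needed). If no
#' mode qualifies, the single slowest mode is retained, so reduction always
#' leaves at least one eigenstate.
#'
#' @param J_blanket square (real or complex) Jacobian of the blanket states.
#' @param dissipation_threshold decay-rate cutoff in Hz (default 1: modes
#'   dissipating within a second are discarded).
#' @param max_modes maximum retained modes (default 8).
#' @return A `particle_eigen`: `values` (retained eigenvalues), `xi`
#'   (blanket-dim x retained eigenvectors), `xi_inv` (left inverse, rows of
#'   the inverse eigenvector matrix).
#' @export
adiabatic_reduce <- function(J_blanket, dissipation_threshold = 1, max_modes = 8) {
  stopifnot_square(J_blanket, "J_blanket")
  e <- eigen_sorted(J_blanket)
  keep <- which(Re(e$values) > -dissipation_threshold)
  if (!length(keep)) keep <- 1L           # fallback: single slowest mode
  if (length(keep) > max_modes) {
    k <- max_modes
    ## do not split a conjugate pair at the cap
    if (Im(e$values[k]) != 0 && k < length(e$values) &&
        abs(e$values[k + 1] - Conj(e$values[k])) <
          1e-8 * (1 + Mod(e$values[k])))
      k <- k + 1L
    keep <- keep[seq_len(k)]
  }
  V <- e$vectors
  cnd <- tryCatch(cond_svd(V), error = function(e) Inf)
  if (!is.finite(cnd) || cnd > 1e12) {
    warning("near-defective eigenbasis; using pseudo-inverse left eigenvectors")
    Vinv <- pinv(V)
  } else {
    Vinv <- solve(V)
  }
  structure(list(values = e$values[keep],
                 xi = V[, keep, drop = FALSE],
                 xi_inv = Vinv[keep, , drop = FALSE]),
            class = "particle_eigen")
}

## reduction support of a particle: its blanket, or all members if the
## blanket is empty (isolated, fully internal particle)
particle_support <- function(particle) {
  if (length(particle$blanket)) particle$blanket
  else sort(c(particle$internal, particle$blanket))
}

#' Coarse-grain one scale: eliminate internal states, retain slow eigenstates
#'
#' Applies the dimension-reduction half of the blocking transformation to a
#' partitioned system: internal states are eliminated (they do not couple
#' particles), each particle's blanket Jacobian is adiabatically reduced,
#' intrinsic blocks of the next-scale Jacobian are the diagonal matrices of
#' retained eigenvalues, and extrinsic blocks are
#' `xi_n^- J(b_n, b_m) xi_m`.
#'
#' @param J scale-i coupling matrix.
#' @param partition a `partition` of the scale-i states.
#' @param dissipation_threshold,max_modes passed to [adiabatic_reduce()].
#' @return List with `J_next` (next-scale coupling matrix, complex),
#'   `eigens` (per-particle `particle_eigen`), `supports` (per-particle
#'   retained state indices) and `index` (mapping of next-scale states to
#'   particles).
#' @export
coarse_grain <- function(J, partition, dissipation_threshold = 1, max_modes = 8) {
  stopifnot(inherits(partition, "partition"))
  np <- length(partition$particles)
  supports <- lapply(partition$particles, particle_support)
  eigens <- lapply(supports, function(b)
    adiabatic_reduce(J[b, b, drop = FALSE], dissipation_threshold, max_modes))
  r <- vapply(eigens, function(e) length(e$values), integer(1))
  offs <- cumsum(c(0L, r[-np]))
  ntot <- sum(r)
  Jn <- matrix(0 + 0i, ntot, ntot)
  for (nn in seq_len(np)) {
    rows <- offs[nn] + seq_len(r[nn])
    Jn[rows, rows] <- diag(eigens[[nn]]$values, nrow = r[nn])
    for (mm in seq_len(np)) {
      if (mm == nn) next
      cols <- offs[mm] + seq_len(r[mm])
      blk <- eigens[[nn]]$xi_inv %*%
        J[supports[[nn]], supports[[mm]], drop = FALSE] %*% eigens[[mm]]$xi
      Jn[rows, cols] <- blk
    }
  }
  list(J_next = Jn, eigens = eigens, supports = supports,
       index = rep(seq_len(np), r))
}

#' Recursive renormalization-group decomposition
#'
#' Alternates the particular partition (grouping) with adiabatic reduction
#' (coarse-graining) starting from a base-scale coupling matrix, recording
#' every scale: its coupling matrix, intrinsic eigenvalues (the diagonal),
#' the partition used, and eigenmodes projected down to the base states.
#' The mean real eigenvalue is checked to be nondecreasing across scales
#' (progressive slowing); a violation triggers a warning and is recorded.
#'
#' @param x an [lss()], or a square coupling matrix.
#' @param geometry a [grid_geometry()] (taken from the `lss` if present).
#' @param n_scales maximum number of scales (>= 1).
#' @param n_internal internal states per particle, per scale (recycled).
#' @param dissipation_threshold,max_modes passed to [adiabatic_reduce()].
#' @param tol adjacency threshold.
#' @param base_modes optional voxels x states matrix of base-scale loadings
#'   (e.g. from [seed_particles_from_voxels()]); defaults to the identity.
#' @return A `multiscale_model`: list of scales with `J`, `lambda`,
#'   `modes`, `partition`, `reduction`; plus `geometry` and `provenance`.
#' @export
run_rg <- function(x, geometry = NULL, n_scales = 3, n_internal = 1,
                   dissipation_threshold = 1, max_modes = 8, tol = 1e-6,
                   base_modes = NULL) {
  if (inherits(x, "lss")) {
    geometry <- geometry %||% x$geometry
    J <- x$J
  } else J <- x
  stopifnot_square(J, "J")
  if (n_scales < 1) stop("n_scales must be >= 1")
  n <- nrow(J)
  n_internal <- rep_len(n_internal, max(1, n_scales - 1))
  modes <- base_modes %||% diag(1, n)
  scales <- list()
  Ji <- J
  for (i in seq_len(n_scales)) {
    sc <- list(index = i, J = Ji, lambda = diag(Ji), modes = modes,
               n_states = ncol(Ji))
    scales[[i]] <- sc
    if (i == n_scales || ncol(Ji) == 1L) break
    part <- particular_partition(Ji, geometry = NULL,
                                 n_internal = n_internal[i], tol = tol)
    red <- coarse_grain(Ji, part, dissipation_threshold, max_modes)
    if (ncol(red$J_next) >= ncol(Ji)) break    # no further reduction possible
    scales[[i]]$partition <- part
    scales[[i]]$reduction <- red
    nm <- matrix(0 + 0i, nrow(modes), ncol(red$J_next))
    offs <- cumsum(c(0L, vapply(red$eigens, function(e)
      length(e$values), integer(1))))
    for (p in seq_along(red$eigens))
      nm[, offs[p] + seq_along(red$eigens[[p]]$values)] <-
        modes[, red$supports[[p]], drop = FALSE] %*% red$eigens[[p]]$xi
    modes <- nm
    Ji <- red$J_next
  }
  slow <- vapply(scales, function(s) mean(Re(s$lambda)), numeric(1))
  if (any(diff(slow) < -1e-8))
    warning("mean Re(eigenvalue) decreased between scales (no slowing)")
  structure(list(scales = scales, geometry = geometry,
                 provenance = list(n_internal = n_internal,
                                   dissipation_threshold = dissipation_threshold,
                                   max_modes = max_modes, tol = tol,
                                   mean_re_lambda = slow)),
            class = "multiscale_model")
}

#' @export
print.multiscale_model <- function(x, ...) {
  cat(sprintf("multiscale_model: %d scale(s)\n", length(x$scales)))
  for (s in x$scales) {
    np <- if (!is.null(s$partition)) length(s$partition$particles) else NA
    cat(sprintf("  scale %d: %d states, mean Re(lambda) = %.4f Hz%s\n",
                s$index, s$n_states, mean(Re(s$lambda)),
                if (!is.na(np)) sprintf(", %d particles", np) else ""))
  }
  invisible(x)
}

#' @export
summary.multiscale_model <- function(object, ...) {
  df <- data.frame(
    scale = vapply(object$scales, `[[`, integer(1), "index"),
    n_states = vapply(object$scales, `[[`, integer(1), "n_states"),
    n_particles = vapply(object$scales, function(s)
      if (is.null(s$partition)) NA_integer_
      else length(s$partition$particles), integer(1)),
    mean_re_lambda = vapply(object$scales, function(s)
      mean(Re(s$lambda)), numeric(1)))
  class(df) <- c("summary.multiscale_model", "data.frame")
  df
}

#' Project eigenmodes of every scale into base (voxel) space
#'
#' Recomputes the chained product of per-particle eigenvector blocks from
#' the base scale upward, so that each eigenstate at each scale has a
#' pattern over the base states (its eigenmode). With identity eigenvectors
#' at every reduction, the top-scale modes equal the base loadings.
#'
#' @param model a `multiscale_model`.
#' @param base_modes optional replacement base loadings.
#' @return List (one element per scale) of voxels x eigenstates matrices.
#' @export
project_eigenmodes <- function(model, base_modes = NULL) {
  stopifnot(inherits(model, "multiscale_model"))
  modes <- base_modes %||% model$scales[[1]]$modes
  out <- list(modes)
  for (i in seq_along(model$scales)) {
    red <- model$scales[[i]]$reduction
    if (is.null(red)) break
    r <- vapply(red$eigens, function(e) length(e$values), integer(1))
    offs <- cumsum(c(0L, r[-length(r)]))
    nm <- matrix(0 + 0i, nrow(modes), sum(r))
    for (p in seq_along(red$eigens)) {
      if (max(red$supports[[p]]) > ncol(modes))
        stop(sprintf("mode/eigenvector shape mismatch between scales %d and %d",
                     i, i + 1))
      nm[, offs[p] + seq_len(r[p])] <-
        modes[, red$supports[[p]], drop = FALSE] %*% red$eigens[[p]]$xi
    }
    modes <- nm
    out[[i + 1]] <- modes
  }
  out
}

#' Anatomical centers of eigenmodes and mirrored distances
#'
#' The center of an eigenstate is its expected location under a probability
#' density given by a softmax of the absolute eigenmode over base states;
#' pairwise Euclidean distances are evaluated after projecting centers
#' across the mirror plane (superimposing homologous locations in the two
#' hemispheres).
#'
#' @param modes voxels x eigenstates matrix (possibly complex).
#' @param geometry a [grid_geometry()] for the base states.
#' @param temperature softmax temperature; default is the standard
#'   deviation of `|mode|` per eigenstate.
#' @return List with `centers` (eigenstates x 3, mm) and `distances`
#'   (mirrored pairwise distances, mm).
#' @export
particle_centers <- function(modes, geometry, temperature = NULL) {
  modes <- as.matrix(modes)
  pos <- geometry$positions
  if (nrow(modes) != nrow(pos)) stop("modes and positions are not conformant")
  k <- ncol(modes)
  centers <- matrix(NA_real_, k, 3)
  for (j in seq_len(k)) {
    a <- Mod(modes[, j])
    if (all(a == 0)) stop(sprintf("eigenmode %d is identically zero", j))
    tj <- temperature %||% stats::sd(a)
    p <- if (is.null(tj) || tj <= 0) {
      w <- as.numeric(a == max(a)); w / sum(w)
    } else softmax(a, tj)
    centers[j, ] <- colSums(p * pos)
  }
  folded <- centers
  folded[, geometry$hemisphere_axis] <- abs(folded[, geometry$hemisphere_axis])
  list(centers = centers, distances = as.matrix(stats::dist(folded)))
}

#' Per-scale characteristic time and length constants
#'
#' The temporal constant of a scale is the mean decay time `-1/Re(lambda)`
#' over its stable eigenstates (unstable modes, `Re(lambda) >= 0`, are
#' retained in the model but excluded from the mean). The spatial constant
#' is the mean effective linear extent of the eigenmodes: the cube root of
#' `voxel_volume x participation_ratio(|mode|)` (`"volume"` method), or
#' twice the weighted RMS dispersion about the mode's centroid
#' (`"caliper"`).
#'
#' @param model a `multiscale_model` with a geometry.
#' @param method `"volume"` (default) or `"caliper"`.
#' @return Data frame with `scale`, `n_states`, `sigma_tau` (s),
#'   `sigma_len` (mm), `n_unstable`.
#' @export
scale_summaries <- function(model, method = c("volume", "caliper")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "multiscale_model"))
  geom <- model$geometry
  if (is.null(geom)) stop("model has no geometry; cannot compute spatial constants")
  vv <- geom$voxel_volume
  rows <- lapply(model$scales, function(s) {
    lam <- s$lambda
    stable <- Re(lam) < 0
    if (!any(stable))
      stop(sprintf("scale %d has no stable modes; no finite time constant", s$index))
    st <- mean(-1 / Re(lam[stable]))
    a <- Mod(s$modes)
    sl <- mean(vapply(seq_len(ncol(a)), function(j) {
      w <- a[, j]
      if (method == "volume") {
        (vv * participation_ratio(w))^(1 / 3)
      } else {
        p <- w^2 / sum(w^2)
        ctr <- colSums(p * geom$positions)
        d2 <- rowSums(sweep(geom$positions, 2, ctr)^2)
        2 * sqrt(sum(p * d2))
      }
    }, numeric(1)))
    data.frame(scale = s$index, n_states = s$n_states,
               sigma_tau = st, sigma_len = sl, n_unstable = sum(!stable))
  })
  do.call(rbind, rows)
}
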