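#' Seed base-scale particles from voxel time series
#'
#' Greedy functional parcellation: repeatedly take the unassigned voxel of
#' largest variance, group it with all unassigned voxels within `radius`
#' mm, summarize the group by its first eigenvariate (first right singular
#' vector of the group's time series, scaled to the first singular value,
#' sign-fixed so the seed voxel loads positively), record the spatial
#' loading, remove the group, and repeat until `n_target` particles exist
#' or voxels are exhausted.
#'
#' @param voxel_series T x V matrix (or `timeseries_matrix`) of voxel time
#'   series.
#' @param voxel_positions V x 3 matrix of voxel coordinates (mm), or a
#'   [grid_geometry()].
#' @param radius grouping radius in mm (default 4).
#' @param n_target maximum number of particles (default 1024).
#' @return List with `series` (T x P eigenvariates), `loadings` (V x P
#'   spatial loading matrix; zero off the group), `groups` (list of voxel
#'   index vectors), `explained` (fraction of group variance captured).
#' @export
seed_particles_from_voxels <- function(voxel_series, voxel_positions,
                                       radius = 4, n_target = 1024) {
  Y <- if (inherits(voxel_series, "timeseries_matrix")) voxel_series$values
       else as.matrix(voxel_series)
  if (!nrow(Y) || !ncol(Y)) stop("empty voxel series")
  pos <- if (inherits(voxel_positions, "grid_geometry")) voxel_positions$positions
         else as.matrix(voxel_positions)
  if (nrow(pos) != ncol(Y)) stop("one position per voxel column required")
  v <- ncol(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  vars <- apply(Yc, 2, stats::var)
  unassigned <- rep(TRUE, v)
  series <- list(); loadings <- list(); groups <- list(); explained <- numeric(0)
  while (any(unassigned) && length(groups) < n_target) {
    seedv <- which(unassigned)[which.max(vars[which(unassigned)])]
    d <- sqrt(rowSums(sweep(pos, 2, pos[seedv, ])^2))
    grp <- which(unassigned & d <= radius)
    sv <- svd(Yc[, grp, drop = FALSE], nu = 1, nv = 1)
    u <- sv$u[, 1] * sv$d[1]
    w <- sv$v[, 1]
    sgn <- sign(w[match(seedv, grp)])
    if (is.na(sgn) || sgn == 0) sgn <- 1
    u <- u * sgn; w <- w * sgn
    load <- numeric(v); load[grp] <- w
    series[[length(series) + 1L]] <- u
    loadings[[length(loadings) + 1L]] <- load
    groups[[length(groups) + 1L]] <- grp
    explained <- c(explained, sv$d[1]^2 / sum(Yc[, grp, drop = FALSE]^2))
    unassigned[grp] <- FALSE
  }
  list(series = do.call(cbind, series),
       loadings = do.call(cbind, loadings),
       groups = groups, explained = explained)
}
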