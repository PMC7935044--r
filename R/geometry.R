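#' Spatial geometry for a set of states
#'
#' A `grid_geometry` holds the anatomical embedding of the states of a
#' spatially extended system: one coordinate (in mm) per state, the volume
#' each state occupies, and the index of the axis that is mirrored when
#' computing homologous (across-hemisphere) distances.
#'
#' @param positions numeric N x 3 matrix of coordinates in mm.
#' @param voxel_volume volume (mm^3) attributed to each state.
#' @param hemisphere_axis index (1-3) of the mirrored axis.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(positions, voxel_volume = 1, hemisphere_axis = 1L) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix (mm)")
  if (nrow(positions) < 2) stop("geometry needs at least 2 positions")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!is.numeric(voxel_volume) || voxel_volume <= 0)
    stop("voxel_volume must be positive")
  structure(
    list(positions = positions, voxel_volume = voxel_volume,
         hemisphere_axis = as.integer(hemisphere_axis)),
    class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d positions, voxel volume %.3g mm^3, mirror axis %d\n",
              nrow(x$positions), x$voxel_volume, x$hemisphere_axis))
  invisible(x)
}

#' Construct a mirror-symmetric set of state positions
#'
#' Builds `2 * n_per_hemisphere` positions arranged symmetrically about the
#' plane `x[hemisphere_axis] = 0`, either on a regular grid or uniformly at
#' random within a cube, emulating the bilateral layout of cortical
#' parcels. The mirrored axis allows homologous pairs (a state and its
#' reflection) to be recognized by near-zero mirrored distance.
#'
#' @param n_per_hemisphere number of states per hemisphere (>= 1).
#' @param spacing grid spacing / length scale in mm (> 0).
#' @param layout `"grid"` or `"random"`.
#' @param seed optional integer seed (used for `"random"` layout).
#' @param hemisphere_axis mirrored axis (default 1).
#' @return A [grid_geometry()].
#' @examples
#' g <- make_geometry(8, 3, "grid")
#' dim(g$positions)
#' @export
make_geometry <- function(n_per_hemisphere, spacing, layout = c("grid", "random"),
                          seed = NULL, hemisphere_axis = 1L) {
  layout <- match.arg(layout)
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive")
  if (n_per_hemisphere < 1) stop("n_per_hemisphere must be >= 1")
  n <- as.integer(n_per_hemisphere)
  half <- with_seed(seed, {
    if (layout == "grid") {
      ## fill a near-cubic lattice, offset from the mirror plane by spacing/2
      k <- ceiling(n^(1 / 3))
      idx <- arrayInd(seq_len(n), .dim = c(k, k, k))
      cbind(spacing / 2 + (idx[, 1] - 1) * spacing,
            (idx[, 2] - 1) * spacing,
            (idx[, 3] - 1) * spacing)
    } else {
      side <- spacing * max(1, ceiling(n^(1 / 3)))
      cbind(stats::runif(n, spacing / 4, side),
            stats::runif(n, 0, side),
            stats::runif(n, 0, side))
    }
  })
  other <- half
  other[, 1] <- -other[, 1]
  pos <- rbind(half, other)
  if (hemisphere_axis != 1L) {         # move mirrored coordinate to requested axis
    perm <- seq_len(3)
    perm[c(1L, hemisphere_axis)] <- perm[c(hemisphere_axis, 1L)]
    pos <- pos[, perm, drop = FALSE]
  }
  grid_geometry(pos, voxel_volume = spacing^3, hemisphere_axis = hemisphere_axis)
}

## fold positions across the mirror plane (take |coordinate| on mirrored axis)
fold_positions <- function(geometry) {
  pos <- geometry$positions
  pos[, geometry$hemisphere_axis] <- abs(pos[, geometry$hemisphere_axis])
  pos
}

#' Pairwise distances between states
#'
#' `mirrored_distances()` evaluates Euclidean distances after projecting all
#' positions across the mirror plane (superimposing homologous locations in
#' the two hemispheres), so that a state and its contralateral homologue are
#' at distance ~0. `plain_distances()` uses the raw coordinates.
#'
#' @param geometry a [grid_geometry()].
#' @return N x N symmetric distance matrix (mm).
#' @export
mirrored_distances <- function(geometry) {
  as.matrix(stats::dist(fold_positions(geometry)))
}

#' @rdname mirrored_distances
#' @export
plain_distances <- function(geometry) {
  as.matrix(stats::dist(geometry$positions))
}

## homologous pairs: mirrored distance below one voxel spacing
homologous_pairs <- function(geometry, spacing = NULL) {
  spacing <- spacing %||% geometry$voxel_volume^(1 / 3)
  dm <- mirrored_distances(geometry)
  dp <- plain_distances(geometry)
  ## homologous: close after folding but not the same location originally
  (dm < spacing) & (dp > spacing / 2)
}
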