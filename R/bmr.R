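#' Bayesian model reduction for Gaussian posteriors
#'
#' Given a Gaussian prior, the corresponding posterior, and a *reduced*
#' prior over the same coordinates, returns the analytic change in log
#' evidence `dF = log p_reduced(y) - log p(y)` and the reduced posterior,
#' without refitting. Reducing with the original prior is the identity
#' (`dF = 0`). A positive `dF` means the reduction (e.g. removing a
#' coupling by shrinking its prior to zero) is favored.
#'
#' @param posterior,prior,reduced_prior lists with `mean` and `cov` over
#'   the same coordinates.
#' @return List with `dF` (nats), `mean`, `cov` of the reduced posterior.
#' @export
bmr <- function(posterior, prior, reduced_prior) {
  as_moments <- function(x, what) {
    if (is.null(x$mean) || is.null(x$cov))
      stop(sprintf("'%s' needs $mean and $cov", what))
    list(mean = as.numeric(x$mean), cov = as.matrix(x$cov))
  }
  po <- as_moments(posterior, "posterior")
  pr <- as_moments(prior, "prior")
  rd <- as_moments(reduced_prior, "reduced_prior")
  d <- length(po$mean)
  inv <- function(M, what) tryCatch(chol2inv(chol(M)), error = function(e)
    stop(sprintf("singular covariance in %s", what), call. = FALSE))
  Pp <- inv(po$cov, "posterior")
  P0 <- inv(pr$cov, "prior")
  Pr <- inv(rd$cov, "reduced prior")
  Pq <- Pp + Pr - P0
  bq <- Pp %*% po$mean + Pr %*% rd$mean - P0 %*% pr$mean
  muq <- tryCatch(solve(Pq, bq), error = function(e)
    stop("reduced posterior precision is singular", call. = FALSE))
  ld <- function(M) determinant(M, logarithm = TRUE)$modulus[1]
  dF <- 0.5 * (ld(Pp) + ld(Pr) - ld(P0) - ld(Pq)) +
    0.5 * (sum(muq * bq) - sum(po$mean * (Pp %*% po$mean)) -
             sum(rd$mean * (Pr %*% rd$mean)) +
             sum(pr$mean * (P0 %*% pr$mean)))
  Sq <- chol2inv(chol(Pq))
  list(dF = as.numeric(dF), mean = as.numeric(muq), cov = (Sq + t(Sq)) / 2)
}

## dF of shrinking a subset of coordinates of one row posterior to zero
## (prior mean 0, prior variance shrink_var)
reduce_row <- function(mean, cov, prior_mean, prior_cov, drop_idx,
                       shrink_var = 1e-8) {
  rd_mean <- prior_mean; rd_cov <- prior_cov
  rd_mean[drop_idx] <- 0
  rd_cov[drop_idx, ] <- 0; rd_cov[, drop_idx] <- 0
  diag(rd_cov)[drop_idx] <- shrink_var
  bmr(list(mean = mean, cov = cov),
      list(mean = prior_mean, cov = prior_cov),
      list(mean = rd_mean, cov = rd_cov))
}

#' Enforce reciprocal coupling by paired Bayesian model reduction
#'
#' For every unordered pair of states, sums the evidence changes for
#' removing the couplings in both directions; if the combined change
#' reaches `threshold_nats` (3 nats, a 20:1 odds ratio, by default) both
#' connections are removed, but not otherwise. All pair decisions are
#' evaluated against the unpruned posterior, so they are
#' order-independent; the removals are then applied jointly per row.
#'
#' @param posterior a `jacobian_posterior` (see [estimate_jacobian()]).
#' @param threshold_nats evidence threshold (default 3).
#' @return The sparsified `jacobian_posterior` (support mask, means and
#'   row covariances updated; removed entries are exactly zero).
#' @export
prune_reciprocal <- function(posterior, threshold_nats = 3) {
  stopifnot(inherits(posterior, "jacobian_posterior"))
  n <- nrow(posterior$mean)
  if (is.infinite(threshold_nats) && threshold_nats > 0) return(posterior)
  dFe <- matrix(0, n, n)     # dF of removing entry (i, j) from row i
  for (i in seq_len(n)) {
    fit <- posterior$rows[[i]]
    for (j in seq_len(n)) {
      if (j == i || !posterior$support[i, j]) next
      dFe[i, j] <- reduce_row(fit$mean, fit$Sigma, fit$prior$mean,
                              fit$prior$cov, j)$dF
    }
  }
  removed <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    present <- posterior$support[i, j] || posterior$support[j, i]
    if (!present) next
    tot <- (if (posterior$support[i, j]) dFe[i, j] else 0) +
      (if (posterior$support[j, i]) dFe[j, i] else 0)
    if (tot >= threshold_nats) {
      removed[i, j] <- posterior$support[i, j]
      removed[j, i] <- posterior$support[j, i]
    }
  }
  posterior <- apply_reduction(posterior, removed)
  posterior$provenance <- c(posterior$provenance,
                            list(list(step = "prune_reciprocal",
                                      threshold_nats = threshold_nats,
                                      n_removed = sum(removed))))
  posterior
}

## apply a joint per-row reduction removing the TRUE entries of `removed`
apply_reduction <- function(posterior, removed) {
  n <- nrow(posterior$mean)
  for (i in seq_len(n)) {
    idx <- which(removed[i, ])
    if (!length(idx)) next
    fit <- posterior$rows[[i]]
    red <- reduce_row(fit$mean, fit$Sigma, fit$prior$mean, fit$prior$cov, idx)
    fit$mean <- red$mean
    fit$mean[idx] <- 0                      # masked entries are exactly zero
    fit$Sigma <- red$cov
    fit$free_energy <- fit$free_energy + red$dF
    posterior$rows[[i]] <- fit
    posterior$mean[i, seq_len(n)] <- fit$mean[seq_len(n)]
    posterior$support[i, idx[idx <= n]] <- FALSE
  }
  posterior$free_energy <- sum(vapply(posterior$rows, `[[`, numeric(1),
                                      "free_energy"))
  posterior
}

#' Evidence for bounded-range coupling: distance model search
#'
#' Scores a family of reduced models that preclude coupling beyond a given
#' radius: for each radius, the couplings spanning a mirrored distance
#' greater than the radius (homologous pairs exempt by default) are shrunk
#' away by Bayesian model reduction and the summed evidence change is
#' recorded. Returns the evidence profile normalized to its minimum and
#' the radius with the greatest evidence (ties within 0.5 nats resolved
#' toward the smallest radius — an Occam preference), and optionally
#' applies the winning reduction.
#'
#' @param posterior a `jacobian_posterior`.
#' @param geometry a [grid_geometry()] for the states.
#' @param radii ascending candidate radii (mm), all `<= hard_bound`.
#' @param hard_bound maximum allowed radius (default 32 mm).
#' @param homologous_exempt exempt homologous (mirror-symmetric) pairs.
#' @param apply if `TRUE` (default), return the posterior reduced at the
#'   best radius alongside the profile.
#' @return List with `radii`, `evidence` (dF per radius), `profile`
#'   (evidence minus its minimum), `best_radius`, and (if `apply`)
#'   `posterior`.
#' @export
distance_model_search <- function(posterior, geometry,
                                  radii = seq(8, 32, by = 4),
                                  hard_bound = 32, homologous_exempt = TRUE,
                                  apply = TRUE) {
  stopifnot(inherits(posterior, "jacobian_posterior"))
  if (!length(radii)) stop("radii must be a nonempty ascending list")
  if (is.unsorted(radii)) stop("radii must be sorted ascending")
  if (any(radii > hard_bound)) stop("radii must not exceed the hard bound")
  n <- nrow(posterior$mean)
  D <- mirrored_distances(geometry)
  H <- homologous_pairs(geometry)
  evid <- numeric(length(radii))
  masks <- vector("list", length(radii))
  for (r in seq_along(radii)) {
    beyond <- D > radii[r] & posterior$support
    diag(beyond) <- FALSE
    if (homologous_exempt) beyond[H] <- FALSE
    masks[[r]] <- beyond
    tot <- 0
    for (i in seq_len(n)) {
      idx <- which(beyond[i, ])
      if (!length(idx)) next
      fit <- posterior$rows[[i]]
      tot <- tot + reduce_row(fit$mean, fit$Sigma, fit$prior$mean,
                              fit$prior$cov, idx)$dF
    }
    evid[r] <- tot
  }
  best <- which(evid >= max(evid) - 0.5)[1]   # smallest radius within 0.5 nats
  out <- list(radii = radii, evidence = evid, profile = evid - min(evid),
              best_radius = radii[best])
  if (apply) {
    posterior <- apply_reduction(posterior, masks[[best]])
    posterior$provenance <- c(posterior$provenance,
                              list(list(step = "distance_model_search",
                                        radii = radii, evidence = evid,
                                        best_radius = radii[best],
                                        n_removed = sum(masks[[best]]))))
    out$posterior <- posterior
  }
  out
}
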