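#' Directed adjacency from a coupling matrix
#'
#' `A[i, j] = 1` iff `i != j` and `|J[i, j]| > tol`: state `j` influences
#' state `i` (the entry `dxdot_i/dx_j` of the Jacobian is nonzero). Self
#' decay (the diagonal) is not an edge. Complex couplings (which arise at
#' coarse-grained scales) are thresholded on their modulus.
#'
#' @param J square coupling matrix (real or complex).
#' @param tol edge threshold in Hz (default 1e-6).
#' @return Binary N x N adjacency matrix.
#' @export
adjacency <- function(J, tol = 1e-6) {
  stopifnot_square(J, "J")
  A <- (Mod(J) > tol) * 1
  diag(A) <- 0
  A
}

#' Markov blanket-forming matrix
#'
#' `B = A + A' + A'A`, thresholded to boolean. Row `n` marks the parents,
#' children and co-parents (parents of the children) of state `n`: the
#' candidate members of its Markov blanket.
#'
#' @param A binary adjacency with `A[i, j] = 1` meaning `j -> i`.
#' @return Binary blanket-forming matrix (diagonal entries from `A'A` are
#'   retained in the matrix but ignored during blanket assembly).
#' @export
blanket_matrix <- function(A) {
  stopifnot_square(A, "A")
  B <- A + t(A) + crossprod(A)    # A'A: co-parents (shared children)
  (B > 0) * 1
}

## graph Laplacian view on the modulus-symmetrized couplings
graph_laplacian <- function(J, tol = 1e-6) {
  W <- Mod(J) + t(Mod(J))
  W[Mod(J) <= tol & t(Mod(J)) <= tol] <- 0
  diag(W) <- 0
  L <- diag(rowSums(W)) - W
  list(L = L, W = W, degree = rowSums(W))
}

## internal partition constructor
new_partition <- function(particles, n_states) {
  assignment <- integer(n_states)
  for (p in seq_along(particles)) {
    pp <- particles[[p]]
    members <- unique(c(pp$internal, pp$blanket, pp$sensory, pp$active))
    assignment[members] <- p
  }
  structure(list(particles = particles, assignment = assignment,
                 n_states = n_states),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d states in %d particles\n",
              x$n_states, length(x$particles)))
  for (p in seq_along(x$particles)) {
    pp <- x$particles[[p]]
    cat(sprintf("  particle %d: %d internal, %d sensory, %d active\n",
                p, length(pp$internal), length(pp$sensory), length(pp$active)))
  }
  invisible(x)
}

#' @export
summary.partition <- function(object, ...) {
  sizes <- vapply(object$particles, function(p)
    length(p$internal) + length(p$sensory) + length(p$active), numeric(1))
  out <- list(n_particles = length(object$particles), sizes = sizes,
              n_states = object$n_states)
  class(out) <- "summary.partition"
  out
}

#' @export
print.summary.partition <- function(x, ...) {
  cat(sprintf("%d particles over %d states; sizes: %s\n",
              x$n_particles, x$n_states, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Particular partition: group states into particles
#'
#' Repeatedly (1) seeds a particle with the eligible unassigned state of
#' largest graph-Laplacian degree, (2) grows the internal set up to
#' `n_internal` states by adding eligible unassigned states whose Laplacian
#' coupling to the seed exceeds a threshold (the 50th percentile of the
#' seed's nonzero couplings), (3) recovers the blanket as the union of the
#' blanket-forming-matrix rows of the internal set (restricted to unassigned
#' states), and (4) appends the particle; when no state is eligible as
#' internal (every remaining state already borders an assigned particle),
#' remaining states are emitted as single-state blanket-only particles.
#' Blanket states are then labelled sensory or active with
#' [classify_blanket()].
#'
#' A state is *eligible* as internal when none of its parents, children or
#' co-parents has been assigned already, so that the full Markov-blanket
#' condition (neighbourhood of every internal state contained in the
#' particle) holds by construction. Ties are broken by lowest state index,
#' making the procedure deterministic.
#'
#' @param J square coupling matrix (real or complex).
#' @param geometry optional [grid_geometry()] (carried through, not used by
#'   the grouping itself).
#' @param n_internal target number of internal states per particle.
#' @param tol edge threshold passed to [adjacency()].
#' @return A `partition` object; each particle has `internal`, `sensory`,
#'   `active` and `blanket` index vectors.
#' @export
particular_partition <- function(J, geometry = NULL, n_internal = 1, tol = 1e-6) {
  stopifnot_square(J, "J")
  n <- nrow(J)
  if (n < 2) stop("need at least 2 states to partition")
  A <- adjacency(J, tol)
  B <- blanket_matrix(A)
  gl <- graph_laplacian(J, tol)
  unassigned <- rep(TRUE, n)
  particles <- list()
  while (any(unassigned)) {
    assigned_idx <- which(!unassigned)
    eligible <- which(unassigned &
                        (if (length(assigned_idx))
                          rowSums(B[, assigned_idx, drop = FALSE]) == 0
                         else rep(TRUE, n)))
    if (length(eligible)) {
      seed <- eligible[order(-gl$degree[eligible], eligible)][1]
      internal <- seed
      if (n_internal > 1) {
        cpl <- gl$W[, seed]              # |L| off-diagonal couplings to seed
        cand <- setdiff(eligible, seed)
        cand <- cand[cpl[cand] > 0]
        if (length(cand)) {
          nz <- cpl[cpl > 0 & seq_len(n) != seed]
          thr <- stats::quantile(nz, 0.5, names = FALSE)
          cand <- cand[cpl[cand] >= thr]
          cand <- cand[order(-cpl[cand], cand)]
          internal <- c(seed, utils::head(cand, n_internal - 1))
        }
      }
      ## B is symmetric (A + A' and A'A both are); row union gives the
      ## candidate blanket of the internal set
      bl <- which(colSums(B[internal, , drop = FALSE]) > 0)
      blanket <- setdiff(intersect(bl, which(unassigned)), internal)
      particles[[length(particles) + 1L]] <-
        list(internal = sort(internal), sensory = integer(0),
             active = integer(0), blanket = sort(blanket))
      unassigned[c(internal, blanket)] <- FALSE
    } else {
      ## blanket-only particle: single state of largest degree
      rem <- which(unassigned)
      seed <- rem[order(-gl$degree[rem], rem)][1]
      particles[[length(particles) + 1L]] <-
        list(internal = integer(0), sensory = integer(0),
             active = integer(0), blanket = seed)
      unassigned[seed] <- FALSE
    }
  }
  part <- new_partition(particles, n)
  part$geometry <- geometry
  classify_blanket(part, A)
}

#' Label blanket states as sensory or active
#'
#' A blanket state is sensory iff it receives an edge from any state outside
#' its particle (it is open to external influence); otherwise it is active
#' (driven only from within the particle). Relabelling is idempotent.
#'
#' @param partition a `partition`.
#' @param A binary adjacency (`A[i, j] = 1` meaning `j -> i`).
#' @return The partition with `sensory`/`active` fields filled in.
#' @export
classify_blanket <- function(partition, A) {
  stopifnot(inherits(partition, "partition"))
  n <- nrow(A)
  for (p in seq_along(partition$particles)) {
    pp <- partition$particles[[p]]
    members <- c(pp$internal, pp$blanket)
    outside <- setdiff(seq_len(n), members)
    sensory <- integer(0); active <- integer(0)
    for (b in pp$blanket) {
      if (length(outside) && any(A[b, outside] > 0)) sensory <- c(sensory, b)
      else active <- c(active, b)
    }
    partition$particles[[p]]$sensory <- sort(sensory)
    partition$particles[[p]]$active <- sort(active)
  }
  partition
}

#' Check partition invariants
#'
#' Verifies, particle by particle, that internal states have no edges (in
#' either direction) to states outside their particle, that every state is
#' assigned to exactly one particle, and that particles are disjoint.
#'
#' @param partition a `partition`.
#' @param A binary adjacency matrix.
#' @return List with `ok` (logical) and `violations` (character vector,
#'   empty on success).
#' @export
verify_partition <- function(partition, A) {
  violations <- character(0)
  n <- nrow(A)
  seen <- integer(n)
  for (p in seq_along(partition$particles)) {
    pp <- partition$particles[[p]]
    members <- c(pp$internal, pp$blanket)
    if (anyDuplicated(members))
      violations <- c(violations, sprintf("particle %d has duplicated members", p))
    seen[members] <- seen[members] + 1L
    outside <- setdiff(seq_len(n), members)
    for (m in pp$internal) {
      bad_out <- outside[A[outside, m] > 0]
      bad_in <- outside[A[m, outside] > 0]
      for (j in bad_out)
        violations <- c(violations,
                        sprintf("internal state %d influences external state %d (particle %d)", m, j, p))
      for (j in bad_in)
        violations <- c(violations,
                        sprintf("internal state %d influenced by external state %d (particle %d)", m, j, p))
    }
  }
  uncovered <- which(seen == 0L)
  if (length(uncovered))
    violations <- c(violations,
                    sprintf("state %d not assigned to any particle", uncovered))
  multi <- which(seen > 1L)
  if (length(multi))
    violations <- c(violations, sprintf("state %d assigned to multiple particles", multi))
  list(ok = length(violations) == 0L, violations = violations)
}
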