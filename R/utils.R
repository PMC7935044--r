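#' @keywords internal
"_PACKAGE"

## Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

## derive a child seed below 2^31 from a base seed and a stage label
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## softmax over a vector, with temperature
softmax <- function(x, temperature = 1) {
  z <- (x - max(x)) / temperature
  e <- exp(z)
  e / sum(e)
}

## participation ratio of a nonnegative weight vector: (sum w^2)^2 / sum w^4.
## For an indicator over k entries this equals k, hence an effective count.
participation_ratio <- function(w) {
  s2 <- sum(w^2)
  if (s2 == 0) return(0)
  s2^2 / sum(w^4)
}

## sorted eigendecomposition with deterministic phase:
## eigenvalues by descending real part (ties: ascending |Im|, then Im),
## each eigenvector rotated so its largest-modulus entry is real positive.
eigen_sorted <- function(M) {
  e <- eigen(M)
  ord <- order(-Re(e$values), abs(Im(e$values)), Im(e$values))
  val <- e$values[ord]
  vec <- e$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vec))) {
    v <- vec[, k]
    i <- which.max(Mod(v))
    ph <- v[i] / Mod(v[i])
    vec[, k] <- v / ph
  }
  list(values = val, vectors = vec)
}

## drop a zero imaginary part
drop_imag <- function(x, tol = 1e-12) {
  if (is.complex(x) && max(abs(Im(x))) <= tol * max(1, max(abs(Re(x))))) Re(x) else x
}

## condition number via SVD (works for complex matrices, unlike kappa())
cond_svd <- function(M) {
  d <- svd(M, nu = 0, nv = 0)$d
  if (!length(d) || min(d) == 0) return(Inf)
  max(d) / min(d)
}

is_square <- function(M) is.matrix(M) && nrow(M) == ncol(M)

stopifnot_square <- function(M, what = "matrix") {
  if (!is_square(M)) stop(sprintf("'%s' must be a square matrix", what), call. = FALSE)
}
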