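#' Fit the spatiotemporal scaling exponent
#'
#' Ordinary least squares of `log(sigma_tau)` on `log(sigma_len)` across
#' scales. The slope is the scaling exponent `alpha` relating temporal to
#' spatial scale (`sigma_tau = gamma * sigma_len^alpha`); the per-step
#' geometric growth factors `exp(beta_tau)` and `exp(beta_len)` are the
#' ratios of successive constants, and `alpha = beta_tau / beta_len` when
#' the factors are constant across scales.
#'
#' @param summaries a data frame from [scale_summaries()], a
#'   `multiscale_model`, or a numeric vector of temporal constants (s).
#' @param sigma_len spatial constants (mm) when `summaries` is a vector.
#' @return A `scaling_fit` with elements `alpha`, `gamma`, `sigma_tau`,
#'   `sigma_len`, `f_tau`/`f_len` (per-step factors), `factors` (their
#'   geometric means), `anchor` (first-scale constants, indexed as scale 0
#'   for extrapolation), and the underlying `lm` fit.
#' @export
fit_scaling <- function(summaries, sigma_len = NULL) {
  if (inherits(summaries, "multiscale_model"))
    summaries <- scale_summaries(summaries)
  if (is.data.frame(summaries)) {
    st <- summaries$sigma_tau; sl <- summaries$sigma_len
  } else {
    st <- as.numeric(summaries); sl <- as.numeric(sigma_len)
  }
  if (length(st) < 2 || length(st) != length(sl))
    stop("need matched sigma_tau and sigma_len for at least 2 scales")
  if (any(st <= 0) || any(sl <= 0)) stop("scale constants must be positive")
  df <- data.frame(lt = log(st), ll = log(sl))
  fit <- stats::lm(lt ~ ll, data = df)
  alpha <- unname(stats::coef(fit)[2])
  gamma <- exp(unname(stats::coef(fit)[1]))
  f_tau <- st[-1] / st[-length(st)]
  f_len <- sl[-1] / sl[-length(sl)]
  structure(list(alpha = alpha, gamma = gamma,
                 sigma_tau = st, sigma_len = sl,
                 f_tau = f_tau, f_len = f_len,
                 factors = c(f_tau = exp(mean(log(f_tau))),
                             f_len = exp(mean(log(f_len)))),
                 anchor = c(sigma_tau0 = st[1], sigma_len0 = sl[1]),
                 lm = fit),
            class = "scaling_fit")
}

#' Scaling fit from explicit anchors and growth factors
#'
#' Convenience constructor when the per-step factors and the scale-0
#' constants are known directly rather than fitted.
#'
#' @param sigma_tau0,sigma_len0 anchors at scale 0 (s, mm).
#' @param f_tau,f_len per-step growth factors `exp(beta_tau)`,
#'   `exp(beta_len)`.
#' @return A `scaling_fit`.
#' @export
scaling_fit_from_anchors <- function(sigma_tau0, sigma_len0, f_tau, f_len) {
  if (any(c(sigma_tau0, sigma_len0, f_tau, f_len) <= 0))
    stop("anchors and factors must be positive")
  structure(list(alpha = log(f_tau) / log(f_len),
                 gamma = sigma_tau0 * sigma_len0^(-log(f_tau) / log(f_len)),
                 sigma_tau = sigma_tau0, sigma_len = sigma_len0,
                 f_tau = f_tau, f_len = f_len,
                 factors = c(f_tau = f_tau, f_len = f_len),
                 anchor = c(sigma_tau0 = sigma_tau0, sigma_len0 = sigma_len0),
                 lm = NULL),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling_fit: alpha = %.3f (sigma_tau = %.3g * sigma_len^alpha)\n",
              x$alpha, x$gamma))
  cat(sprintf("  per-step factors: time x%.3g, space x%.3g\n",
              x$factors["f_tau"], x$factors["f_len"]))
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  c(alpha = object$alpha, gamma = object$gamma,
    f_tau = unname(object$factors["f_tau"]),
    f_len = unname(object$factors["f_len"]))
}

#' Extrapolate characteristic scales beyond the observed range
#'
#' Projects the fitted geometric growth to arbitrary (positive or negative)
#' scale indices: `sigma_tau(i) = sigma_tau(0) * f_tau^i` and
#' `sigma_len(i) = sigma_len(0) * f_len^i`, with the first observed scale
#' anchored at index 0.
#'
#' @param fit a `scaling_fit`.
#' @param scale_indices integer (possibly negative) scale indices.
#' @return Data frame with `scale`, `sigma_len` (mm), `sigma_tau` (s).
#' @export
extrapolate_scales <- function(fit, scale_indices) {
  stopifnot(inherits(fit, "scaling_fit"))
  ft <- unname(fit$factors["f_tau"]); fl <- unname(fit$factors["f_len"])
  data.frame(scale = scale_indices,
             sigma_len = unname(fit$anchor["sigma_len0"]) * fl^scale_indices,
             sigma_tau = unname(fit$anchor["sigma_tau0"]) * ft^scale_indices)
}

#' @export
#' @method predict scaling_fit
#' @rdname extrapolate_scales
#' @param object,... standard predict arguments; `scale_indices` as above.
predict.scaling_fit <- function(object, scale_indices = 0, ...) {
  extrapolate_scales(object, scale_indices)
}

#' @export
plot.scaling_fit <- function(x, ...) {
  if (length(x$sigma_tau) < 2) {
    warning("nothing to plot for an anchors-only fit")
    return(invisible(x))
  }
  graphics::plot(log(x$sigma_len), log(x$sigma_tau),
                 xlab = "log sigma_len (mm)", ylab = "log sigma_tau (s)",
                 pch = 19, ...)
  graphics::abline(log(x$gamma), x$alpha, col = "red3")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("alpha = %.2f", x$alpha))
  invisible(x)
}
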