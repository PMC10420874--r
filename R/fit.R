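#' Exponential decay of transition periods with pulling force
#'
#' Fits trc = A * exp(-k * F) by least squares on the log-transformed
#' periods, i.e. an ordinary linear fit of log(trc) on F. Constant periods
#' give k = 0 exactly; scaling all periods by c scales A by c and leaves k
#' unchanged.
#'
#' @param forces pulling-force magnitudes (m rc/tau^2), length >= 3.
#' @param periods transition periods trc (tau), same length, all > 0.
#' @return An object of class `exp_decay_fit` with components `A`, `k`, the
#'   underlying `lm` fit, and the data. Methods: `print`, `coef`, `predict`,
#'   `residuals`, `plot`, `summary`.
#' @examples
#' f <- seq(0.5, 2, by = 0.25)
#' fit <- fit_exponential_decay(f, 100 * exp(-2 * f))
#' coef(fit) # A = 100, k = 2
#' @export
fit_exponential_decay <- function(forces, periods) {
  forces <- as.numeric(forces); periods <- as.numeric(periods)
  keep <- is.finite(forces) & is.finite(periods)
  forces <- forces[keep]; periods <- periods[keep]
  if (length(forces) < 3) stop("need at least three (force, period) points")
  if (any(periods <= 0)) stop("periods must be positive")
  fit <- lm(log(periods) ~ forces)
  structure(list(A = exp(unname(coef(fit)[1])), k = -unname(coef(fit)[2]),
                 lm = fit, forces = forces, periods = periods),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf("trc(F) = A * exp(-k F):  A = %.6g tau,  k = %.6g (m rc/tau^2)^-1\n",
              x$A, x$k))
  cat(sprintf("  fitted on %d points, residual sd (log scale) = %.3g\n",
              length(x$forces), sqrt(mean(residuals(x$lm)^2))))
  invisible(x)
}

#' @export
coef.exp_decay_fit <- function(object, ...) c(A = object$A, k = object$k)

#' @param object,x an `exp_decay_fit`.
#' @param newdata optional numeric vector of forces to predict at.
#' @param ... unused.
#' @rdname fit_exponential_decay
#' @export
predict.exp_decay_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) object$forces else as.numeric(newdata)
  object$A * exp(-object$k * f)
}

#' @rdname fit_exponential_decay
#' @export
residuals.exp_decay_fit <- function(object, ...) {
  object$periods - predict(object)
}

#' @rdname fit_exponential_decay
#' @export
plot.exp_decay_fit <- function(x, ...) {
  graphics::plot(x$forces, x$periods, log = "y",
                 xlab = "pulling force F (m rc/tau^2)",
                 ylab = "transition period trc (tau)", ...)
  fgrid <- seq(min(x$forces), max(x$forces), length.out = 100)
  graphics::lines(fgrid, predict(x, fgrid), col = 2)
  invisible(x)
}

#' @export
summary.exp_decay_fit <- function(object, ...) {
  s <- summary(object$lm)
  cat(sprintf("Exponential decay fit: A = %.6g, k = %.6g (R^2 = %.3f)\n",
              object$A, object$k, s$r.squared))
  invisible(s)
}
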