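# Model-object methods for rate_fit (the logistic rate estimator).

#' @export
print.rate_fit <- function(x, ...) {
  if (x$no_growth) {
    cat("Autocatalytic rate fit: no growth detected (rate = 0)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Autocatalytic rate fit (window %s, t <= %.3g min):\n  rate |k| = %.4g min^-1 (max slope %.4g %s), x0 = %.4g min, L = %.4g\n",
    x$window_source, x$t_f, x$rate, x$rate_slope, x$rate_slope_units,
    x$x0, x$L))
  invisible(x)
}

#' @export
summary.rate_fit <- function(object, ...) {
  cat("Autocatalytic rate estimate\n")
  cat("  normalisation:", object$normalize, "\n")
  cat("  window source:", object$window_source, "\n")
  if (!is.null(object$gaussian) && isTRUE(object$gaussian$converged))
    cat(sprintf("  difference Gaussian: a1 = %.4g, b1 = %.4g, c1 = %.4g\n",
                object$gaussian$a1, object$gaussian$b1, object$gaussian$c1))
  if (object$no_growth) cat("  no growth detected; rate = 0\n")
  else {
    cat(sprintf("  fit window end t_f = %.4g min (%d samples)\n",
                object$t_f, object$logistic$n))
    cat(sprintf("  rate |k| = %.4g min^-1 (k = %.4g, x0 = %.4g, L = %.4g)\n",
                object$rate, object$k, object$x0, object$L))
    cat(sprintf("  max slope |k|L/4 = %.4g %s\n", object$rate_slope,
                object$rate_slope_units))
    cat(sprintf("  residual rms = %.3g\n", object$quality))
  }
  invisible(object)
}

#' @export
coef.rate_fit <- function(object, ...) {
  c(L = object$L, k = object$k, x0 = object$x0, rate = object$rate,
    t_f = object$t_f)
}

#' @export
predict.rate_fit <- function(object, newdata = NULL, ...) {
  if (object$no_growth)
    stop("predict.rate_fit: no converged logistic model")
  t <- if (is.null(newdata)) object$trace$t
       else if (is.data.frame(newdata)) newdata$t else as.numeric(newdata)
  object$L / (1 + exp(object$k * (t - object$x0)))
}

#' @export
fitted.rate_fit <- function(object, ...) predict(object)

#' @export
residuals.rate_fit <- function(object, ...) {
  sel <- object$trace$t <= object$t_f
  object$trace$A[sel] - predict(object)[sel]
}

#' @export
plot.rate_fit <- function(x, ...) {
  graphics::plot(x$trace$t, x$trace$A, pch = 16, cex = 0.6,
                 xlab = "time (min)",
                 ylab = if (x$trace$normalized) "normalised signal"
                        else "fluorescence (RFU)", ...)
  if (!x$no_growth) {
    tt <- seq(min(x$trace$t), max(x$trace$t), length.out = 200)
    graphics::lines(tt, x$L / (1 + exp(x$k * (tt - x$x0))), col = "red3")
    graphics::abline(v = x$t_f, lty = 2, col = "grey40")
    graphics::legend("topleft", bty = "n", legend = c(
      sprintf("rate = %.3g %s", x$rate, x$rate_units),
      sprintf("t_f = %.3g min (%s)", x$t_f, x$window_source)))
  }
  invisible(x)
}
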