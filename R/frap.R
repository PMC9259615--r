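# FRAP normalisation, recovery fitting, diffusion conversion and the
# partition (sequestration) coefficient.

#' Normalise a raw FRAP measurement
#'
#' Double normalisation: the bleached-region signal is background-corrected
#' and divided by the background-corrected reference region,
#' `I = (raw - background) / (reference - background)`, then rescaled by the
#' pre-bleach mean so the pre-bleach level is 1. In `whole_droplet` mode
#' (transport into a fully bleached droplet) the signal is additionally
#' divided by the background-corrected whole-droplet series before the
#' pre-bleach rescale. Shared gain drift and shared additive offsets cancel.
#'
#' @param raw Bleached-region intensity series.
#' @param background Background series (same time grid).
#' @param reference Reference-region series (same grid);
#'   `reference - background` must be positive everywhere.
#' @param t Sample times (s, strictly increasing).
#' @param t0 Bleach time (s): time of the first post-bleach sample.
#' @param mode "standard" or "whole_droplet".
#' @param whole_droplet Whole-droplet series, required in
#'   `whole_droplet` mode.
#' @return A [frap_trace()].
#' @export
normalize_frap <- function(raw, background, reference, t, t0,
                           mode = c("standard", "whole_droplet"),
                           whole_droplet = NULL) {
  mode <- match.arg(mode)
  n <- length(raw)
  if (length(background) != n || length(reference) != n || length(t) != n)
    stop("normalize_frap: series must share one time grid")
  if (any(reference - background <= 0))
    stop("normalization error: reference must exceed background everywhere")
  I <- (raw - background) / (reference - background)
  if (mode == "whole_droplet") {
    if (is.null(whole_droplet) || length(whole_droplet) != n)
      stop("normalize_frap: 'whole_droplet' series required for this mode")
    wd <- whole_droplet - background
    if (any(wd <= 0))
      stop("normalization error: whole-droplet signal must exceed background")
    I <- I / (wd / (reference - background))
  }
  pre <- I[t < t0]
  if (length(pre) < 1L) stop("normalize_frap: no pre-bleach samples")
  if (mean(pre) <= 0) stop("normalization error: non-positive pre-bleach mean")
  frap_trace(t, I / mean(pre), t0, mode)
}

#' Fit the exponential FRAP recovery model
#'
#' Fits the piecewise recovery `I(t) = 1` before the bleach and
#' `I(t) = 1 - A * exp(-(t - t0)/tau)` after it to the post-bleach samples
#' (the pre-bleach level is fixed at 1 by normalisation). When the
#' two-parameter model is rejected against a free-plateau extension
#' `I(t) = p - B * exp(-(t - t0)/tau)` by an F-ratio on the nested fits at
#' the 5% level, the free-plateau fit is used; its long-time limit gives
#' the immobile fraction
#' `1 - (plateau - I(t0+)) / (1 - I(t0+))`.
#'
#' @param trace A [frap_trace()] with at least 3 pre-bleach and 10
#'   post-bleach samples.
#' @return An object of class `frap_fit`: `A` (bleach depth
#'   `1 - I(t0+)`), `tau` (s), `plateau`, `immobile_fraction` (clamped to
#'   [0, 1]), `immobile_fraction_last` (QC alternative from the mean of the
#'   last 5 samples), `residual_rms`, `model` ("two_parameter" or
#'   "free_plateau").
#' @examples
#' tr <- synthesize_frap_trace(A = 0.8, tau = 5, t0 = 10,
#'                             t_grid = seq(0, 60, 0.5))$trace
#' fit_recovery(tr)
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- trace$t < trace$t0
  post <- !pre
  if (sum(pre) < 3L) stop("fit_recovery: need >= 3 pre-bleach samples")
  if (sum(post) < 10L) stop("fit_recovery: need >= 10 post-bleach samples")
  t <- trace$t[post]; I <- trace$I[post]; t0 <- trace$t0
  if (min(I) > 0.95)
    stop("unidentifiable: no bleach detected (post-bleach minimum > 0.95)")

  A0 <- 1 - min(I)
  plat0 <- mean(I[t >= stats::quantile(t, 0.8)])
  half <- min(I) + (plat0 - min(I)) / 2
  ih <- which(I >= half)
  tau0 <- max(if (length(ih)) t[ih[1L]] - t0 else diff(range(t)) / 4,
              diff(range(t)) / 100)

  fit2 <- tryCatch(
    minpack.lm::nlsLM(I ~ 1 - A * exp(-(t - t0) / tau),
                      start = list(A = A0, tau = tau0),
                      lower = c(0, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  fit3 <- tryCatch(
    minpack.lm::nlsLM(I ~ p - B * exp(-(t - t0) / tau),
                      start = list(p = plat0, B = plat0 - min(I), tau = tau0),
                      lower = c(0, 0, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit2) && is.null(fit3))
    stop("fit_recovery: recovery fit failed to converge")

  use3 <- FALSE
  if (is.null(fit2)) use3 <- TRUE
  else if (!is.null(fit3)) {
    rss2 <- sum(stats::resid(fit2)^2)
    rss3 <- sum(stats::resid(fit3)^2)
    n <- length(I)
    if (rss2 > n * 1e-20 && rss3 < rss2) {
      Fstat <- (rss2 - rss3) / max(rss3 / (n - 3), 1e-300)
      use3 <- stats::pf(Fstat, 1, n - 3) > 0.95
    }
  }

  if (use3) {
    cf <- stats::coef(fit3)
    plateau <- unname(cf["p"])
    I0 <- plateau - unname(cf["B"])
    tau <- unname(cf["tau"])
    rms <- sqrt(mean(stats::resid(fit3)^2))
    model <- "free_plateau"
  } else {
    cf <- stats::coef(fit2)
    tau <- unname(cf["tau"])
    I0 <- 1 - unname(cf["A"])
    plateau <- 1
    rms <- sqrt(mean(stats::resid(fit2)^2))
    model <- "two_parameter"
  }
  A_depth <- 1 - I0
  imm <- if (A_depth > 0) 1 - (plateau - I0) / (1 - I0) else 0
  imm <- min(max(imm, 0), 1)
  last <- mean(utils::tail(I, 5L))
  imm_last <- if (A_depth > 0) min(max(1 - (last - I0) / (1 - I0), 0), 1)
              else 0
  structure(list(A = A_depth, tau = tau, plateau = plateau,
                 immobile_fraction = imm, immobile_fraction_last = imm_last,
                 mobile_fraction = 1 - imm, residual_rms = rms,
                 model = model, t0 = t0, trace = trace),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "FRAP recovery fit (%s): A = %.3g, tau = %.3g s, plateau = %.3g, immobile fraction = %.2g\n",
    x$model, x$A, x$tau, x$plateau, x$immobile_fraction))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(A = object$A, tau = object$tau, plateau = object$plateau,
    immobile_fraction = object$immobile_fraction)
}

#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$trace$t
       else if (is.data.frame(newdata)) newdata$t else as.numeric(newdata)
  ifelse(t < object$t0, 1,
         object$plateau - (object$plateau - (1 - object$A)) *
           exp(-(t - object$t0) / object$tau))
}

#' @export
residuals.frap_fit <- function(object, ...)
  object$trace$I - predict(object)

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$trace$t, x$trace$I, pch = 16, cex = 0.5,
                 xlab = "time (s)", ylab = "normalised intensity", ...)
  tt <- seq(min(x$trace$t), max(x$trace$t), length.out = 400)
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 1.5)
  graphics::abline(v = x$t0, lty = 2, col = "grey50")
  invisible(x)
}

#' Diffusion coefficient from a FRAP time constant
#'
#' Converts the exponential recovery time constant to an apparent
#' diffusion coefficient with the classic half-time relation
#' `D = 0.88 * r^2 / (4 * tau * ln 2)`, where `r` is the bleach-spot
#' radius. The natural logarithm converts the time constant to the
#' half-time `t_1/2 = tau * ln 2`.
#'
#' @param tau Recovery time constant (s, > 0).
#' @param r Bleach-spot radius (um, > 0); always a user input, never
#'   inferred from images.
#' @return Apparent diffusion coefficient (um^2 s^-1).
#' @examples
#' diffusion_coefficient(tau = 1, r = 2)  # 0.88*4/(4*log(2)) ~ 1.2696
#' @export
diffusion_coefficient <- function(tau, r) {
  if (any(tau <= 0)) stop("'tau' must be > 0")
  if (any(r <= 0)) stop("'r' must be > 0")
  0.88 * r^2 / (4 * tau * log(2))
}

#' Aggregate diffusion estimates over bleaching events
#'
#' Converts each event's time constant to a diffusion coefficient and
#' reports the arithmetic mean and sample standard deviation across
#' events (the convention for reporting an apparent D averaged over
#' repeated bleaches).
#'
#' @param fits List of [fit_recovery()] results (>= 2 events).
#' @param r Bleach-spot radius (um), shared across events.
#' @return A `diffusion_estimate` list: `D` (mean, um^2 s^-1), `D_sd`,
#'   `n_events`, `r`, `D_events`.
#' @export
aggregate_frap <- function(fits, r) {
  if (!is.list(fits) || length(fits) < 2L)
    stop("aggregation error: need at least 2 bleaching events")
  taus <- vapply(fits, function(f) {
    if (!inherits(f, "frap_fit")) stop("aggregate_frap: not a frap_fit")
    f$tau
  }, numeric(1))
  D <- diffusion_coefficient(taus, r)
  structure(list(D = mean(D), D_sd = stats::sd(D), n_events = length(D),
                 r = r, D_events = D),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.3g +/- %.2g um^2 s^-1 (n = %d events, r = %g um)\n",
              x$D, x$D_sd, x$n_events, x$r))
  invisible(x)
}

#' Partition (sequestration) coefficient
#'
#' Ratio of the fluorescence intensity inside a proteinosome to the
#' intensity just outside it, `K = F_in / F_out`, computed on raw
#' intensities without background removal.
#'
#' @param F_in Intensity inside the compartment (RFU).
#' @param F_out Intensity outside (RFU, > 0).
#' @return A `partition_measurement` list: `F_in`, `F_out`, `K`.
#' @examples
#' partition_coefficient(57, 10)$K  # 5.7
#' @export
partition_coefficient <- function(F_in, F_out) {
  if (any(F_out <= 0)) stop("'F_out' must be > 0")
  if (any(F_in < 0)) stop("'F_in' must be >= 0")
  structure(list(F_in = F_in, F_out = F_out, K = F_in / F_out),
            class = "partition_measurement")
}

#' @export
print.partition_measurement <- function(x, ...) {
  cat(sprintf("Partition coefficient K = F_in/F_out = %.3g\n", x$K))
  invisible(x)
}
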