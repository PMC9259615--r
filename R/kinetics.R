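# Autocatalytic rate extraction: logistic fit over a data window whose end
# is the half-decay point of a Gaussian fitted to the first differences of
# the fluorescence signal.

#' Normalise a kinetic trace
#'
#' `to_point` divides the whole signal by its value at the sample nearest
#' `t_ref` (the convention used to compare plate-reader and microscope
#' acquisitions of the same reaction). `minmax` maps the baseline (mean of
#' the first 5 samples, truncated to the available points) to 0 and the
#' maximum to 1.
#'
#' @param trace A [kinetic_trace()].
#' @param mode "to_point" or "minmax".
#' @param t_ref Reference time (min) for `to_point`.
#' @return A normalised [kinetic_trace()] (`normalized = TRUE`).
#' @export
normalize_trace <- function(trace, mode = c("to_point", "minmax"),
                            t_ref = max(trace$t)) {
  stopifnot(inherits(trace, "kinetic_trace"))
  mode <- match.arg(mode)
  A <- trace$A
  if (mode == "to_point") {
    ref <- A[which.min(abs(trace$t - t_ref))]
    if (ref <= 0) stop("normalization error: reference value must be > 0")
    A <- A / ref
  } else {
    base <- mean(A[seq_len(min(5L, max(1L, length(A) - 2L)))])
    top <- max(A)
    if (top <= base) stop("normalization error: max must exceed baseline")
    A <- (A - base) / (top - base)
  }
  out <- trace
  out$A <- A
  out$normalized <- TRUE
  out
}

#' Discrete first differences of a trace
#'
#' Numerical differentiation as used before the Gaussian window fit: the
#' raw signal differences between every pair of consecutive time points,
#' located at the interval midpoints. No smoothing is applied by default;
#' an optional 3-point moving average is available.
#'
#' @param trace A [kinetic_trace()] with at least 3 samples.
#' @param smooth If TRUE, apply a 3-point moving average to the differences.
#' @return data.frame with columns `t` (interval midpoints, min) and
#'   `d` (signal change per interval, RFU).
#' @export
difference_series <- function(trace, smooth = FALSE) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (length(trace$t) < 3L)
    stop("difference_series: need at least 3 samples")
  d <- diff(trace$A)
  tm <- (trace$t[-length(trace$t)] + trace$t[-1L]) / 2
  if (smooth && length(d) >= 3L) {
    d <- stats::filter(d, rep(1 / 3, 3), sides = 2)
    keep <- !is.na(d)
    d <- as.numeric(d[keep]); tm <- tm[keep]
  }
  data.frame(t = tm, d = d)
}

#' Fit a Gaussian to a difference series
#'
#' Nonlinear least squares of `a1 * exp(-((x - b1)/c1)^2)` to the first
#' differences, with the peak location bounded to the sampled time range.
#' Initial values: `a1` = the (lightly smoothed) series maximum, `b1` = its
#' location, `c1` = one eighth of the time span. The fit is flagged
#' unconverged when the solver fails or when the amplitude does not clear
#' twice a median-absolute-deviation estimate of the residual noise (a
#' scale-free no-growth guard); a non-positive series yields an unconverged
#' fit rather than an error.
#'
#' @param diff_series data.frame from [difference_series()].
#' @return A `gaussian_diff_fit` list: `a1`, `b1`, `c1`, `converged`,
#'   `f_half` (`a1/2`).
#' @export
fit_gaussian_difference <- function(diff_series) {
  x <- diff_series$t; d <- diff_series$d
  bad <- list(a1 = NA_real_, b1 = NA_real_, c1 = NA_real_,
              converged = FALSE, f_half = NA_real_)
  class(bad) <- "gaussian_diff_fit"
  if (length(d) < 4L || max(d) <= 0) return(bad)
  # initialise from a lightly smoothed series so a single noise spike
  # cannot anchor the peak location
  dsm <- if (length(d) >= 7L) {
    v <- stats::filter(d, rep(1 / 5, 5), sides = 2)
    v[is.na(v)] <- d[is.na(v)]
    as.numeric(v)
  } else d
  a0 <- max(max(dsm), 1e-12); b0 <- x[which.max(dsm)]
  c0 <- (max(x) - min(x)) / 8
  if (c0 <= 0) return(bad)
  # solver bounded to the sampled range: the difference peak must lie
  # inside the data and the width cannot exceed the span
  span <- max(x) - min(x)
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ a1 * exp(-((x - b1) / c1)^2),
                      start = list(a1 = a0, b1 = b0, c1 = c0),
                      lower = c(a1 = 1e-12, b1 = min(x),
                                c1 = min(diff(x)) / 2),
                      upper = c(a1 = 5 * a0, b1 = max(x), c1 = span),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  cf <- stats::coef(fit)
  cf["c1"] <- abs(cf["c1"])
  noise <- stats::mad(stats::resid(fit))
  ok <- is.finite(cf["a1"]) && cf["a1"] > 0 && cf["c1"] > 0 &&
    cf["a1"] > 2 * noise
  structure(list(a1 = unname(cf["a1"]), b1 = unname(cf["b1"]),
                 c1 = unname(cf["c1"]), converged = ok,
                 f_half = unname(cf["a1"]) / 2),
            class = "gaussian_diff_fit")
}

#' @export
print.gaussian_diff_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("Gaussian difference fit: a1 = %.4g, b1 = %.4g min, c1 = %.4g min\n",
                x$a1, x$b1, x$c1))
  else cat("Gaussian difference fit: not converged (no growth detected)\n")
  invisible(x)
}

#' Half-decay time of the fitted difference Gaussian
#'
#' Inverts the Gaussian on its decaying side: the time at which the first
#' differences have fallen to `f` is `b1 + c1 * sqrt(log(a1/f))` (natural
#' logarithm, forced by inverting the Gaussian exponential). With the
#' default `f = a1/2` this is the end of the logistic fit window.
#'
#' @param fit A converged `gaussian_diff_fit`.
#' @param f Threshold on the difference amplitude, `0 < f <= a1`.
#' @return Window end `t_f` (min).
#' @examples
#' # a1 = 2, b1 = 10, c1 = 4, f = 1: 10 + 4*sqrt(log(2)) ~ 13.331
#' @export
midpoint_to_decay <- function(fit, f = fit$a1 / 2) {
  stopifnot(inherits(fit, "gaussian_diff_fit"))
  if (!isTRUE(fit$converged))
    stop("midpoint_to_decay: unconverged Gaussian fit; use the fallback window")
  if (!is.numeric(f) || f <= 0 || f > fit$a1)
    stop("midpoint_to_decay: need 0 < f <= a1")
  fit$b1 + fit$c1 * sqrt(log(fit$a1 / f))
}

#' Fit the logistic growth model over a time window
#'
#' Least squares of the logistic model as conventionally written for these
#' reactions, `A(x) = L / (1 + exp(k * (x - x0)))`, to the samples with
#' `t <= t_f`. In this parameterisation a growing sigmoid has `k < 0`; the
#' reported rate is `|k|` (min^-1). For a normalised trace `L` is fixed
#' at 1, otherwise it is free. Initialisation: `L` = window maximum,
#' `x0` = time of half maximum, `k = -4 * max_slope / L`.
#'
#' @param trace A [kinetic_trace()].
#' @param t_f Window end (min); the window `[0, t_f]` must contain at
#'   least 5 samples.
#' @param L_fixed Override for the fixed-plateau behaviour; default follows
#'   `trace$normalized`.
#' @return A `logistic_fit` list: `L`, `k`, `x0`, `rate` (= `|k|`),
#'   `t_f`, `converged`, `residual_rms`, `n`.
#' @export
fit_logistic <- function(trace, t_f, L_fixed = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  sel <- trace$t <= t_f
  if (sum(sel) < 5L)
    stop("window error: [0, t_f] must contain at least 5 samples")
  x <- trace$t[sel]; A <- trace$A[sel]
  fix_L <- if (is.null(L_fixed)) isTRUE(trace$normalized) else isTRUE(L_fixed)
  out <- list(L = NA_real_, k = NA_real_, x0 = NA_real_, rate = NA_real_,
              t_f = t_f, converged = FALSE, residual_rms = NA_real_,
              n = sum(sel))
  class(out) <- "logistic_fit"
  if (max(A) <= min(A)) return(out)  # no growth in window
  L0 <- if (fix_L) 1 else max(A)
  slope <- max(diff(A) / diff(x))
  if (slope <= 0) return(out)
  x00 <- x[which.min(abs(A - L0 / 2))]
  k0 <- -4 * slope / L0
  fit <- tryCatch({
    if (fix_L)
      minpack.lm::nlsLM(A ~ 1 / (1 + exp(k * (x - x0))),
                        start = list(k = k0, x0 = x00),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    else
      minpack.lm::nlsLM(A ~ L / (1 + exp(k * (x - x0))),
                        start = list(L = L0, k = k0, x0 = x00),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
  }, error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  out$L <- if (fix_L) 1 else unname(cf["L"])
  out$k <- unname(cf["k"])
  out$x0 <- unname(cf["x0"])
  out$rate <- abs(out$k)
  out$residual_rms <- sqrt(mean(stats::resid(fit)^2))
  out$converged <- TRUE
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "Logistic fit (n = %d, t <= %.3g min): rate |k| = %.4g min^-1, x0 = %.4g min, L = %.4g\n",
      x$n, x$t_f, x$rate, x$x0, x$L))
  else cat("Logistic fit: no growth detected in window\n")
  invisible(x)
}

#' Extract the autocatalytic rate of a kinetic trace
#'
#' The full rate pipeline: optional normalisation, first differences,
#' Gaussian fit of the differences, window end at the half-decay of the
#' Gaussian (falling back to a fixed fraction of the trace duration when
#' the Gaussian fit does not converge or yields too short a window), then
#' the windowed logistic fit. Returns a `rate_fit` model object with
#' `print`, `summary`, `coef`, `predict`, `plot`, `residuals` and
#' `fitted` methods.
#'
#' @param trace A [kinetic_trace()].
#' @param normalize Normalisation before fitting: "none" (rates in
#'   RFU min^-1 with free plateau), "minmax" or "to_point" (dimensionless
#'   rates in min^-1 with plateau fixed at 1).
#' @param fallback_t_f Window end used when the Gaussian route fails;
#'   default 60% of the trace duration.
#' @param smooth Passed to [difference_series()].
#' @param flat_threshold Multiple of the difference-series noise estimate
#'   below which the total excursion is classified as no growth.
#' @return An object of class `rate_fit`: the logistic parameters, `rate`
#'   (`|k|`, 0 with `no_growth = TRUE` for flat traces), `window_source`
#'   ("gaussian" or "fallback"), the underlying `gaussian_diff_fit` and
#'   `logistic_fit`, and the (possibly normalised) data.
#' @examples
#' tr <- simulate_bulk_reaction(pen_params(), 1, 1, duration = 120, dt = 1)
#' fit <- estimate_rate(tr)
#' coef(fit)
#' @export
estimate_rate <- function(trace, normalize = c("none", "minmax", "to_point"),
                          fallback_t_f = NULL, smooth = FALSE,
                          flat_threshold = 5) {
  stopifnot(inherits(trace, "kinetic_trace"))
  normalize <- match.arg(normalize)
  work <- switch(normalize,
                 none = trace,
                 minmax = normalize_trace(trace, "minmax"),
                 to_point = normalize_trace(trace, "to_point"))
  baseline <- 0
  if (normalize == "none" && !isTRUE(work$normalized)) {
    # the logistic model has no offset term: subtract the early baseline so
    # the fitted rate is invariant under positive affine signal maps
    baseline <- mean(work$A[seq_len(min(5L, max(1L, length(work$A) - 2L)))])
    work$A <- work$A - baseline
  }
  if (is.null(fallback_t_f)) fallback_t_f <- 0.6 * max(work$t)

  out <- list(trace = work, normalize = normalize, baseline = baseline,
              rate_units = "min^-1",
              rate_slope_units = if (normalize == "none" &&
                                     !isTRUE(trace$normalized))
                "RFU min^-1" else "min^-1",
              rate = NA_real_, rate_slope = NA_real_, k = NA_real_,
              x0 = NA_real_, L = NA_real_,
              t_f = NA_real_, window_source = NA_character_,
              no_growth = FALSE, quality = NA_real_,
              gaussian = NULL, logistic = NULL)
  class(out) <- "rate_fit"

  # flat-trace guard: total excursion against a scale-free noise estimate
  d <- diff(work$A)
  noise <- stats::mad(d) / sqrt(2)
  if (max(work$A) - min(work$A) <= flat_threshold * noise) {
    out$rate <- 0; out$no_growth <- TRUE
    return(out)
  }

  ds <- difference_series(work, smooth = smooth)
  g <- fit_gaussian_difference(ds)
  out$gaussian <- g
  t_f <- NA_real_
  source <- "fallback"
  if (isTRUE(g$converged)) {
    t_try <- midpoint_to_decay(g)
    # a midpoint beyond the sampled range means the decay of the growth
    # rate was never observed: the window is undeterminable, use fallback.
    # The window must also contain a real rise (guards against a Gaussian
    # locking onto an early noise bump and windowing out the growth phase).
    win <- work$A[work$t <= t_try]
    if (t_try <= max(work$t) && length(win) >= 5L &&
        max(win) - min(win) > flat_threshold * noise) {
      t_f <- t_try; source <- "gaussian"
    }
  }
  if (source == "fallback") t_f <- fallback_t_f
  if (sum(work$t <= t_f) < 5L) t_f <- max(work$t)

  lf <- tryCatch(fit_logistic(work, t_f), error = function(e) NULL)
  out$logistic <- lf
  out$t_f <- t_f
  out$window_source <- source
  if (is.null(lf) || !lf$converged) {
    out$rate <- 0; out$no_growth <- TRUE
    return(out)
  }
  out$rate <- lf$rate; out$k <- lf$k; out$x0 <- lf$x0; out$L <- lf$L
  # plateau-scaled slope rate (signal units per min): the maximum slope of
  # the fitted logistic, |k|*L/4
  out$rate_slope <- lf$rate * lf$L / 4
  out$quality <- lf$residual_rms
  out
}

#' Classify the qualitative shape of a kinetic profile
#'
#' Distinguishes switched-off traces (flat), autocatalytic growth
#' (sigmoidal) and linear-node production followed by exonuclease-driven
#' decay (pulse). The trace is smoothed with a 5-point running mean; it is
#' flat when the total excursion does not clear `flat_threshold` times a
#' median-absolute-deviation noise estimate, a pulse when the maximum is
#' followed by a sustained decline of at least 20% of the peak excursion,
#' and sigmoidal otherwise.
#'
#' @param trace A [kinetic_trace()] with at least 10 samples.
#' @param flat_threshold Noise multiple for the flat test.
#' @param decline_frac Fraction of the peak excursion that must be lost
#'   after the maximum to call a pulse.
#' @return One of "flat", "sigmoidal", "pulse".
#' @export
classify_profile <- function(trace, flat_threshold = 5, decline_frac = 0.2) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (length(trace$t) < 10L)
    stop("classify_profile: need at least 10 samples")
  A <- trace$A
  sm <- stats::filter(A, rep(1 / 5, 5), sides = 2)
  sm <- as.numeric(sm[!is.na(sm)])
  noise <- stats::mad(diff(A)) / sqrt(2)
  excursion <- max(sm) - min(sm)
  if (excursion <= flat_threshold * noise) return("flat")
  m <- which.max(sm)
  rise <- sm[m] - sm[1L]
  fall <- sm[m] - min(sm[m:length(sm)])
  if (m < length(sm) && fall >= decline_frac * max(rise, excursion))
    return("pulse")
  "sigmoidal"
}
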