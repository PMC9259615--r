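#' Rate versus template concentration slope (dr/d[T])
#'
#' Ordinary least squares of rate against template concentration, the
#' effect-size summary used to compare compartmentalised and buffer
#' autocatalysis. The slope is in rate units per uM of template.
#'
#' @param template Template concentrations (>= 3 distinct values).
#' @param rate Fitted autocatalytic rates, same length. All rates must be
#'   in the same units (do not mix normalised min^-1 and RFU min^-1 fits).
#' @param intercept Include an intercept (default TRUE).
#' @return A `linear_rate_fit` list: `slope`, `intercept`, `stderr_slope`,
#'   `r_squared`, `n`, plus the underlying `lm` fit.
#' @examples
#' rate_vs_template_slope(c(0.2, 0.4, 0.8), 144.5 * c(0.2, 0.4, 0.8))
#' @export
rate_vs_template_slope <- function(template, rate, intercept = TRUE) {
  template <- as.numeric(template); rate <- as.numeric(rate)
  if (length(template) != length(rate)) stop("lengths differ")
  if (length(template) < 3L) stop("need at least 3 points")
  if (length(unique(template)) < 2L)
    stop("rank error: template values are degenerate")
  fit <- if (intercept) stats::lm(rate ~ template)
         else stats::lm(rate ~ template + 0)
  sm <- summary(fit)
  cf <- sm$coefficients
  row <- "template"
  structure(list(slope = cf[row, "Estimate"],
                 intercept = if (intercept) cf["(Intercept)", "Estimate"] else 0,
                 stderr_slope = cf[row, "Std. Error"],
                 r_squared = sm$r.squared, n = length(template), lm = fit),
            class = "linear_rate_fit")
}

#' @export
print.linear_rate_fit <- function(x, ...) {
  cat(sprintf("dr/d[T] = %.4g +/- %.2g per uM (n = %d, R^2 = %.3f)\n",
              x$slope, x$stderr_slope, x$n, x$r_squared))
  invisible(x)
}

# Tukey box statistics: quartiles, adjacent values at 1.5 x IQR, outside
# points beyond the fences.
.box_stats <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  inside <- v[v >= lo & v <= hi]
  list(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
       lower_adjacent = min(inside), upper_adjacent = max(inside),
       outside_points = sort(v[v < lo | v > hi]))
}

#' Population kinetics: mean profiles and rate box statistics
#'
#' Groups traces by population label, computes the pointwise mean and
#' standard deviation of the signal across each group (the bold line and
#' shaded band of a population kinetic plot), extracts a rate per trace
#' with [estimate_rate()] and summarises the group's rates with Tukey box
#' statistics (median, quartiles, adjacent values at 1.5 x IQR, outside
#' points).
#'
#' @param traces List of [kinetic_trace()] objects (or a [trace_set()]).
#' @param time_grid Common grid; traces on other grids are resampled by
#'   linear interpolation. Defaults to the first trace's grid.
#' @param ... Passed to [estimate_rate()].
#' @return A `population_kinetics` list with one entry per population:
#'   `profile` (data.frame `t`, `mean`, `sd`, `n`), `rates` (per-trace),
#'   and `summary` (the box statistics).
#' @export
population_kinetics <- function(traces, time_grid = NULL, ...) {
  if (inherits(traces, "trace_set")) traces <- traces$traces
  if (!is.list(traces) || length(traces) == 0L)
    stop("population_kinetics: empty trace group")
  pops <- vapply(traces, function(tr) tr$population, character(1))
  if (is.null(time_grid)) time_grid <- traces[[1L]]$t
  out <- list()
  for (pop in unique(pops)) {
    grp <- traces[pops == pop]
    mat <- vapply(grp, function(tr) {
      if (length(tr$t) == length(time_grid) && all(tr$t == time_grid)) tr$A
      else stats::approx(tr$t, tr$A, xout = time_grid, rule = 2)$y
    }, numeric(length(time_grid)))
    mat <- matrix(mat, nrow = length(time_grid))
    prof <- data.frame(t = time_grid,
                       mean = rowMeans(mat),
                       sd = apply(mat, 1L, stats::sd),
                       n = length(grp))
    rates <- vapply(grp, function(tr) estimate_rate(tr, ...)$rate, numeric(1))
    out[[pop]] <- list(profile = prof, rates = rates,
                       summary = .box_stats(rates))
  }
  structure(out, class = "population_kinetics")
}

#' @export
print.population_kinetics <- function(x, ...) {
  for (pop in names(x)) {
    s <- x[[pop]]$summary
    cat(sprintf("%s: n = %d, rate median %.4g [q1 %.4g, q3 %.4g], %d outside point(s)\n",
                pop, s$n, s$median, s$q1, s$q3, length(s$outside_points)))
  }
  invisible(x)
}

#' @export
plot.population_kinetics <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(2L, length(x)), "Dark 3")
  ylim <- range(vapply(x, function(g)
    range(g$profile$mean - g$profile$sd, g$profile$mean + g$profile$sd),
    numeric(2)))
  xlim <- range(x[[1L]]$profile$t)
  graphics::plot(NULL, xlim = xlim, ylim = ylim, xlab = "time (min)",
                 ylab = "fluorescence (RFU)", ...)
  for (i in seq_along(x)) {
    p <- x[[i]]$profile
    graphics::polygon(c(p$t, rev(p$t)), c(p$mean - p$sd, rev(p$mean + p$sd)),
                      col = grDevices::adjustcolor(cols[i], 0.3), border = NA)
    graphics::lines(p$t, p$mean, col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = names(x), col = cols[seq_along(x)],
                   lwd = 2, bty = "n")
  invisible(x)
}
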