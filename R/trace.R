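#' Construct a kinetic fluorescence trace
#'
#' A `kinetic_trace` holds one compartment's (or a bulk sample's)
#' fluorescence time series together with the metadata needed by the
#' rate-extraction pipeline.
#'
#' @param t Time points (min, strictly increasing).
#' @param A Fluorescence signal (RFU), same length as `t`, finite.
#' @param compartment_id Identifier of the compartment ("bulk" for the
#'   continuous phase).
#' @param population Population label (e.g. "population1").
#' @param template_conc Template concentration associated with the trace.
#' @param template_units Units of `template_conc`, "uM" or "nM".
#' @param exonuclease_nM Exonuclease concentration (nM).
#' @param normalized Logical; TRUE once the trace has been normalised.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(t, A, compartment_id = "bulk",
                          population = "population1",
                          template_conc = NA_real_, template_units = "uM",
                          exonuclease_nM = NA_real_, normalized = FALSE) {
  t <- as.numeric(t); A <- as.numeric(A)
  if (length(t) != length(A)) stop("kinetic_trace: t and A lengths differ")
  if (length(t) < 2L) stop("kinetic_trace: need at least 2 samples")
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    stop("kinetic_trace: t must be finite and strictly increasing")
  if (any(!is.finite(A))) stop("kinetic_trace: A must be finite")
  if (!template_units %in% c("uM", "nM"))
    stop("kinetic_trace: template_units must be 'uM' or 'nM'")
  structure(list(t = t, A = A,
                 compartment_id = as.character(compartment_id),
                 population = as.character(population),
                 template_conc = as.numeric(template_conc),
                 template_units = template_units,
                 exonuclease_nM = as.numeric(exonuclease_nM),
                 normalized = isTRUE(normalized)),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf(
    "Kinetic trace '%s' (%s): %d samples, t = %g..%g min, A = %.3g..%.3g%s\n",
    x$compartment_id, x$population, length(x$t), min(x$t), max(x$t),
    min(x$A), max(x$A), if (x$normalized) " (normalised)" else ""))
  invisible(x)
}

#' @export
plot.kinetic_trace <- function(x, ...) {
  graphics::plot(x$t, x$A, type = "l", xlab = "time (min)",
                 ylab = if (x$normalized) "normalised signal" else
                   "fluorescence (RFU)",
                 main = paste("Compartment", x$compartment_id), ...)
  invisible(x)
}

#' Construct a set of simulated traces with their generating truth
#'
#' @param traces List of [kinetic_trace()] objects sharing one time grid.
#' @param time_grid The common sampling times (min).
#' @param seed Integer seed used for any noise, or NA.
#' @param truth List with the generating parameters (free-strand matrices,
#'   `pen_params`, layout).
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, time_grid, seed = NA_integer_, truth = list()) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  for (tr in traces) {
    if (!inherits(tr, "kinetic_trace")) stop("trace_set: not a kinetic_trace")
    if (length(tr$t) != length(time_grid) || any(tr$t != time_grid))
      stop("trace_set: all traces must share the time grid")
    if (any(tr$A < 0)) stop("trace_set: signals must be >= 0")
  }
  structure(list(traces = traces, time_grid = as.numeric(time_grid),
                 seed = seed, truth = truth), class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  pops <- table(vapply(x$traces, function(tr) tr$population, character(1)))
  cat(sprintf("Trace set: %d traces over %d time points (%g..%g min)\n",
              length(x$traces), length(x$time_grid), min(x$time_grid),
              max(x$time_grid)))
  for (nm in names(pops)) cat("  ", nm, ":", pops[[nm]], "trace(s)\n")
  invisible(x)
}

#' @export
plot.trace_set <- function(x, ...) {
  ylim <- range(vapply(x$traces, function(tr) range(tr$A), numeric(2)))
  pops <- vapply(x$traces, function(tr) tr$population, character(1))
  cols <- grDevices::hcl.colors(max(1L, length(unique(pops))), "Dark 3")
  graphics::plot(NULL, xlim = range(x$time_grid), ylim = ylim,
                 xlab = "time (min)", ylab = "fluorescence (RFU)", ...)
  for (i in seq_along(x$traces))
    graphics::lines(x$traces[[i]]$t, x$traces[[i]]$A,
                    col = cols[match(pops[i], unique(pops))])
  invisible(x)
}
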