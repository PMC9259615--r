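#' Sample a proteinosome radius population
#'
#' Draws compartment radii emulating either the near-monodisperse
#' microfluidic preparation (normal radii, RSD around 14%) or the
#' polydisperse bulk-emulsification preparation (log-normal radii, RSD
#' around 48%). For the log-normal shape the parameters are chosen so that
#' the arithmetic mean and relative standard deviation match the request:
#' `sdlog^2 = log(1 + cv^2)`, `meanlog = log(mean) - sdlog^2/2`.
#'
#' @param n Number of radii to draw (>= 1).
#' @param mean_radius Target arithmetic mean radius (um, > 0).
#' @param rsd Target relative standard deviation (percent, in [0, 100)).
#' @param shape "normal" or "lognormal".
#' @param seed Integer seed; identical seeds give identical samples.
#' @return Numeric vector of `n` strictly positive radii (um).
#' @examples
#' r <- sample_proteinosome_population(100, 12.1, 14, "normal", seed = 1)
#' @export
sample_proteinosome_population <- function(n, mean_radius, rsd,
                                           shape = c("normal", "lognormal"),
                                           seed = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  if (mean_radius <= 0) stop("'mean_radius' must be > 0")
  if (rsd < 0 || rsd >= 100) stop("'rsd' must be in [0, 100)")
  if (!is.null(seed)) set.seed(seed)
  if (rsd == 0) return(rep(mean_radius, n))
  sd <- mean_radius * rsd / 100
  if (shape == "normal") {
    r <- stats::rnorm(n, mean_radius, sd)
    # rejection of non-positive draws; never return radii <= 0
    while (any(bad <- r <= 0)) r[bad] <- stats::rnorm(sum(bad), mean_radius, sd)
    r
  } else {
    cv2 <- (rsd / 100)^2
    sdlog <- sqrt(log(1 + cv2))
    meanlog <- log(mean_radius) - sdlog^2 / 2
    stats::rlnorm(n, meanlog, sdlog)
  }
}

#' Size statistics of a droplet population
#'
#' Mean, sample standard deviation (n - 1 denominator) and relative standard
#' deviation (RSD, percent) of a set of radii — the monodispersity summary
#' used to compare proteinosome preparations.
#'
#' @param radii Positive radii (um); at least 2 values for a standard
#'   deviation.
#' @param shape Optional distribution-shape label recorded in the output
#'   ("normal", "lognormal" or "unknown").
#' @return A `size_stats` list: `n`, `mean_radius`, `sd_radius`, `rsd`
#'   (percent, `100 * sd/mean`), `pdi_note`. With fewer than 2 radii,
#'   `sd_radius` and `rsd` are `NA` and `flagged` is TRUE.
#' @examples
#' size_statistics(c(12, 24, 36))
#' @export
size_statistics <- function(radii, shape = "unknown") {
  radii <- as.numeric(radii)
  if (length(radii) < 1L) stop("size_statistics: need at least 1 radius")
  if (any(radii <= 0)) stop("size_statistics: radii must be > 0")
  m <- mean(radii)
  if (length(radii) >= 2L) {
    s <- stats::sd(radii)
    out <- list(n = length(radii), mean_radius = m, sd_radius = s,
                rsd = 100 * s / m, pdi_note = shape, flagged = FALSE)
  } else {
    out <- list(n = 1L, mean_radius = m, sd_radius = NA_real_,
                rsd = NA_real_, pdi_note = shape, flagged = TRUE)
  }
  structure(out, class = "size_stats")
}

#' @export
print.size_stats <- function(x, ...) {
  cat(sprintf("Population of %d droplets: radius = %.1f +/- %.1f um, RSD = %.0f%% (%s)\n",
              x$n, x$mean_radius, x$sd_radius, x$rsd, x$pdi_note))
  invisible(x)
}

#' Relative standard deviation from a printed mean/sd summary
#'
#' @param mean_radius,sd_radius Summary statistics (um).
#' @return RSD in percent, `100 * sd/mean`.
#' @examples
#' relative_sd(24.0, 11.4)  # 47.5, i.e. 48% to the nearest integer
#' @export
relative_sd <- function(mean_radius, sd_radius) {
  if (mean_radius <= 0) stop("'mean_radius' must be > 0")
  100 * sd_radius / mean_radius
}
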