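#' Calibrate proteinosome count against total fluorescence
#'
#' Ordinary least squares of total fluorescence against proteinosome count
#' from a serial dilution, used to convert a bulk fluorescence reading into
#' a proteinosome number.
#'
#' @param counts Proteinosome counts (>= 3 paired points, non-negative, not
#'   all equal).
#' @param fluorescence Total fluorescence (RFU), same length.
#' @return A `calibration_curve` list: `slope` (RFU per proteinosome),
#'   `intercept` (RFU), `r_squared`, `n`, plus the underlying `lm`.
#' @examples
#' fit_calibration(c(10, 20, 40), c(100, 200, 400))
#' @export
fit_calibration <- function(counts, fluorescence) {
  counts <- as.numeric(counts); fluorescence <- as.numeric(fluorescence)
  if (length(counts) != length(fluorescence)) stop("lengths differ")
  if (length(counts) < 3L) stop("need at least 3 calibration points")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(unique(counts)) < 2L)
    stop("rank error: all counts are equal")
  fit <- stats::lm(fluorescence ~ counts)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)["counts"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = sm$r.squared, n = length(counts), lm = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration: fluorescence = %.4g * count + %.4g (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...)
  c(slope = object$slope, intercept = object$intercept)

#' @export
predict.calibration_curve <- function(object, newdata, ...) {
  counts <- if (is.data.frame(newdata)) newdata$counts else as.numeric(newdata)
  object$slope * counts + object$intercept
}

#' Estimate a proteinosome count from a fluorescence reading
#'
#' Inverts the calibration line: `(fluorescence - intercept) / slope`,
#' clamped at zero.
#'
#' @param fluorescence Total fluorescence (RFU).
#' @param curve A [fit_calibration()] result with positive slope.
#' @return Estimated count (real, >= 0).
#' @export
estimate_proteinosome_count <- function(fluorescence, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("invalid-curve error: slope must be > 0")
  pmax(0, (fluorescence - curve$intercept) / curve$slope)
}

#' Total template concentration of a proteinosome dispersion
#'
#' Each proteinosome holds a fixed internal template concentration
#' (0.12 uM by calibration); the dispersion-wide total is that value scaled
#' by the volume fraction the compartments occupy, reported in nM.
#'
#' @param compartment_volume_total Total compartment volume (any volume
#'   unit, same as `sample_volume`).
#' @param sample_volume Total sample volume; must exceed the compartment
#'   volume.
#' @param internal_template Internal template concentration (uM).
#' @return Total template concentration in the dispersion (nM).
#' @examples
#' total_template_concentration(0.005, 1)  # 0.6 nM
#' @export
total_template_concentration <- function(compartment_volume_total,
                                         sample_volume,
                                         internal_template = 0.12) {
  if (compartment_volume_total < 0) stop("compartment volume must be >= 0")
  if (sample_volume <= 0) stop("sample volume must be > 0")
  if (compartment_volume_total >= sample_volume)
    stop("argument error: compartment volume must be below the sample volume")
  if (internal_template < 0) stop("internal template must be >= 0")
  internal_template * (compartment_volume_total / sample_volume) * 1000
}
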