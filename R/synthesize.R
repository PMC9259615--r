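# Synthetic microscopy fixtures: uniform-interior disks on a dark
# background with additive Gaussian noise. Images are matrices indexed
# [x, y] (x = column in the rendered image, origin top-left), matching
# the EBImage convention used by the segmentation stage.

#' Render a synthetic proteinosome image stack with ground truth
#'
#' Each frame renders every compartment as a filled disk whose uniform
#' interior intensity equals the compartment's trace value at that frame;
#' the background is 0. Additive Gaussian noise (sd `noise_sd`) is applied
#' per pixel and frame. Membrane edge enrichment seen in real proteinosomes
#' is deliberately not modelled.
#'
#' @param radii Disk radii (um).
#' @param traces Either a [trace_set()] (its non-bulk traces are used, in
#'   order) or a numeric matrix with one row per disk and one column per
#'   frame.
#' @param positions Optional n x 2 matrix of centre coordinates (um). When
#'   `NULL`, non-overlapping positions are drawn uniformly at random with
#'   bounded retries.
#' @param pixel_size Pixel size (um/px, > 0).
#' @param frame_shape Frame size in pixels, `c(nx, ny)`.
#' @param noise_sd Gaussian noise standard deviation (RFU).
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param frame_times Optional frame times (min) recorded in the output.
#' @return A list with `stack` (array `nx x ny x n_frames`, RFU),
#'   `truth` (data.frame: id, frame, x_um, y_um, radius_um, true_intensity),
#'   `pixel_size` and `frame_times`.
#' @examples
#' s <- synthesize_image_stack(radii = c(10, 10),
#'                             traces = matrix(100, 2, 3),
#'                             pixel_size = 0.65,
#'                             frame_shape = c(128, 128), seed = 1)
#' @export
synthesize_image_stack <- function(radii, traces, positions = NULL,
                                   pixel_size = 0.65,
                                   frame_shape = c(256, 256),
                                   noise_sd = 0, seed = NULL,
                                   frame_times = NULL) {
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  if (any(radii <= 0)) stop("'radii' must be > 0")
  inten <- if (inherits(traces, "trace_set")) {
    keep <- vapply(traces$traces, function(tr) tr$compartment_id != "bulk",
                   logical(1))
    do.call(rbind, lapply(traces$traces[keep], function(tr) tr$A))
  } else as.matrix(traces)
  n <- length(radii)
  if (nrow(inten) != n)
    stop("number of radii and of intensity traces differ")
  n_frames <- ncol(inten)
  nx <- as.integer(frame_shape[1]); ny <- as.integer(frame_shape[2])
  fov <- c(nx, ny) * pixel_size

  if (!is.null(seed)) set.seed(seed)
  r_px_margin <- radii + 2 * pixel_size
  if (any(2 * r_px_margin > min(fov)))
    stop("placement error: compartment does not fit in the frame")
  if (is.null(positions)) {
    positions <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        cx <- stats::runif(1, r_px_margin[i], fov[1] - r_px_margin[i])
        cy <- stats::runif(1, r_px_margin[i], fov[2] - r_px_margin[i])
        if (i == 1L || all(sqrt((positions[seq_len(i - 1L), 1] - cx)^2 +
                                (positions[seq_len(i - 1L), 2] - cy)^2) >
                           r_px_margin[i] + r_px_margin[seq_len(i - 1L)])) {
          positions[i, ] <- c(cx, cy); placed <- TRUE; break
        }
      }
      if (!placed)
        stop("placement error: could not place compartment ", i,
             " without overlap after bounded retries")
    }
  } else {
    positions <- as.matrix(positions)
    if (nrow(positions) != n) stop("'positions' must have one row per disk")
  }

  # pixel-centre coordinates in um (pixel k spans [(k-1), k] * pixel_size)
  xs <- (seq_len(nx) - 0.5) * pixel_size
  ys <- (seq_len(ny) - 0.5) * pixel_size
  masks <- lapply(seq_len(n), function(i) {
    dx2 <- (xs - positions[i, 1])^2
    dy2 <- (ys - positions[i, 2])^2
    which(outer(dx2, dy2, "+") <= radii[i]^2)
  })

  stack <- array(0, dim = c(nx, ny, n_frames))
  for (f in seq_len(n_frames)) {
    frame <- matrix(0, nx, ny)
    for (i in seq_len(n)) frame[masks[[i]]] <- inten[i, f]
    if (noise_sd > 0)
      frame <- frame + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
    stack[, , f] <- frame
  }

  truth <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(id = i, frame = seq_len(n_frames),
               x_um = positions[i, 1], y_um = positions[i, 2],
               radius_um = radii[i], true_intensity = inten[i, ])))
  list(stack = stack, truth = truth, pixel_size = pixel_size,
       frame_times = frame_times)
}

#' Construct a FRAP trace
#'
#' @param t Times (s, strictly increasing).
#' @param I Normalised intensity.
#' @param t0 Bleach time (s): the time of the first post-bleach sample.
#' @param mode Normalisation mode, "standard" or "whole_droplet".
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(t, I, t0, mode = c("standard", "whole_droplet")) {
  mode <- match.arg(mode)
  t <- as.numeric(t); I <- as.numeric(I)
  if (length(t) != length(I)) stop("frap_trace: t and I lengths differ")
  if (any(diff(t) <= 0)) stop("frap_trace: t must be strictly increasing")
  pre <- I[t < t0]
  if (length(pre) && (mean(pre) < 0.9 || mean(pre) > 1.1))
    stop("frap_trace: pre-bleach mean outside [0.9, 1.1]; normalise first")
  structure(list(t = t, I = I, t0 = t0, mode = mode), class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("FRAP trace (%s): %d samples, bleach at t0 = %g s\n",
              x$mode, length(x$t), x$t0))
  invisible(x)
}

#' Synthesize a FRAP recovery trace with known truth
#'
#' Generates the piecewise exponential recovery
#' `I(t) = 1` for `t < t0` and
#' `I(t) = (1 - A * im) - A * (1 - im) * exp(-(t - t0)/tau)` for `t >= t0`,
#' so that the intensity immediately after the bleach is `1 - A` and the
#' long-time plateau is `1 - A * immobile_fraction`.
#'
#' @param A Bleach depth in [0, 1].
#' @param tau Recovery time constant (s, > 0).
#' @param immobile_fraction Non-recovering signal share in [0, 1].
#' @param t0 Bleach time (s); `t_grid` must span it.
#' @param t_grid Sampling times (s).
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer seed for the noise.
#' @return List with `trace` (a [frap_trace()]) and `truth`.
#' @examples
#' synthesize_frap_trace(A = 0.8, tau = 5, t0 = 10,
#'                       t_grid = seq(0, 60, 0.5))$trace
#' @export
synthesize_frap_trace <- function(A, tau, immobile_fraction = 0, t0,
                                  t_grid, noise_sd = 0, seed = NULL) {
  if (A < 0 || A > 1) stop("'A' must be in [0, 1]")
  if (tau <= 0) stop("'tau' must be > 0")
  if (immobile_fraction < 0 || immobile_fraction > 1)
    stop("'immobile_fraction' must be in [0, 1]")
  if (min(t_grid) >= t0 || max(t_grid) <= t0)
    stop("'t_grid' must span t0")
  I <- ifelse(t_grid < t0, 1,
              (1 - A * immobile_fraction) -
                A * (1 - immobile_fraction) * exp(-(t_grid - t0) / tau))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    I <- I + stats::rnorm(length(I), 0, noise_sd)
  }
  list(trace = frap_trace(t_grid, I, t0),
       truth = list(A = A, tau = tau,
                    immobile_fraction = immobile_fraction, t0 = t0,
                    noise_sd = noise_sd))
}
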