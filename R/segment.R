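# Proteinosome detection and per-droplet trace extraction.
# Pipeline mirrors the classic FIJI recipe: Gaussian blur -> threshold ->
# fill holes -> watershed split -> particle filters on circularity and
# equivalent diameter.

# perimeter from the Euclidean length of the 8-connected outer contour
# chain; EBImage's pixel-count perimeter overestimates strongly on disks.
.contour_perimeter <- function(oc) {
  if (nrow(oc) < 3L) return(nrow(oc))
  d <- rbind(diff(oc), oc[1L, ] - oc[nrow(oc), ])
  sum(sqrt(rowSums(d^2)))
}

#' Segment proteinosomes in a single fluorescence frame
#'
#' Detection pipeline: Gaussian blur (`blur_sigma` px) -> binarisation
#' (Otsu's threshold on the blurred frame rescaled to [0, 1], or a fixed
#' intensity value) -> hole filling -> watershed split of touching objects
#' on the distance map -> connected components -> shape measurement.
#' Objects are kept only if their circularity `4*pi*A/P^2` (perimeter from
#' the outer contour; values slightly above 1 from discretisation are
#' clipped to 1) lies in `circularity_range` and their equivalent-area-circle
#' diameter (um) lies in `diameter_range_um` (both closed intervals).
#'
#' @param frame Numeric matrix, indexed `[x, y]` with the origin top-left.
#' @param pixel_size Pixel size (um/px, > 0).
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param threshold "otsu" or a fixed numeric intensity threshold.
#' @param circularity_range Closed interval of accepted circularities.
#' @param diameter_range_um Closed interval of accepted equivalent
#'   diameters (um).
#' @return A data.frame of class `proteinosome_records`, sorted in raster
#'   order of centroids (row by row, then left to right), with columns
#'   `id`, `x_um`, `y_um`, `radius_um`, `area_um2`, `circularity`,
#'   `n_pixels`. The watershed label image and each record's label are kept
#'   in attributes `labels` / column `label` for [extract_traces()].
#'   An all-constant frame yields zero records.
#' @examples
#' s <- synthesize_image_stack(radii = 10, traces = matrix(100, 1, 1),
#'                             positions = matrix(c(40, 40), 1),
#'                             pixel_size = 0.65, frame_shape = c(128, 128))
#' segment_proteinosomes(s$stack[, , 1], pixel_size = 0.65,
#'                       diameter_range_um = c(17, 25))
#' @export
segment_proteinosomes <- function(frame, pixel_size, blur_sigma = 2,
                                  threshold = "otsu",
                                  circularity_range = c(0.7, 1.0),
                                  diameter_range_um = c(17, 25)) {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0L)
    stop("'frame' must be a non-empty numeric matrix")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be > 0")
  if (length(circularity_range) != 2L ||
      circularity_range[1] > circularity_range[2])
    stop("'circularity_range' must be an ordered interval")
  if (length(diameter_range_um) != 2L ||
      diameter_range_um[1] > diameter_range_um[2])
    stop("'diameter_range_um' must be an ordered interval")

  empty <- structure(
    data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
               radius_um = numeric(), area_um2 = numeric(),
               circularity = numeric(), n_pixels = integer(),
               label = integer()),
    class = c("proteinosome_records", "data.frame"),
    labels = matrix(0L, nrow(frame), ncol(frame)), pixel_size = pixel_size)

  rng <- range(frame)
  if (rng[1] == rng[2]) return(empty)

  img <- EBImage::Image(frame)
  blurred <- if (blur_sigma > 0) EBImage::gblur(img, sigma = blur_sigma) else img
  if (identical(threshold, "otsu")) {
    v <- (blurred - rng[1]) / (rng[2] - rng[1])
    v[v < 0] <- 0; v[v > 1] <- 1
    th <- EBImage::otsu(v, range = c(0, 1))
    binary <- v > th
  } else if (is.numeric(threshold)) {
    binary <- blurred > threshold
  } else stop("'threshold' must be \"otsu\" or a numeric value")
  if (!any(binary)) return(empty)

  binary <- EBImage::fillHull(binary)
  lab <- EBImage::watershed(EBImage::distmap(binary), tolerance = 1)
  nobj <- max(lab)
  if (nobj == 0L) return(empty)

  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  ocs <- EBImage::ocontour(lab)
  area_px <- shp[, "s.area"]
  per <- vapply(ocs, .contour_perimeter, numeric(1))
  circ <- 4 * pi * area_px / per^2
  circ[circ > 1] <- 1
  area_um2 <- area_px * pixel_size^2
  radius_um <- sqrt(area_um2 / pi)
  diam_um <- 2 * radius_um
  keep <- circ >= circularity_range[1] & circ <= circularity_range[2] &
    diam_um >= diameter_range_um[1] & diam_um <= diameter_range_um[2]

  rec <- data.frame(x_um = mom[, "m.cx"] * pixel_size,
                    y_um = mom[, "m.cy"] * pixel_size,
                    radius_um = radius_um, area_um2 = area_um2,
                    circularity = circ, n_pixels = as.integer(area_px),
                    label = seq_len(nobj))[keep, , drop = FALSE]
  # raster order: scan rows (y) top to bottom, then x left to right
  rec <- rec[order(rec$y_um, rec$x_um), , drop = FALSE]
  rec <- cbind(id = seq_len(nrow(rec)), rec)
  rownames(rec) <- NULL
  structure(rec, class = c("proteinosome_records", "data.frame"),
            labels = EBImage::imageData(lab), pixel_size = pixel_size)
}

#' @export
print.proteinosome_records <- function(x, ...) {
  cat("Proteinosome records:", nrow(x), "object(s)\n")
  if (nrow(x)) print.data.frame(x, digits = 4)
  invisible(x)
}

#' Extract per-compartment kinetic traces from an image stack
#'
#' For each segmented record and each frame, the trace value is the
#' integrated intensity over the record's watershed mask divided by the
#' mask area in pixels (i.e. the mean interior intensity, RFU).
#'
#' @param stack Image array `nx x ny x n_frames` (or a list with elements
#'   `stack`, `frame_times` as returned by [synthesize_image_stack()]).
#' @param records A `proteinosome_records` object from
#'   [segment_proteinosomes()] run on the reference frame; masks are reused
#'   for all frames (no tracking — proteinosomes are sedimented).
#' @param frame_times Frame times (min); defaults to the stack's recorded
#'   times or `0, 1, 2, ...`.
#' @param frame_interval Alternative to `frame_times`: uniform spacing (min).
#' @return List of [kinetic_trace()] objects, one per record. Records whose
#'   mask is empty are flagged by omission (with a warning).
#' @export
extract_traces <- function(stack, records, frame_times = NULL,
                           frame_interval = NULL) {
  if (is.list(stack) && !is.null(stack$stack)) {
    if (is.null(frame_times)) frame_times <- stack$frame_times
    stack <- stack$stack
  }
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
  if (length(dim(stack)) != 3L) stop("'stack' must be nx x ny x n_frames")
  if (!inherits(records, "proteinosome_records"))
    stop("'records' must come from segment_proteinosomes()")
  n_frames <- dim(stack)[3]
  if (is.null(frame_times))
    frame_times <- if (!is.null(frame_interval))
      (seq_len(n_frames) - 1L) * frame_interval else seq_len(n_frames) - 1L
  if (length(frame_times) != n_frames)
    stop("'frame_times' length must match the number of frames")
  lab <- attr(records, "labels")
  if (any(dim(lab) != dim(stack)[1:2]))
    stop("records' masks do not match the stack frame size")
  out <- list()
  for (i in seq_len(nrow(records))) {
    mask <- which(lab == records$label[i])
    if (length(mask) == 0L) {
      warning("record ", records$id[i], " has an empty mask; trace omitted")
      next
    }
    vals <- vapply(seq_len(n_frames),
                   function(f) sum(stack[, , f][mask]) / length(mask),
                   numeric(1))
    out[[length(out) + 1L]] <- kinetic_trace(
      frame_times, vals, compartment_id = as.character(records$id[i]))
  }
  out
}
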