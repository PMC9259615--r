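# File formats: kinetic-trace CSV, FRAP CSV and multi-page 16-bit TIFF
# stacks with a JSON sidecar recording the intensity gain.

#' Write kinetic traces to CSV
#'
#' Schema: `time_min, signal_rfu, compartment_id, population, template_uM,
#' exonuclease_nM`, one row per sample, traces stacked. Values are written
#' to 12 significant digits so a read round trip is lossless at that
#' precision.
#'
#' @param traces List of [kinetic_trace()] objects or a [trace_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "trace_set")) traces <- traces$traces
  df <- do.call(rbind, lapply(traces, function(tr) {
    tuM <- if (tr$template_units == "uM") tr$template_conc
           else tr$template_conc / 1000
    data.frame(time_min = signif(tr$t, 12),
               signal_rfu = signif(tr$A, 12),
               compartment_id = tr$compartment_id,
               population = tr$population,
               template_uM = tuM,
               exonuclease_nM = tr$exonuclease_nM)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read kinetic traces from CSV
#'
#' Expects the [write_traces()] schema; the time column must be strictly
#' increasing within each compartment.
#'
#' @param path CSV path.
#' @return List of [kinetic_trace()] objects.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "signal_rfu", "compartment_id", "population",
            "template_uM", "exonuclease_nM")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (id in unique(df$compartment_id)) {
    sub <- df[df$compartment_id == id, ]
    bad <- which(diff(sub$time_min) <= 0)
    if (length(bad)) {
      row <- which(df$compartment_id == id)[bad[1L] + 1L]
      stop("format error: non-monotonic time at row ", row,
           " (compartment ", id, ")")
    }
    out[[length(out) + 1L]] <- kinetic_trace(
      sub$time_min, sub$signal_rfu, compartment_id = id,
      population = sub$population[1L], template_conc = sub$template_uM[1L],
      template_units = "uM", exonuclease_nM = sub$exonuclease_nM[1L])
  }
  out
}

#' Write an image stack as multi-page 16-bit TIFF
#'
#' One page per time point, 16-bit unsigned, intensities scaled by a gain
#' recorded (with pixel size and frame times) in a `<path>.meta.json`
#' sidecar so [read_image_stack()] restores physical units.
#'
#' @param stack Array `nx x ny x n_frames` (or a
#'   [synthesize_image_stack()] result).
#' @param path Output TIFF path.
#' @param gain RFU-to-integer gain; default scales the stack maximum
#'   to 65535.
#' @param pixel_size,frame_times Metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, gain = NULL, pixel_size = NA,
                              frame_times = NULL) {
  if (is.list(stack) && !is.null(stack$stack)) {
    if (is.na(pixel_size)) pixel_size <- stack$pixel_size
    if (is.null(frame_times)) frame_times <- stack$frame_times
    stack <- stack$stack
  }
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
  mx <- max(stack)
  if (is.null(gain)) gain <- if (mx > 0) 65535 / mx else 1
  pages <- lapply(seq_len(dim(stack)[3]), function(f) {
    q <- round(pmin(pmax(stack[, , f] * gain, 0), 65535))
    t(q) / 65535  # tiff expects [row = y, col = x] in [0, 1]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(gain = gain, pixel_size = pixel_size, frame_times = frame_times),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-page TIFF image stack
#'
#' @param path TIFF path written by [write_image_stack()] (or any
#'   multi-page grayscale TIFF; without a sidecar the gain is 1).
#' @param as_integers If TRUE, return the raw 16-bit integers without
#'   applying the recorded gain.
#' @return List with `stack` (`nx x ny x n_frames`), `pixel_size`,
#'   `frame_times`, `gain`.
#' @export
read_image_stack <- function(path, as_integers = FALSE) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- list(gain = 1, pixel_size = NA, frame_times = NULL)
  mpath <- paste0(path, ".meta.json")
  if (file.exists(mpath))
    meta <- utils::modifyList(meta, jsonlite::read_json(mpath,
                                                        simplifyVector = TRUE))
  stack <- array(0, c(ncol(pages[[1L]]), nrow(pages[[1L]]), length(pages)))
  for (f in seq_along(pages)) {
    q <- t(pages[[f]])
    stack[, , f] <- if (as_integers) q else q / meta$gain
  }
  list(stack = stack, pixel_size = meta$pixel_size,
       frame_times = meta$frame_times, gain = meta$gain)
}

#' Write FRAP series to CSV
#'
#' Schema: `t_s, roi, reference, background` plus optional `whole_droplet`.
#'
#' @param df data.frame with those columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frap_csv <- function(df, path) {
  need <- c("t_s", "roi", "reference", "background")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read FRAP series from CSV
#'
#' @param path CSV with columns `t_s, roi, reference, background`
#'   (optionally `whole_droplet`); time must be strictly increasing.
#' @return The validated data.frame.
#' @export
read_frap_csv <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "roi", "reference", "background")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad))
    stop("format error: non-monotonic time at row ", bad[1L] + 1L)
  df
}
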