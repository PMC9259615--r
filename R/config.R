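# Pipeline configuration: defaults, validation, JSON/YAML serialisation.

#' Default pipeline configuration
#'
#' All stage parameters materialised with their defaults. The `simulate`
#' block describes the demo study: one population of microfluidic-sized
#' proteinosomes (radius 12.1 um) holding 0.12 uM autocatalytic template at
#' a volume fraction giving 0.6 nM total template, imaged every 3 minutes.
#'
#' @return A `pen_config` nested list.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    simulate = list(
      enabled = TRUE,
      params = unclass(pen_params()),
      layout = list(
        populations = list(list(node_kind = "autocatalytic", T_in = 0.12,
                                n_compartments = 6L, radius_um = 12.1)),
        volume_fraction = 0.005),
      primer0 = 1, duration = 300, dt = 3, noise_sd = 0,
      image = list(pixel_size = 0.65, frame_shape = c(256L, 256L),
                   noise_sd = 2)),
    segment = list(blur_sigma = 2, threshold = "otsu",
                   circularity_range = c(0.7, 1.0),
                   diameter_range_um = c(17, 25)),
    kinetics = list(normalize = "none", fallback_frac = 0.6, smooth = FALSE),
    frap = list(enabled = FALSE, r_um = 2, A = 0.8, tau = 5,
                immobile_fraction = 0, t0 = 10, t_max = 60, dt = 0.2,
                noise_sd = 0.02, n_events = 20L),
    io = list(input_tiff = NULL, outdir = "penkit_run")
  ), class = "pen_config")
}

# recursive merge of a user config into the defaults, collecting problems
# (unknown keys, type mismatches) with their path-to-field.
.merge_config <- function(def, user, path = "") {
  problems <- character()
  for (nm in names(user)) {
    here <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(def)) {
      problems <- c(problems, paste0("unknown key: ", here))
      next
    }
    dv <- def[[nm]]; uv <- user[[nm]]
    if (is.list(dv) && !nm %in% c("populations", "input_tiff")) {
      res <- .merge_config(dv, as.list(uv), here)
      def[[nm]] <- res$config
      problems <- c(problems, res$problems)
    } else if (nm %in% c("input_tiff")) {
      def[nm] <- list(uv)   # preserve NULL values
    } else if (nm == "populations") {
      def[[nm]] <- lapply(uv, as.list)
    } else {
      if (is.numeric(dv) && !is.numeric(uv) && !nm %in% c("threshold"))
        problems <- c(problems, paste0("wrong type (expected numeric): ", here))
      else def[[nm]] <- uv
    }
  }
  list(config = def, problems = problems)
}

.validate_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed: single integer")
  sg <- cfg$segment
  chk(length(sg$circularity_range) == 2L &&
        sg$circularity_range[1] <= sg$circularity_range[2] &&
        sg$circularity_range[1] >= 0 && sg$circularity_range[2] <= 1.1,
      "segment.circularity_range: ordered interval within [0, 1.1]")
  chk(length(sg$diameter_range_um) == 2L &&
        sg$diameter_range_um[1] <= sg$diameter_range_um[2] &&
        sg$diameter_range_um[1] > 0,
      "segment.diameter_range_um: ordered positive interval")
  chk(sg$blur_sigma >= 0, "segment.blur_sigma: must be >= 0")
  chk(identical(sg$threshold, "otsu") || is.numeric(sg$threshold),
      "segment.threshold: 'otsu' or numeric")
  chk(cfg$kinetics$normalize %in% c("none", "minmax", "to_point"),
      "kinetics.normalize: one of none/minmax/to_point")
  chk(cfg$kinetics$fallback_frac > 0 && cfg$kinetics$fallback_frac <= 1,
      "kinetics.fallback_frac: in (0, 1]")
  sim <- cfg$simulate
  chk(sim$duration > 0 && sim$dt > 0 && sim$dt <= sim$duration / 10,
      "simulate.duration/dt: need dt > 0 and dt <= duration/10")
  chk(sim$layout$volume_fraction > 0 && sim$layout$volume_fraction < 1,
      "simulate.layout.volume_fraction: in (0, 1)")
  chk(sim$image$pixel_size > 0, "simulate.image.pixel_size: must be > 0")
  fr <- cfg$frap
  chk(fr$A >= 0 && fr$A <= 1, "frap.A: in [0, 1]")
  chk(fr$tau > 0, "frap.tau: must be > 0")
  chk(fr$r_um > 0, "frap.r_um: must be > 0")
  problems
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON or YAML file (by extension), fills every omitted field with
#' its default and validates the result. All problems (unknown keys, wrong
#' types, out-of-range values) are reported together, each with its
#' path-to-field.
#'
#' @param path Config file (`.json`, `.yaml`/`.yml`), or a named list of
#'   overrides to validate directly.
#' @return A validated `pen_config`.
#' @examples
#' cfg <- load_config(list(seed = 7))
#' cfg$segment$diameter_range_um
#' @export
load_config <- function(path) {
  user <- if (is.list(path)) path
  else {
    if (!file.exists(path)) stop("input error: no such file: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE,
                                           simplifyDataFrame = FALSE,
                                           simplifyMatrix = FALSE)
    else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
    else stop("config must be .json or .yaml")
  }
  res <- .merge_config(unclass(default_config()), user)
  problems <- c(res$problems, .validate_config(res$config))
  if (length(problems))
    stop("validation error:\n  ", paste(problems, collapse = "\n  "))
  structure(res$config, class = "pen_config")
}

#' Save a pipeline configuration
#'
#' Writes JSON (or YAML by extension); `load_config(save_config(cfg, p))`
#' is the identity.
#'
#' @param config A `pen_config`.
#' @param path Output path (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  else if (ext %in% c("yaml", "yml"))
    yaml::write_yaml(unclass(config), path)
  else stop("config must be .json or .yaml")
  invisible(path)
}

#' @export
print.pen_config <- function(x, ...) {
  cat("penkit pipeline configuration (seed ", x$seed, ")\n", sep = "")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
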