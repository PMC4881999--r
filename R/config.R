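#' Default run configuration
#'
#' One nested list holding the feature, detector and scene parameter
#' blocks plus the run seed. Serialized as a flat, human-editable
#' `[section]` / `key = value` file; every output artifact records the
#' configuration it was produced with.
#'
#' @return nested list with elements `feature`, `detector`, `scene`,
#'   `run`.
#' @export
default_run_config <- function() {
  list(
    feature = list(window = 25L, m_max = 4L, k_max = 4L, n_radii = 4L,
                   composite_budget = 50L, use_magnitudes = TRUE),
    detector = list(contrast_window = 7L, contrast_threshold = 0.02,
                    score_threshold = 0.5, min_area = 0L, stride = 1L,
                    n_rounds = 100L, tree_depth = 2L),
    scene = list(width = 192L, height = 192L, n_animals = 20L,
                 blob_sigma_major = 3.2, blob_sigma_minor = 1.3,
                 blob_contrast = 0.35, background_level = 0.55,
                 texture_scale = 6, texture_amplitude = 0.06,
                 clutter_level = 0L, light_level = 1.0,
                 min_separation = 14),
    run = list(seed = 1L))
}

#' Write / read a configuration file
#'
#' Flat `key = value` format with `[section]` headers. Types round-trip:
#' integers, doubles and logicals are restored as such.
#'
#' @param config nested list of sections (see [default_run_config()]).
#' @param path file path.
#' @return `write_config`: the path invisibly; `read_config`: the nested
#'   list.
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  for (sec in names(config)) {
    lines <- c(lines, sprintf("[%s]", sec))
    blk <- config[[sec]]
    for (key in names(blk)) {
      v <- blk[[key]]
      val <- if (is.logical(v)) ifelse(v, "true", "false")
             else format(v, digits = 17, scientific = FALSE, trim = TRUE)
      lines <- c(lines, sprintf("%s = %s", key, val))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no config file: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  sec <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- sub("^\\[(.*)\\]$", "\\1", ln)
      out[[sec]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(sec)) stop("config line before any [section]: ", ln, call. = FALSE)
      key <- trimws(sub("=.*", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      parsed <- if (val %in% c("true", "false")) {
        val == "true"
      } else if (grepl("^-?[0-9]+$", val)) {
        as.integer(val)
      } else if (suppressWarnings(!is.na(as.numeric(val)))) {
        as.numeric(val)
      } else {
        val
      }
      out[[sec]][[key]] <- parsed
    }
  }
  out
}

# Instantiate parameter objects from a config list, tolerating partial
# blocks (missing keys fall back to the function defaults).
config_feature <- function(config) do.call(feature_config, config$feature %||% list())
config_detector <- function(config) do.call(detector_config, config$detector %||% list())
config_scene <- function(config, ...) {
  args <- config$scene %||% list()
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scene_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
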