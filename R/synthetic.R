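# Run code with a private RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic aerial-scene configuration
#'
#' Parameters of the scene generator. Defaults describe a grassland strip
#' seen from survey altitude: a smooth textured background, dark elongated
#' animal-scale blobs at uniformly random orientations, an optional number
#' of high-contrast landscape streaks (clutter) that are not animals, and a
#' global light level.
#'
#' @param width,height scene size in pixels.
#' @param n_animals number of planted animals.
#' @param blob_sigma_major,blob_sigma_minor Gaussian half-axes of the body
#'   profile (px); the body spans roughly 4 x sigma.
#' @param blob_contrast intensity drop at the body centre (animals are dark
#'   on grass).
#' @param background_level mean background intensity before light scaling.
#' @param texture_scale Gaussian blur sigma (px) of the background texture.
#' @param texture_amplitude standard deviation of the background texture.
#' @param clutter_level number of landscape streaks (not in ground truth).
#' @param light_level global intensity multiplier in (0, 1].
#' @param min_separation minimum distance between planted centroids (px).
#' @param seed RNG seed; the same config and seed give an identical scene.
#' @param orientation_seed optional separate seed for the body
#'   orientations only; two configs differing only here give the same
#'   background and centroids but independently re-drawn orientations.
#' @return object of class `wc_scene_config`.
#' @export
scene_config <- function(width = 192L, height = 192L, n_animals = 20L,
                         blob_sigma_major = 3.2, blob_sigma_minor = 1.3,
                         blob_contrast = 0.35, background_level = 0.55,
                         texture_scale = 6, texture_amplitude = 0.06,
                         clutter_level = 0L, light_level = 1.0,
                         min_separation = 14, seed = 1L,
                         orientation_seed = NA_integer_) {
  if (light_level <= 0 || light_level > 1) {
    stop("light_level must be in (0, 1]", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_animals = as.integer(n_animals),
                 blob_sigma_major = blob_sigma_major,
                 blob_sigma_minor = blob_sigma_minor,
                 blob_contrast = blob_contrast,
                 background_level = background_level,
                 texture_scale = texture_scale,
                 texture_amplitude = texture_amplitude,
                 clutter_level = as.integer(clutter_level),
                 light_level = light_level,
                 min_separation = min_separation,
                 seed = as.integer(seed),
                 orientation_seed = as.integer(orientation_seed)),
            class = "wc_scene_config")
}

#' Render one elongated blob analytically
#'
#' Adds (or subtracts) an anisotropic Gaussian body profile at an exact
#' sub-pixel centre and orientation. Because the profile is evaluated from
#' its parametric form, a rotated instance needs no image resampling —
#' required by the rotation-invariance tests.
#'
#' @param image grayscale matrix (modified copy returned).
#' @param x,y centre, 0-based pixel coordinates (x = column).
#' @param orientation body axis angle in radians.
#' @param sigma_major,sigma_minor Gaussian half-axes (px).
#' @param contrast peak intensity change; positive values darken.
#' @return the image with the blob applied.
#' @export
render_blob <- function(image, x, y, orientation, sigma_major = 3.2,
                        sigma_minor = 1.3, contrast = 0.35) {
  ext <- ceiling(4 * sigma_major)
  r0 <- max(0L, floor(y) - ext); r1 <- min(nrow(image) - 1L, ceiling(y) + ext)
  c0 <- max(0L, floor(x) - ext); c1 <- min(ncol(image) - 1L, ceiling(x) + ext)
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - y, length(rows), length(cols))
  dx <- matrix(cols - x, length(rows), length(cols), byrow = TRUE)
  u <- cos(orientation) * dx + sin(orientation) * dy
  v <- -sin(orientation) * dx + cos(orientation) * dy
  prof <- contrast * exp(-(u^2 / (2 * sigma_major^2) + v^2 / (2 * sigma_minor^2)))
  image[rows + 1L, cols + 1L] <- image[rows + 1L, cols + 1L] - prof
  image
}

# Smooth background texture: Gaussian-blurred white noise, unit sd.
smooth_noise <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  side <- 2L * ceiling(3 * sigma) + 1L
  off <- seq(-(side - 1L) / 2, (side - 1L) / 2)
  g <- exp(-off^2 / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  sm <- Re(conv_reflect(z + 0i, k))
  (sm - mean(sm)) / stats::sd(as.vector(sm))
}

#' Generate a synthetic survey scene with ground truth
#'
#' Builds a textured background, plants `n_animals` dark elongated blobs at
#' uniformly random orientations (centroids kept one body length from the
#' border and `min_separation` apart), optionally adds landscape clutter
#' streaks, scales the whole image by `light_level`, and clamps to \[0, 1\].
#'
#' @param config a [scene_config()].
#' @return list with `image` (grayscale matrix) and `truth` (data frame
#'   `id`, `x`, `y`, `orientation`; 0-based coordinates).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "wc_scene_config"))
  body_len <- 4 * config$blob_sigma_major
  margin <- ceiling(body_len)
  if (2 * margin >= config$width || 2 * margin >= config$height) {
    stop("blob does not fit in the image at this size", call. = FALSE)
  }
  with_seed(config$seed, {
    img <- config$background_level +
      config$texture_amplitude * smooth_noise(config$height, config$width,
                                              config$texture_scale)
    # rejection-sample centroids with a minimum separation
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pts) < config$n_animals) {
      tries <- tries + 1L
      if (tries > 10000L) stop("cannot place blobs: scene too crowded", call. = FALSE)
      cand <- c(stats::runif(1, margin, config$width - 1 - margin),
                stats::runif(1, margin, config$height - 1 - margin))
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
          config$min_separation) {
        pts <- rbind(pts, cand)
      }
    }
    if (!is.na(config$orientation_seed)) set.seed(config$orientation_seed)
    orientations <- stats::runif(config$n_animals, 0, 2 * pi)
    if (config$n_animals > 0L) {
      for (i in seq_len(config$n_animals)) {
        img <- render_blob(img, pts[i, 1], pts[i, 2], orientations[i],
                           config$blob_sigma_major, config$blob_sigma_minor,
                           config$blob_contrast)
      }
    }
    if (config$clutter_level > 0L) {
      for (i in seq_len(config$clutter_level)) {
        cx <- stats::runif(1, margin, config$width - 1 - margin)
        cy <- stats::runif(1, margin, config$height - 1 - margin)
        phi <- stats::runif(1, 0, 2 * pi)
        sgn <- sample(c(-1, 1), 1)
        img <- render_blob(img, cx, cy, phi,
                           sigma_major = 12, sigma_minor = 1.0,
                           contrast = sgn * 0.3)
      }
    }
    img <- pmin(pmax(img * config$light_level, 0), 1)
    truth <- data.frame(id = seq_len(config$n_animals),
                        x = if (config$n_animals) pts[, 1] else numeric(0),
                        y = if (config$n_animals) pts[, 2] else numeric(0),
                        orientation = orientations)
    list(image = img, truth = truth)
  })
}

#' Write / read ground-truth annotations
#'
#' CSV with columns image_id, x, y, orientation; round-trips losslessly to
#' full double precision.
#'
#' @param truth data frame with `x`, `y`, `orientation` (and optionally
#'   `image_id`).
#' @param path CSV path.
#' @param image_id id recorded when `truth` has none.
#' @return `write_annotations`: the path, invisibly; `read_annotations`:
#'   the annotations data frame.
#' @export
write_annotations <- function(truth, path, image_id = 1L) {
  df <- data.frame(
    image_id = if ("image_id" %in% names(truth)) truth$image_id
               else rep(image_id, nrow(truth)),
    x = truth$x, y = truth$y, orientation = truth$orientation)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write annotations: no directory ", dir,
                             call. = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no annotation file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("image_id", "x", "y", "orientation")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Harvest a labelled training set from synthetic scenes
#'
#' Positive samples are the descriptors at each planted centroid; negative
#' samples are drawn at uniformly random pixels at least one window
#' diameter from every ground-truth centroid.
#'
#' @param scenes list of `generate_scene()` outputs.
#' @param n_pos,n_neg total samples per class across the scenes.
#' @param feature_cfg a [feature_config()].
#' @param seed RNG seed for negative placement.
#' @return list with `descriptors` (matrix) and `labels` (0/1 vector).
#' @export
sample_training_set <- function(scenes, n_pos, n_neg,
                                feature_cfg = feature_config(), seed = 1L) {
  spec <- make_descriptor_spec(feature_cfg)
  margin <- feature_cfg$radius
  diam <- feature_cfg$window
  with_seed(seed, {
    desc <- list(); labels <- integer(0)
    per_pos <- ceiling(n_pos / length(scenes))
    per_neg <- ceiling(n_neg / length(scenes))
    for (sc in scenes) {
      raw <- compute_raw_features(sc$image, feature_cfg)
      nr <- nrow(sc$image); nc <- ncol(sc$image)
      tr <- sc$truth
      if (nrow(tr)) {
        take <- utils::head(seq_len(nrow(tr)), per_pos)
        cx <- round(tr$x[take]); cy <- round(tr$y[take])
        idx <- as.integer((cy + 1) + nr * cx)
        desc[[length(desc) + 1L]] <- invariant_feature_matrix(raw, spec, idx)
        labels <- c(labels, rep(1L, length(idx)))
      }
      got <- 0L
      neg_idx <- integer(0)
      while (got < per_neg) {
        cx <- floor(stats::runif(1, margin, nc - margin))
        cy <- floor(stats::runif(1, margin, nr - margin))
        if (nrow(tr) == 0 ||
            min(sqrt((tr$x - cx)^2 + (tr$y - cy)^2)) >= diam) {
          neg_idx <- c(neg_idx, as.integer((cy + 1) + nr * cx))
          got <- got + 1L
        }
      }
      desc[[length(desc) + 1L]] <- invariant_feature_matrix(raw, spec, neg_idx)
      labels <- c(labels, rep(0L, length(neg_idx)))
    }
    m <- do.call(rbind, desc)
    keep_pos <- which(labels == 1L)[seq_len(min(n_pos, sum(labels == 1L)))]
    keep_neg <- which(labels == 0L)[seq_len(min(n_neg, sum(labels == 0L)))]
    keep <- c(keep_pos, keep_neg)
    list(descriptors = m[keep, , drop = FALSE], labels = labels[keep])
  })
}
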