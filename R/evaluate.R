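#' Per-image count error statistics
#'
#' `rms_error` is the root mean square of per-image differences
#' `D_i = counts_i - truth_i`; `mean_error` is their arithmetic mean (the
#' systematic bias of a counter). By the Cauchy-Schwarz inequality
#' `rms_error >= |mean_error|` always.
#'
#' @param counts,truth equal-length numeric vectors of per-image counts.
#' @return a single number.
#' @export
rms_error <- function(counts, truth) {
  if (length(counts) != length(truth)) {
    stop("counts and truth must have the same length", call. = FALSE)
  }
  if (length(counts) < 1L) stop("need at least one image", call. = FALSE)
  sqrt(mean((counts - truth)^2))
}

#' @rdname rms_error
#' @export
mean_error <- function(counts, truth) {
  if (length(counts) != length(truth)) {
    stop("counts and truth must have the same length", call. = FALSE)
  }
  if (length(counts) < 1L) stop("need at least one image", call. = FALSE)
  mean(counts - truth)
}

#' Summary statistics of a count column
#'
#' Total, mean per image, and coefficient of variation (sample standard
#' deviation over the mean) of a per-image count vector.
#'
#' @param counts numeric vector of per-image counts.
#' @return list with `total`, `mean_per_image`, `coefficient_of_variation`.
#' @export
summary_stats <- function(counts) {
  if (length(counts) < 2L) stop("need at least 2 images for the CV", call. = FALSE)
  m <- mean(counts)
  if (m == 0) stop("coefficient of variation undefined for zero mean", call. = FALSE)
  list(total = sum(counts), mean_per_image = m,
       coefficient_of_variation = stats::sd(counts) / m)
}

#' Match detections to ground truth by centroid distance
#'
#' Greedy nearest-neighbour matching: detection-truth pairs are accepted in
#' order of increasing distance, each detection and each truth used at most
#' once, up to a maximum radius. TP = matched pairs, FP = unmatched
#' detections, FN = unmatched truths. When the image area and the
#' animal-window area are supplied, TN is estimated as the number of
#' non-overlapping animal-sized regions in the image not occupied by any of
#' the above, `floor(image_area / window_area) - TP - FP - FN`.
#'
#' @param detections data frame with `x`, `y` (0-based centroids).
#' @param truth data frame with `x`, `y`.
#' @param radius maximum match distance in pixels (> 0).
#' @param image_area,window_area optional, for the TN estimate.
#' @return list with `TP`, `FP`, `FN`, `TN` (NA when areas not given) and
#'   `matches` (data frame detection, truth, distance).
#' @export
match_detections <- function(detections, truth, radius,
                             image_area = NULL, window_area = NULL) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  nd <- nrow(detections); nt <- nrow(truth)
  matches <- data.frame(detection = integer(0), truth = integer(0),
                        distance = numeric(0))
  if (nd > 0L && nt > 0L) {
    dmat <- outer(detections$x, truth$x, "-")^2 + outer(detections$y, truth$y, "-")^2
    dmat <- sqrt(dmat)
    ord <- order(dmat)
    used_d <- logical(nd); used_t <- logical(nt)
    for (o in ord) {
      if (dmat[o] > radius) break
      i <- ((o - 1L) %% nd) + 1L
      j <- ((o - 1L) %/% nd) + 1L
      if (used_d[i] || used_t[j]) next
      used_d[i] <- TRUE; used_t[j] <- TRUE
      matches <- rbind(matches, data.frame(detection = i, truth = j,
                                           distance = dmat[o]))
    }
  }
  tp <- nrow(matches)
  fp <- nd - tp
  fn <- nt - tp
  tn <- if (!is.null(image_area) && !is.null(window_area)) {
    max(0L, floor(image_area / window_area) - tp - fp - fn)
  } else NA_integer_
  list(TP = tp, FP = fp, FN = fn, TN = tn, matches = matches)
}

#' Precision and recall from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`; TN is not used.
#'
#' @param counts list with `TP`, `FP`, `FN` (e.g. from
#'   [match_detections()]).
#' @return list with `precision` and `recall`, as fractions in \[0, 1\].
#' @export
precision_recall <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  if (tp + fp == 0 || tp + fn == 0) {
    stop("precision/recall undefined: zero denominator", call. = FALSE)
  }
  list(precision = tp / (tp + fp), recall = tp / (tp + fn))
}

#' Regression of under-counting on image light level
#'
#' The under-count fraction of an image is `1 - automated / true`. Images
#' where the algorithm over-counts (`automated > true`) are excluded, as
#' are images with a true count of zero (the fraction is undefined).
#' Ordinary least squares of the retained fractions on the light level
#' (mean HSV value) gives the slope and R-squared.
#'
#' @param automated,true per-image counts.
#' @param light_levels per-image mean HSV value in \[0, 1\].
#' @return list with `slope`, `r_squared`, `intercept`, `se_slope`,
#'   `n_used`, `excluded` (indices dropped by the rule).
#' @export
undercount_regression <- function(automated, true, light_levels) {
  n <- length(true)
  if (length(automated) != n || length(light_levels) != n) {
    stop("inputs must have the same length", call. = FALSE)
  }
  excluded <- which(automated > true | true == 0)
  keep <- setdiff(seq_len(n), excluded)
  if (length(keep) < 3L) {
    stop("fewer than 3 images retained after the exclusion rule", call. = FALSE)
  }
  frac <- 1 - automated[keep] / true[keep]
  if (stats::var(frac) == 0) {
    return(list(slope = 0, r_squared = 0, intercept = frac[1], se_slope = 0,
                n_used = length(keep), excluded = excluded))
  }
  fit <- stats::lm(frac ~ light_levels[keep])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = sm$r.squared,
       intercept = unname(stats::coef(fit)[1]),
       se_slope = sm$coefficients[2, 2],
       n_used = length(keep),
       excluded = excluded)
}

#' Mean HSV value (light level) of an image
#'
#' The HSV value channel is the per-pixel maximum of the R, G and B
#' channels (the intensity itself for grayscale input); the light level is
#' its mean over the image.
#'
#' @param img numeric matrix or height x width x 3 array in \[0, 1\].
#' @return a number in \[0, 1\].
#' @export
compute_light_level <- function(img) {
  if (length(img) == 0L) stop("empty image", call. = FALSE)
  if (is.matrix(img)) return(mean(img))
  if (is.array(img) && length(dim(img)) == 3L) {
    return(mean(pmax(img[, , 1], img[, , 2], img[, , 3])))
  }
  stop("img must be a matrix or a 3-d RGB array", call. = FALSE)
}

#' Read a per-image count table
#'
#' CSV with one row per image: `image_id`, `first_manual`, `second_manual`,
#' `final_manual` and one or more automated-count columns (any column whose
#' name starts with `automated`). Counts must be non-negative numbers and
#' `final_manual` must never be missing; offending rows are reported with
#' their line numbers.
#'
#' @param path CSV path.
#' @return data frame of class `wc_count_table`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no count file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("image_id", "first_manual", "second_manual", "final_manual")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("count file is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  auto_cols <- grep("^automated", names(df), value = TRUE)
  count_cols <- c("first_manual", "second_manual", "final_manual", auto_cols)
  bad <- integer(0)
  for (cc in count_cols) {
    vals <- df[[cc]]
    bad <- union(bad, which(!is.na(vals) & (!is.finite(vals) | vals < 0)))
  }
  bad <- union(bad, which(is.na(df$final_manual)))
  if (length(bad)) {
    stop("invalid count rows at line(s) ",
         paste(sort(bad) + 1L, collapse = ", "),
         " of ", path, " (negative, non-finite, or missing final_manual)",
         call. = FALSE)
  }
  class(df) <- c("wc_count_table", class(df))
  df
}

#' Count-table evaluation report
#'
#' Computes, for each counter column (both manual first passes and every
#' automated column), the total, mean per image, coefficient of variation,
#' and the RMS and mean per-image error against the final (consensus)
#' manual count. The final count's own error columns are NA by definition.
#'
#' @param table a count table from [read_counts()] or an equivalent data
#'   frame.
#' @return data frame with one row per counter.
#' @export
evaluate_counts <- function(table) {
  auto_cols <- grep("^automated", names(table), value = TRUE)
  counters <- c("first_manual", "second_manual", "final_manual", auto_cols)
  truth <- table$final_manual
  rows <- lapply(counters, function(cc) {
    s <- summary_stats(table[[cc]])
    is_final <- identical(cc, "final_manual")
    data.frame(counter = cc,
               total = s$total,
               mean_per_image = s$mean_per_image,
               coefficient_of_variation = s$coefficient_of_variation,
               rms_error = if (is_final) NA_real_ else rms_error(table[[cc]], truth),
               mean_error = if (is_final) NA_real_ else mean_error(table[[cc]], truth))
  })
  do.call(rbind, rows)
}

#' Published 2009 Serengeti census reference numbers
#'
#' The headline numbers of the original wildebeest-count study, kept as
#' data for cross-checks and worked examples: per-counter summary rows
#' (totals, mean per image over the 2,018-image set, coefficient of
#' variation, RMS and mean per-image error against the final count) and
#' the confusion counts recorded on a 100-image subsample.
#'
#' @return `published_count_summary()`: data frame of the per-counter
#'   summary; `published_confusion()`: list with `TP`, `FP`, `FN`, `TN`
#'   and `n_images`.
#' @export
published_count_summary <- function() {
  data.frame(
    counter = c("first_manual", "second_manual", "final_manual", "automated"),
    total = c(33644, 51918, 42007, 42147),
    mean_per_image = c(16.67, 25.73, 20.82, 20.89),
    coefficient_of_variation = c(2.61, 2.21, 2.32, 1.83),
    rms_error = c(15.64, 19.75, NA, 31.70),
    mean_error = c(-4.14, 4.91, NA, 0.07),
    n_images = 2018L)
}

#' @rdname published_count_summary
#' @export
published_confusion <- function() {
  list(TP = 1423L, FP = 496L, FN = 235L, TN = 1.2e6, n_images = 100L)
}
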