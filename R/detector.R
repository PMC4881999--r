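#' Detector configuration
#'
#' @param contrast_window odd side (px) of the local-contrast window.
#' @param contrast_threshold local intensity standard deviation above which
#'   a pixel is considered non-uniform and is classified.
#' @param score_threshold classifier score in \[0, 1\] above which a pixel is
#'   called positive.
#' @param min_area minimum component area (px) kept as a detection; 0 keeps
#'   everything.
#' @param stride scan stride in pixels within the contrast mask.
#' @param n_rounds boosting rounds.
#' @param tree_depth depth of the weak decision trees.
#' @return an object of class `wc_detector_config`.
#' @export
detector_config <- function(contrast_window = 7L, contrast_threshold = 0.02,
                            score_threshold = 0.5, min_area = 0L, stride = 1L,
                            n_rounds = 100L, tree_depth = 2L) {
  if (contrast_window < 3L || contrast_window %% 2L == 0L) {
    stop("contrast_window must be odd and >= 3", call. = FALSE)
  }
  structure(list(contrast_window = as.integer(contrast_window),
                 contrast_threshold = contrast_threshold,
                 score_threshold = score_threshold,
                 min_area = as.integer(min_area),
                 stride = as.integer(stride),
                 n_rounds = as.integer(n_rounds),
                 tree_depth = as.integer(tree_depth)),
            class = "wc_detector_config")
}

#' Local-contrast pre-filter
#'
#' Flags pixels whose windowed intensity standard deviation exceeds a
#' threshold. Uniform regions are discarded before per-pixel
#' classification. The standard deviation is the population form over the
#' window, with reflected borders.
#'
#' @param image grayscale matrix in \[0, 1\].
#' @param window odd window side, >= 3.
#' @param threshold contrast threshold (intensity units).
#' @return logical matrix, TRUE where local sd > threshold.
#' @export
local_contrast_mask <- function(image, window, threshold) {
  image <- as_gray(image)
  if (window %% 2L == 0L || window < 3L) {
    stop("window must be odd and >= 3", call. = FALSE)
  }
  box <- matrix(1 / window^2, window, window)
  mu <- Re(conv_reflect(image + 0i, box))
  mu2 <- Re(conv_reflect(image^2 + 0i, box))
  v <- pmax(mu2 - mu^2, 0)
  sqrt(v) > threshold
}

# One weighted weak learner: a shallow classification tree.
fit_stump <- function(x, y, w, depth) {
  d <- as.data.frame(x)
  d$.y <- factor(y, levels = c(0, 1))
  rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
               control = rpart::rpart.control(maxdepth = depth, cp = 0,
                                              minsplit = 4L, minbucket = 2L,
                                              xval = 0L, maxcompete = 0L,
                                              maxsurrogate = 0L))
}

predict_stump <- function(tree, x) {
  p <- predict(tree, as.data.frame(x), type = "prob")
  as.integer(p[, "1"] >= 0.5)
}

#' Train the boosted pixel classifier
#'
#' Discrete AdaBoost over shallow decision trees: each round fits a
#' weighted classification tree, and misclassified samples are up-weighted
#' for the next round. The prediction score is the weighted vote fraction
#' for the positive class, in \[0, 1\].
#'
#' @param descriptors numeric matrix, one row per sample.
#' @param labels binary vector (1 = animal, 0 = background).
#' @param cfg a [detector_config()].
#' @param feature_cfg the [feature_config()] used to build the descriptors
#'   (stored with the model).
#' @param seed integer stored in the training metadata.
#' @return object of class `wc_classifier`.
#' @export
train_classifier <- function(descriptors, labels, cfg = detector_config(),
                             feature_cfg = feature_config(), seed = NA_integer_) {
  descriptors <- as.matrix(descriptors)
  labels <- as.integer(labels)
  if (length(labels) != nrow(descriptors)) {
    stop("labels and descriptors disagree in length", call. = FALSE)
  }
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < 2L)) stop("need at least 2 samples in each class", call. = FALSE)
  n <- nrow(descriptors)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (t in seq_len(cfg$n_rounds)) {
    tree <- fit_stump(descriptors, labels, w * n, cfg$tree_depth)
    h <- predict_stump(tree, descriptors)
    err <- sum(w * (h != labels))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(h != labels, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-10) break   # perfectly separated; more rounds add nothing
  }
  structure(list(trees = trees, alphas = alphas,
                 prior = mean(labels),
                 n_features = ncol(descriptors),
                 feature_names = colnames(descriptors),
                 feature_cfg = feature_cfg,
                 meta = list(n_pos = unname(tab["1"]), n_neg = unname(tab["0"]),
                             seed = seed, n_rounds_used = length(trees))),
            class = "wc_classifier")
}

#' Classifier scores for descriptor rows
#'
#' @param model a `wc_classifier`.
#' @param descriptors numeric matrix with the trained number of columns.
#' @return numeric vector of scores in \[0, 1\] (weighted positive vote).
#' @export
predict_scores <- function(model, descriptors) {
  descriptors <- as.matrix(descriptors)
  if (ncol(descriptors) != model$n_features) {
    stop("descriptor length does not match the trained model", call. = FALSE)
  }
  if (!is.null(model$feature_names)) colnames(descriptors) <- model$feature_names
  if (!length(model$trees)) {
    # no weak learner beat chance: fall back to the class prior
    return(rep(model$prior, nrow(descriptors)))
  }
  d <- as.data.frame(descriptors)
  vote <- numeric(nrow(descriptors))
  for (i in seq_along(model$trees)) {
    vote <- vote + model$alphas[i] * predict_stump(model$trees[[i]], d)
  }
  vote / sum(model$alphas)
}

#' 8-connected components of a binary mask
#'
#' Labels maximal 8-connected blocks of TRUE pixels. Diagonal adjacency on
#' a small animal body must not split one individual in two, hence
#' 8-connectivity.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  pos <- which(mask)
  if (!length(pos)) return(lab)
  id <- integer(nr * nc)
  id[pos] <- seq_along(pos)
  rows <- ((pos - 1L) %% nr) + 1L
  cols <- ((pos - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- id[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(id[pos[ok]][hit], id[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(pos), directed = FALSE)
  lab[pos] <- igraph::components(g)$membership
  lab
}

#' Detect and count animals in one image
#'
#' The full per-image pipeline: grayscale conversion, local-contrast
#' masking, rotation-invariant descriptor extraction and boosted
#' classification at every masked pixel, then 8-connected grouping of
#' positive pixels. Each component is one detection; the count is the
#' number of components. Pixels outside the contrast mask are never
#' classified positive.
#'
#' @param image matrix or RGB array in \[0, 1\].
#' @param model a trained `wc_classifier`.
#' @param cfg a [detector_config()].
#' @return object of class `wc_detection`: list with `mask` (logical
#'   positive-pixel matrix), `components` (data frame x, y, area, score;
#'   0-based centroid coordinates) and `count`.
#' @export
detect <- function(image, model, cfg = detector_config()) {
  gray <- as_gray(image)
  fcfg <- model$feature_cfg
  if (is.null(fcfg)) stop("model carries no feature configuration", call. = FALSE)
  cmask <- local_contrast_mask(gray, cfg$contrast_window, cfg$contrast_threshold)
  if (cfg$stride > 1L) {
    keep_r <- seq(1L, nrow(gray), by = cfg$stride)
    keep_c <- seq(1L, ncol(gray), by = cfg$stride)
    strided <- matrix(FALSE, nrow(gray), ncol(gray))
    strided[keep_r, keep_c] <- TRUE
    cmask <- cmask & strided
  }
  pos_mask <- matrix(FALSE, nrow(gray), ncol(gray))
  scores <- matrix(0, nrow(gray), ncol(gray))
  idx <- which(cmask)
  if (length(idx)) {
    raw <- compute_raw_features(gray, fcfg)
    feats <- invariant_feature_matrix(raw, make_descriptor_spec(fcfg), idx)
    s <- predict_scores(model, feats)
    scores[idx] <- s
    pos_mask[idx] <- s >= cfg$score_threshold
  }
  lab <- label_components(pos_mask)
  ncomp <- max(lab)
  comps <- data.frame(x = numeric(0), y = numeric(0),
                      area = integer(0), score = numeric(0))
  if (ncomp > 0L) {
    p <- which(lab > 0L)
    rr <- ((p - 1L) %% nrow(lab))       # 0-based row (y)
    cc <- ((p - 1L) %/% nrow(lab))      # 0-based col (x)
    l <- lab[p]
    comps <- data.frame(
      x = as.numeric(tapply(cc, l, mean)),
      y = as.numeric(tapply(rr, l, mean)),
      area = as.integer(tapply(p, l, length)),
      score = as.numeric(tapply(scores[p], l, max)))
    comps <- comps[comps$area >= cfg$min_area, , drop = FALSE]
    rownames(comps) <- NULL
  }
  structure(list(mask = pos_mask, components = comps, count = nrow(comps)),
            class = "wc_detection")
}

#' Grow a training set from automatic detections
#'
#' Iterative (bootstrap) training: a classifier trained on the initial set
#' is run over unlabelled images; each detection is submitted to a
#' correction callback, and the corrected samples are appended to the
#' training set. In tests the callback is an oracle using synthetic ground
#' truth; in field use it is a human check.
#'
#' @param descriptors,labels initial training set.
#' @param images list of grayscale matrices to scan.
#' @param callback `function(image_index, detections)` returning a logical
#'   vector, TRUE where the detection really is an animal.
#' @param cfg a [detector_config()].
#' @param feature_cfg the shared [feature_config()].
#' @param progress_path where the partial set is saved if the callback
#'   fails (RDS).
#' @return list with the enlarged `descriptors`, `labels`, and `log`
#'   (per-image detection and acceptance counts).
#' @export
bootstrap_train <- function(descriptors, labels, images, callback,
                            cfg = detector_config(),
                            feature_cfg = feature_config(),
                            progress_path = tempfile(fileext = ".rds")) {
  model <- train_classifier(descriptors, labels, cfg, feature_cfg)
  spec <- make_descriptor_spec(feature_cfg)
  log <- data.frame(image = integer(0), detections = integer(0),
                    accepted = integer(0))
  for (i in seq_along(images)) {
    det <- detect(images[[i]], model, cfg)
    if (det$count == 0L) {
      log <- rbind(log, data.frame(image = i, detections = 0L, accepted = 0L))
      next
    }
    verdict <- tryCatch(callback(i, det$components), error = function(e) e)
    if (inherits(verdict, "error")) {
      saveRDS(list(descriptors = descriptors, labels = labels, log = log),
              progress_path)
      stop("correction callback failed on image ", i, " (partial set saved to ",
           progress_path, "): ", conditionMessage(verdict), call. = FALSE)
    }
    raw <- compute_raw_features(as_gray(images[[i]]), feature_cfg)
    cx <- round(det$components$x); cy <- round(det$components$y)
    idx <- as.integer((cy + 1) + nrow(images[[i]]) * cx)
    feats <- invariant_feature_matrix(raw, spec, idx)
    descriptors <- rbind(descriptors, feats)
    labels <- c(labels, as.integer(verdict))
    log <- rbind(log, data.frame(image = i, detections = det$count,
                                 accepted = sum(verdict)))
  }
  list(descriptors = descriptors, labels = labels, log = log)
}

#' Save / load a trained model with its configuration
#'
#' Single-file serialized model with a versioned header, containing the
#' boosted ensemble, the feature configuration and training metadata.
#'
#' @param model a `wc_classifier`.
#' @param path file path (RDS).
#' @return `save_model`: the path, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "wc_classifier"))
  saveRDS(list(format = "wildcount-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "wildcount-model")) {
    stop("not a wildcount model file: ", path, call. = FALSE)
  }
  obj$model
}
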