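#' Feature configuration for Fourier HOG descriptors
#'
#' Bundles every tunable of the descriptor: the window size, the Fourier
#' truncation orders, the radial profile layout and the composite-feature
#' budget. The same configuration object is stored inside trained models so
#' descriptors are reproducible.
#'
#' @param window odd window side in pixels (the descriptor support).
#' @param m_max highest Fourier mode of the gradient-orientation expansion.
#' @param k_max highest basis-function wavenumber.
#' @param n_radii number of concentric radial profiles (rings), the first
#'   centred at radius 0.
#' @param sigma radial width (standard deviation, px) of each Gaussian
#'   annulus; default is half the ring spacing.
#' @param composite_budget maximum number of composite (product) features.
#' @param use_magnitudes append the moduli `|X_{k,m}|` (trivially rotation
#'   invariant) to the descriptor.
#' @return an object of class `wc_feature_config`.
#' @export
feature_config <- function(window = 25L, m_max = 4L, k_max = 4L,
                           n_radii = 4L, sigma = NULL,
                           composite_budget = 50L, use_magnitudes = TRUE) {
  window <- as.integer(window)
  if (window < 5L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 5", call. = FALSE)
  }
  if (m_max < 1L) stop("m_max must be >= 1", call. = FALSE)
  if (k_max < 0L) stop("k_max must be >= 0", call. = FALSE)
  if (n_radii < 1L) stop("n_radii must be >= 1", call. = FALSE)
  radius <- (window - 1L) / 2
  spacing <- if (n_radii > 1L) radius / (n_radii - 1L) else radius / 2
  radii <- spacing * (seq_len(n_radii) - 1L)
  if (is.null(sigma)) sigma <- spacing / 2
  structure(list(window = window, radius = radius,
                 m_max = as.integer(m_max), k_max = as.integer(k_max),
                 radii = radii, sigma = sigma,
                 composite_budget = as.integer(composite_budget),
                 use_magnitudes = isTRUE(use_magnitudes)),
            class = "wc_feature_config")
}

#' Fourier encoding of a gradient field
#'
#' Treats the gradient at each pixel as a Dirac delta on the circle of
#' orientations, weighted by the gradient magnitude, and expands it in a
#' Fourier series. For a pixel with gradient `r * exp(1i * theta)` the
#' mode-m coefficient is `r * exp(1i * m * theta)`; mode 0 is the gradient
#' magnitude itself.
#'
#' @param field complex gradient matrix from [compute_gradient_field()].
#' @param m_max truncation order (>= 1).
#' @return list of complex matrices, element `m + 1` holding mode `m`
#'   (m = 0 ... m_max).
#' @export
fourier_encode_gradients <- function(field, m_max) {
  if (m_max < 1L) stop("m_max must be >= 1", call. = FALSE)
  r <- Mod(field)
  theta <- Arg(field)
  stack <- lapply(0:m_max, function(m) {
    out <- r * exp(complex(imaginary = m * theta))
    out[r == 0] <- 0 + 0i
    matrix(out, nrow(field), ncol(field))
  })
  attr(stack, "m_max") <- as.integer(m_max)
  stack
}

#' Circular-harmonic basis functions
#'
#' Builds the complex convolution kernels `U_{j,k}(rho, psi) =
#' w_j(rho) * exp(1i * k * psi)` on a square grid of odd side `window`,
#' where `w_j` is a Gaussian annulus centred on `radii[j + 1]` with radial
#' width `sigma`, zeroed outside the inscribed disc, and normalized to unit
#' total weight. For `k != 0` the centre pixel (where the angle is
#' undefined) is set to zero.
#'
#' @param radii numeric vector of ring radii (px); must fit in the window.
#' @param k_max highest wavenumber (>= 0).
#' @param window odd kernel side (px).
#' @param sigma radial width of the annuli (px).
#' @return list of basis functions, each `list(kernel, j, k)`, ordered by
#'   `j` then `k`.
#' @export
make_basis_functions <- function(radii, k_max, window, sigma) {
  if (length(radii) == 0L) stop("radii must be non-empty", call. = FALSE)
  if (k_max < 0L) stop("k_max must be >= 0", call. = FALSE)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  r <- (window - 1L) / 2
  if (any(radii > r + 1e-9)) stop("radii must fit within the window", call. = FALSE)
  off <- seq(-r, r)
  dx <- matrix(off, window, window, byrow = TRUE)   # column offset
  dy <- matrix(off, window, window)                 # row offset (downward)
  rho <- sqrt(dx^2 + dy^2)
  psi <- atan2(dy, dx)
  inside <- rho <= r + 1e-9
  out <- list()
  for (j in seq_along(radii) - 1L) {
    w <- exp(-(rho - radii[j + 1L])^2 / (2 * sigma^2))
    w[!inside] <- 0
    w <- w / sum(w)
    for (k in 0:k_max) {
      ang <- exp(complex(imaginary = k * psi))
      if (k > 0L) ang[rho == 0] <- 0 + 0i
      out[[length(out) + 1L]] <- list(kernel = matrix(w * ang, window, window),
                                      j = j, k = as.integer(k))
    }
  }
  out
}

# Symmetric (edge-including) reflection padding of a matrix by `r` pixels.
pad_reflect <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(rev(seq_len(r)), seq_len(nr), nr - seq_len(r) + 1L)
  ci <- c(rev(seq_len(r)), seq_len(nc), nc - seq_len(r) + 1L)
  x[ri, ci, drop = FALSE]
}

# Kernel wrapped into an N1 x N2 array with its centre at index (1, 1),
# ready for FFT-based cross-correlation.
wrap_kernel <- function(kernel, n1, n2) {
  side <- nrow(kernel)
  r <- (side - 1L) / 2
  b <- matrix(0 + 0i, n1, n2)
  idx1 <- ((seq(-r, r)) %% n1) + 1L
  idx2 <- ((seq(-r, r)) %% n2) + 1L
  b[idx1, idx2] <- kernel
  b
}

# Cross-correlation of `x` with the conjugated kernel under symmetric
# reflection padding: out(p) = sum_q Conj(K(q)) x(p + q). FFT-based.
conv_reflect <- function(x, kernel) {
  r <- (nrow(kernel) - 1L) / 2
  xp <- pad_reflect(x, r)
  n1 <- nrow(xp); n2 <- ncol(xp)
  b <- wrap_kernel(kernel, n1, n2)
  res <- stats::fft(stats::fft(xp) * Conj(stats::fft(b)), inverse = TRUE) / (n1 * n2)
  res[(r + 1):(r + nrow(x)), (r + 1):(r + ncol(x)), drop = FALSE]
}

#' Convolve a Fourier gradient stack with one basis function
#'
#' Produces the raw (rotation-covariant) Fourier HOG feature maps
#' `X_{k,m} = U_{j,k} * F_m`, one complex map per mode m. The operation is
#' implemented as cross-correlation with the conjugated kernel under
#' reflected borders, which fixes the phase convention: rotating the image
#' by `alpha` multiplies `X_{k,m}` by `exp(1i * alpha * (m - k))`.
#'
#' @param stack output of [fourier_encode_gradients()].
#' @param basis one element of [make_basis_functions()].
#' @return list of complex matrices (element `m + 1` is mode m), with
#'   attributes `j` and `k`.
#' @export
convolve_features <- function(stack, basis) {
  if (nrow(basis$kernel) > nrow(stack[[1]]) || ncol(basis$kernel) > ncol(stack[[1]])) {
    stop("basis support exceeds image size", call. = FALSE)
  }
  maps <- lapply(stack, conv_reflect, kernel = basis$kernel)
  attr(maps, "j") <- basis$j
  attr(maps, "k") <- basis$k
  maps
}

#' Descriptor specification: which invariant combinations to use
#'
#' Enumerates the rotation-invariant entries of the descriptor for a given
#' feature configuration:
#' * singles: `X_{k,m}` with `m = k` (invariant by the shift property);
#' * composites: products `X_{k1,m1} * X_{k2,m2}` with
#'   `m1 - k1 + m2 - k2 = 0`, restricted to pairs whose radial indices
#'   differ by at most one, ordered by `(j1,k1,m1,j2,k2,m2)` and capped at
#'   `composite_budget`;
#' * magnitudes: `|X_{k,m}|` for every computed (j, k, m), if enabled.
#'
#' @param cfg a [feature_config()].
#' @return an object of class `wc_descriptor_spec` with data frames
#'   `singles`, `composites`, `magnitudes`.
#' @export
make_descriptor_spec <- function(cfg) {
  stopifnot(inherits(cfg, "wc_feature_config"))
  js <- seq_along(cfg$radii) - 1L
  km <- 0:min(cfg$k_max, cfg$m_max)
  singles <- expand.grid(k = km, j = js)[, c("j", "k")]
  singles <- singles[order(singles$j, singles$k), , drop = FALSE]
  singles$m <- singles$k
  rownames(singles) <- NULL

  all_f <- expand.grid(m = 0:cfg$m_max, k = 0:cfg$k_max, j = js)[, c("j", "k", "m")]
  all_f <- all_f[order(all_f$j, all_f$k, all_f$m), , drop = FALSE]
  rownames(all_f) <- NULL

  # composite pairs: d1 + d2 = 0 with d = m - k, at least one non-invariant
  d <- all_f$m - all_f$k
  comp <- list()
  n <- nrow(all_f)
  for (a in seq_len(n)) {
    if (d[a] <= 0) next        # take d1 > 0 so each unordered pair appears once
    for (b in seq_len(n)) {
      if (d[b] != -d[a]) next
      if (abs(all_f$j[a] - all_f$j[b]) > 1L) next
      comp[[length(comp) + 1L]] <- c(all_f$j[a], all_f$k[a], all_f$m[a],
                                     all_f$j[b], all_f$k[b], all_f$m[b])
    }
  }
  composites <- if (length(comp)) {
    cm <- do.call(rbind, comp)
    colnames(cm) <- c("j1", "k1", "m1", "j2", "k2", "m2")
    cm <- as.data.frame(cm)
    cm <- cm[order(cm$j1, cm$k1, cm$m1, cm$j2, cm$k2, cm$m2), , drop = FALSE]
    utils::head(cm, cfg$composite_budget)
  } else {
    data.frame(j1 = integer(), k1 = integer(), m1 = integer(),
               j2 = integer(), k2 = integer(), m2 = integer())
  }
  rownames(composites) <- NULL

  magnitudes <- if (cfg$use_magnitudes) all_f else all_f[0, , drop = FALSE]
  structure(list(singles = singles, composites = composites,
                 magnitudes = magnitudes, cfg = cfg),
            class = "wc_descriptor_spec")
}

#' Length and names of the descriptor defined by a spec
#' @param spec a `wc_descriptor_spec`.
#' @return character vector of feature names (two per complex entry).
#' @export
descriptor_names <- function(spec) {
  s <- spec$singles; cpr <- spec$composites; mg <- spec$magnitudes
  c(as.vector(rbind(sprintf("s_j%dk%d_re", s$j, s$k),
                    sprintf("s_j%dk%d_im", s$j, s$k))),
    as.vector(rbind(sprintf("c_%d%d%d_%d%d%d_re", cpr$j1, cpr$k1, cpr$m1, cpr$j2, cpr$k2, cpr$m2),
                    sprintf("c_%d%d%d_%d%d%d_im", cpr$j1, cpr$k1, cpr$m1, cpr$j2, cpr$k2, cpr$m2))),
    sprintf("mag_j%dk%dm%d", mg$j, mg$k, mg$m))
}

#' Raw Fourier HOG feature maps for a whole image
#'
#' Runs gradient extraction, Fourier encoding and all basis convolutions,
#' returning every raw complex map `X_{j,k,m}` at full image resolution.
#' FFTs of the padded gradient modes and kernels are computed once each.
#'
#' @param image grayscale matrix in \[0, 1\].
#' @param cfg a [feature_config()].
#' @return object of class `wc_raw_features`: list with `maps` (named list
#'   `"j_k_m"` of complex matrices), `cfg` and `dim`.
#' @export
compute_raw_features <- function(image, cfg) {
  stopifnot(inherits(cfg, "wc_feature_config"))
  image <- as_gray(image)
  if (nrow(image) < cfg$window || ncol(image) < cfg$window) {
    stop("image smaller than the feature window", call. = FALSE)
  }
  field <- compute_gradient_field(image)
  stack <- fourier_encode_gradients(field, cfg$m_max)
  basis <- make_basis_functions(cfg$radii, cfg$k_max, cfg$window, cfg$sigma)
  r <- cfg$radius
  padded <- lapply(stack, pad_reflect, r = r)
  n1 <- nrow(padded[[1]]); n2 <- ncol(padded[[1]])
  ffts <- lapply(padded, stats::fft)
  maps <- list()
  for (b in basis) {
    kf <- Conj(stats::fft(wrap_kernel(b$kernel, n1, n2)))
    for (m in 0:cfg$m_max) {
      res <- stats::fft(ffts[[m + 1L]] * kf, inverse = TRUE) / (n1 * n2)
      maps[[sprintf("%d_%d_%d", b$j, b$k, m)]] <-
        res[(r + 1):(r + nrow(image)), (r + 1):(r + ncol(image)), drop = FALSE]
    }
  }
  structure(list(maps = maps, cfg = cfg, dim = dim(image)),
            class = "wc_raw_features")
}

# Validate the invariance conditions of a descriptor spec. Hard error:
# using a non-invariant combination silently would break the method.
validate_spec <- function(spec) {
  if (nrow(spec$singles) && any(spec$singles$m != spec$singles$k)) {
    stop("invalid descriptor spec: single feature with m != k is not rotation invariant",
         call. = FALSE)
  }
  if (nrow(spec$composites)) {
    rs <- with(spec$composites, m1 - k1 + m2 - k2)
    if (any(rs != 0L)) {
      stop("invalid descriptor spec: composite pair with m1 - k1 + m2 - k2 != 0",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Invariant feature matrix at a set of linear pixel indices (internal,
# vectorized over pixels). Rows = pixels, columns = descriptor entries.
invariant_feature_matrix <- function(raw, spec, idx) {
  validate_spec(spec)
  get_map <- function(j, k, m) {
    key <- sprintf("%d_%d_%d", j, k, m)
    map <- raw$maps[[key]]
    if (is.null(map)) stop("raw feature (", key, ") not available", call. = FALSE)
    map
  }
  cols <- list()
  s <- spec$singles
  for (i in seq_len(nrow(s))) {
    v <- get_map(s$j[i], s$k[i], s$m[i])[idx]
    cols[[length(cols) + 1L]] <- Re(v)
    cols[[length(cols) + 1L]] <- Im(v)
  }
  cp <- spec$composites
  for (i in seq_len(nrow(cp))) {
    v <- get_map(cp$j1[i], cp$k1[i], cp$m1[i])[idx] *
      get_map(cp$j2[i], cp$k2[i], cp$m2[i])[idx]
    cols[[length(cols) + 1L]] <- Re(v)
    cols[[length(cols) + 1L]] <- Im(v)
  }
  mg <- spec$magnitudes
  for (i in seq_len(nrow(mg))) {
    cols[[length(cols) + 1L]] <- Mod(get_map(mg$j[i], mg$k[i], mg$m[i])[idx])
  }
  out <- do.call(cbind, cols)
  colnames(out) <- descriptor_names(spec)
  out
}

#' Rotation-invariant descriptor at a pixel
#'
#' Assembles the real-valued invariant feature vector at one pixel from
#' precomputed raw maps. Every single entry must satisfy `m = k` and every
#' composite pair `m1 - k1 + m2 - k2 = 0`; violations raise an error.
#'
#' @param raw output of [compute_raw_features()].
#' @param spec a [make_descriptor_spec()] (or a hand-built spec of the same
#'   shape).
#' @param centre pixel coordinate `c(x, y)`, 0-based, x = column, y = row.
#' @return named numeric vector.
#' @export
build_invariant_features <- function(raw, spec, centre) {
  x <- centre[1]; y <- centre[2]
  if (x < 0 || y < 0 || y >= raw$dim[1] || x >= raw$dim[2]) {
    stop("centre outside image", call. = FALSE)
  }
  idx <- (y + 1) + raw$dim[1] * x   # column-major linear index
  drop(invariant_feature_matrix(raw, spec, as.integer(idx)))
}

#' Extract the invariant descriptor of a window
#'
#' Full composition gradient -> Fourier encoding -> basis convolutions ->
#' invariant combinations, evaluated at `centre`. Deterministic: identical
#' inputs give bit-identical descriptors.
#'
#' @param image grayscale matrix in \[0, 1\].
#' @param centre pixel coordinate `c(x, y)`, 0-based.
#' @param cfg a [feature_config()].
#' @return named numeric vector (the descriptor).
#' @export
extract_window_descriptor <- function(image, centre, cfg) {
  raw <- compute_raw_features(image, cfg)
  build_invariant_features(raw, make_descriptor_spec(cfg), centre)
}
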