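# Independent, loop-based oracles. These deliberately avoid the package's
# FFT / vectorized code paths.

# Mirror an out-of-range index back into 1..n (edge-including reflection).
reflect_idx <- function(i, n) {
  i <- ifelse(i < 1, 1 - i, i)
  ifelse(i > n, 2 * n + 1 - i, i)
}

# Elementwise finite differences: central in the interior, one-sided at
# the borders.
naive_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0 + 0i, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    dx <- if (c == 1) img[r, 2] - img[r, 1]
          else if (c == nc) img[r, nc] - img[r, nc - 1]
          else (img[r, c + 1] - img[r, c - 1]) / 2
    dy <- if (r == 1) img[2, c] - img[1, c]
          else if (r == nr) img[nr, c] - img[nr - 1, c]
          else (img[r + 1, c] - img[r - 1, c]) / 2
    out[r, c] <- complex(real = dx, imaginary = dy)
  }
  out
}

# Double-loop cross-correlation with the conjugated kernel and reflected
# borders (the package's convolution contract).
naive_corr <- function(x, kern) {
  r <- (nrow(kern) - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0 + 0i, nr, nc)
  for (p in 1:nr) for (q in 1:nc) {
    s <- 0 + 0i
    for (a in -r:r) for (b in -r:r) {
      s <- s + Conj(kern[a + r + 1, b + r + 1]) *
        x[reflect_idx(p + a, nr), reflect_idx(q + b, nc)]
    }
    out[p, q] <- s
  }
  out
}

# Full descriptor pipeline by plain loops: gradient, Fourier encoding,
# correlation evaluated only at the centre pixel, invariant combinations.
naive_descriptor <- function(img, centre, cfg) {
  g <- naive_gradient(img)
  nr <- nrow(img); nc <- ncol(img)
  modes <- list()
  for (m in 0:cfg$m_max) {
    f <- matrix(0 + 0i, nr, nc)
    for (r in 1:nr) for (c in 1:nc) {
      rad <- Mod(g[r, c])
      f[r, c] <- if (rad == 0) 0 + 0i else rad * exp(1i * m * Arg(g[r, c]))
    }
    modes[[m + 1]] <- f
  }
  basis <- make_basis_functions(cfg$radii, cfg$k_max, cfg$window, cfg$sigma)
  rw <- (cfg$window - 1) / 2
  row0 <- centre[2] + 1; col0 <- centre[1] + 1
  raw_at <- function(j, k, m) {
    kern <- NULL
    for (b in basis) if (b$j == j && b$k == k) kern <- b$kernel
    s <- 0 + 0i
    for (a in -rw:rw) for (bb in -rw:rw) {
      s <- s + Conj(kern[a + rw + 1, bb + rw + 1]) *
        modes[[m + 1]][reflect_idx(row0 + a, nr), reflect_idx(col0 + bb, nc)]
    }
    s
  }
  spec <- make_descriptor_spec(cfg)
  vals <- numeric(0)
  for (i in seq_len(nrow(spec$singles))) {
    v <- raw_at(spec$singles$j[i], spec$singles$k[i], spec$singles$m[i])
    vals <- c(vals, Re(v), Im(v))
  }
  for (i in seq_len(nrow(spec$composites))) {
    v <- raw_at(spec$composites$j1[i], spec$composites$k1[i], spec$composites$m1[i]) *
      raw_at(spec$composites$j2[i], spec$composites$k2[i], spec$composites$m2[i])
    vals <- c(vals, Re(v), Im(v))
  }
  for (i in seq_len(nrow(spec$magnitudes))) {
    vals <- c(vals, Mod(raw_at(spec$magnitudes$j[i], spec$magnitudes$k[i],
                               spec$magnitudes$m[i])))
  }
  vals
}

# Windowed population standard deviation by loops, reflected borders.
naive_window_sd <- function(img, window) {
  r <- (window - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (p in 1:nr) for (q in 1:nc) {
    vals <- numeric(0)
    for (a in -r:r) for (b in -r:r) {
      vals <- c(vals, img[reflect_idx(p + a, nr), reflect_idx(q + b, nc)])
    }
    out[p, q] <- sqrt(mean((vals - mean(vals))^2))
  }
  out
}

# Connected components by recursive flood fill (8-connectivity).
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0
  for (p in 1:nr) for (q in 1:nc) {
    if (!mask[p, q] || seen[p, q]) next
    count <- count + 1
    stack <- list(c(p, q))
    seen[p, q] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (a in -1:1) for (b in -1:1) {
        rr <- cur[1] + a; cc <- cur[2] + b
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  count
}

# Exhaustive optimal assignment within a radius: maximize matched pairs,
# break ties by minimal total distance. Feasible only for tiny instances.
exhaustive_match <- function(detections, truth, radius) {
  nd <- nrow(detections); nt <- nrow(truth)
  d <- sqrt(outer(detections$x, truth$x, "-")^2 +
            outer(detections$y, truth$y, "-")^2)
  best <- list(tp = -1, dist = Inf)
  recurse <- function(i, used_t, tp, dist) {
    if (i > nd) {
      if (tp > best$tp || (tp == best$tp && dist < best$dist)) {
        best <<- list(tp = tp, dist = dist)
      }
      return(invisible())
    }
    recurse(i + 1, used_t, tp, dist)   # detection i unmatched
    for (j in seq_len(nt)) {
      if (!used_t[j] && d[i, j] <= radius) {
        used_t[j] <- TRUE
        recurse(i + 1, used_t, tp + 1, dist + d[i, j])
        used_t[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, nt), 0, 0)
  list(TP = best$tp, FP = nd - best$tp, FN = nt - best$tp)
}

# Exact 90-degree grid rotation about the image centre (square images):
# (x, y) -> (-y, x) in 0-based pixel coordinates.
rot90_img <- function(img) {
  n <- nrow(img)
  out <- matrix(0, n, n)
  for (y in 0:(n - 1)) for (x in 0:(n - 1)) {
    out[x + 1, (n - 1 - y) + 1] <- img[y + 1, x + 1]
  }
  out
}
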