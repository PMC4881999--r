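test_that("gradient field matches finite-difference definitions", {
  # constant image: zero gradient everywhere
  g <- compute_gradient_field(matrix(0.5, 6, 6))
  expect_equal(max(Mod(g)), 0)

  # horizontal ramp: pure real (x) gradient in the interior
  w <- 10
  ramp <- matrix(rep((0:(w - 1)) / w, each = w), w, w)   # I(x, y) = x / w
  g <- compute_gradient_field(ramp)
  interior <- g[2:(w - 1), 2:(w - 1)]
  expect_true(all(Re(interior) > 0))
  expect_equal(max(abs(Im(interior))), 0)

  # random image: elementwise agreement with the loop oracle
  set.seed(11)
  img <- matrix(runif(64), 8, 8)
  expect_equal(compute_gradient_field(img), naive_gradient(img), tolerance = 1e-12)

  expect_error(compute_gradient_field(matrix(0.1, 2, 2)), "3 x 3")
})

test_that("Fourier encoding gives r * exp(1i m theta) per mode", {
  f <- matrix(c(0 + 0i, 3 + 0i, 0 + 1i, 1 - 1i), 2, 2)
  st <- fourier_encode_gradients(f, 3)
  # zero gradient stays zero in every mode
  for (m in 0:3) expect_identical(st[[m + 1]][1, 1], 0 + 0i)
  # theta = 0: every mode equals the magnitude
  for (m in 0:3) expect_equal(st[[m + 1]][2, 1], 3 + 0i)
  # theta = pi/2, m = 2: exp(1i * pi) = -1
  expect_equal(st[[3]][1, 2], -1 + 0i, tolerance = 1e-12)
  # mode 0 is the gradient magnitude (real)
  expect_equal(st[[1]], matrix(Mod(f) + 0i, 2, 2), tolerance = 1e-12)
  expect_error(fourier_encode_gradients(f, 0), "m_max")
})

test_that("basis functions are circular harmonics on Gaussian annuli", {
  expect_error(make_basis_functions(numeric(0), 2, 9, 1), "non-empty")
  bs <- make_basis_functions(c(0, 4, 8, 12), 4, 25, 2)

  # j = 0, k = 0: real, non-negative, radially symmetric
  b00 <- bs[[1]]$kernel
  expect_equal(max(abs(Im(b00))), 0)
  expect_true(all(Re(b00) >= 0))
  expect_equal(b00, b00[25:1, ], tolerance = 1e-12)
  expect_equal(b00, t(b00), tolerance = 1e-12)

  # k >= 1 kernels integrate to ~0 (exactly for k = 1..3 by the grid's
  # fourfold symmetry; k = 4 only up to angular quadrature error)
  for (b in bs) {
    if (b$k %in% 1:3) expect_lt(Mod(sum(b$kernel)), 1e-12)
    if (b$k == 4) expect_lt(Mod(sum(b$kernel)), 0.1)
  }

  # rotating the k = 2 kernel grid by 90 degrees multiplies it by
  # exp(1i k pi / 2) = -1
  k2 <- bs[[3 + 5]]$kernel          # j = 1, k = 2
  rot <- matrix(0 + 0i, 25, 25)
  for (y in 0:24) for (x in 0:24) rot[x + 1, 24 - y + 1] <- k2[y + 1, x + 1]
  expect_equal(rot, -k2, tolerance = 1e-12)

  expect_error(make_basis_functions(c(0, 20), 2, 25, 2), "fit")
})

test_that("feature convolution is linear and matches the loop oracle", {
  set.seed(21)
  img <- matrix(runif(225), 15, 15)
  field <- compute_gradient_field(img)
  st <- fourier_encode_gradients(field, 2)
  basis <- make_basis_functions(c(0, 2, 4), 2, 9, 1)

  zero_st <- fourier_encode_gradients(matrix(0 + 0i, 15, 15), 2)
  z <- convolve_features(zero_st, basis[[5]])
  expect_equal(max(Mod(z[[1]])), 0)

  # linearity: doubling the gradient field doubles every raw feature
  st2 <- fourier_encode_gradients(2 * field, 2)
  a <- convolve_features(st, basis[[4]])
  b <- convolve_features(st2, basis[[4]])
  for (m in 0:2) expect_equal(b[[m + 1]], 2 * a[[m + 1]], tolerance = 1e-10)

  # every pixel agrees with the naive double-loop correlation
  for (bidx in c(1, 5, 9)) {
    got <- convolve_features(st, basis[[bidx]])
    for (m in 0:2) {
      expect_equal(got[[m + 1]], naive_corr(st[[m + 1]], basis[[bidx]]$kernel),
                   tolerance = 1e-10)
    }
  }
})

test_that("descriptor spec enforces the invariance conditions", {
  cfg <- feature_config(window = 9)
  raw <- compute_raw_features(matrix(runif(225), 15, 15), cfg)
  spec <- make_descriptor_spec(cfg)

  # generated specs satisfy the conditions by construction
  expect_true(all(spec$singles$m == spec$singles$k))
  expect_true(all(with(spec$composites, m1 - k1 + m2 - k2) == 0))
  expect_lte(nrow(spec$composites), cfg$composite_budget)

  # a single feature with m != k is rejected outright
  bad <- spec
  bad$singles$m[1] <- bad$singles$k[1] + 1L
  expect_error(build_invariant_features(raw, bad, c(7, 7)), "m != k")

  # composite pair (k1=0,m1=1) x (k2=2,m2=1): rotation index sum 0, accepted
  ok <- spec
  ok$composites <- data.frame(j1 = 0L, k1 = 0L, m1 = 1L, j2 = 0L, k2 = 2L, m2 = 1L)
  expect_silent(build_invariant_features(raw, ok, c(7, 7)))

  # pair (k1=0,m1=1) x (k2=0,m2=1): sum 2, rejected
  bad2 <- spec
  bad2$composites <- data.frame(j1 = 0L, k1 = 0L, m1 = 1L, j2 = 0L, k2 = 0L, m2 = 1L)
  expect_error(build_invariant_features(raw, bad2, c(7, 7)), "m1 - k1 \\+ m2 - k2")

  expect_error(build_invariant_features(raw, spec, c(50, 7)), "outside")
})

test_that("the (j,k=0,m=0) single is the ring-weighted sum of gradient magnitudes", {
  set.seed(31)
  img <- matrix(runif(21 * 21), 21, 21)
  cfg <- feature_config(window = 13, use_magnitudes = FALSE, composite_budget = 0)
  raw <- compute_raw_features(img, cfg)
  spec <- make_descriptor_spec(cfg)
  v <- build_invariant_features(raw, spec, c(10, 10))

  r <- Mod(naive_gradient(img))
  basis <- make_basis_functions(cfg$radii, cfg$k_max, cfg$window, cfg$sigma)
  w1 <- Re(basis[[cfg$k_max + 2]]$kernel)   # j = 1, k = 0
  rw <- cfg$radius
  expected <- sum(w1 * r[(11 - rw):(11 + rw), (11 - rw):(11 + rw)])
  expect_equal(unname(v["s_j1k0_re"]), expected, tolerance = 1e-10)
  expect_equal(unname(v["s_j1k0_im"]), 0, tolerance = 1e-10)
})

test_that("window descriptors are deterministic and zero on constant input", {
  cfg <- feature_config(window = 9)
  flat <- matrix(0.4, 15, 15)
  expect_equal(max(abs(extract_window_descriptor(flat, c(7, 7), cfg))), 0)

  set.seed(41)
  img <- matrix(runif(225), 15, 15)
  d1 <- extract_window_descriptor(img, c(7, 7), cfg)
  d2 <- extract_window_descriptor(img, c(7, 7), cfg)
  expect_identical(d1, d2)
})

test_that("descriptors of an analytically re-rendered rotated blob agree", {
  n <- 49; ctr <- (n - 1) / 2
  cfg <- feature_config(window = 25)
  base <- matrix(0.55, n, n)
  d0 <- extract_window_descriptor(render_blob(base, ctr, ctr, 0), c(ctr, ctr), cfg)
  rel <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
  # default animal-scale blob: body width ~2.6 px is near the sampling
  # limit, so grid discretization (not the algebra) dominates the error
  for (ang in c(0.646, 2.1)) {
    d1 <- extract_window_descriptor(render_blob(base, ctr, ctr, ang), c(ctr, ctr), cfg)
    expect_lt(rel(d1, d0), 0.25)
  }
  # a smoother body profile brings the same comparison much tighter
  s0 <- extract_window_descriptor(render_blob(base, ctr, ctr, 0, 4.5, 2.2),
                                  c(ctr, ctr), cfg)
  s1 <- extract_window_descriptor(render_blob(base, ctr, ctr, 0.646, 4.5, 2.2),
                                  c(ctr, ctr), cfg)
  expect_lt(rel(s1, s0), 0.11)
})

test_that("descriptors are exactly invariant under 90/180/270 degree rotations", {
  cfg <- feature_config(window = 25)
  set.seed(51)
  for (rep in 1:5) {
    img <- matrix(runif(625, 0.2, 0.8), 25, 25)
    img <- pmin(pmax(render_blob(img, 12, 12, runif(1, 0, 2 * pi)), 0), 1)
    d0 <- extract_window_descriptor(img, c(12, 12), cfg)
    rot <- img
    for (q in 1:3) {
      rot <- rot90_img(rot)
      dq <- extract_window_descriptor(rot, c(12, 12), cfg)
      expect_lt(max(abs(dq - d0)) / max(max(abs(d0)), 1), 1e-10)
    }
  }
})

test_that("raw features transform by exp(1i alpha (m - k)) under rotation", {
  cfg <- feature_config(window = 25)
  set.seed(61)
  n <- 25
  img <- matrix(runif(n * n, 0.2, 0.8), n, n)
  raw0 <- compute_raw_features(img, cfg)
  raw1 <- compute_raw_features(rot90_img(img), cfg)
  idx <- 13 + n * 12   # centre pixel, column-major
  for (j in 0:3) for (k in 0:4) for (m in 0:4) {
    v0 <- raw0$maps[[sprintf("%d_%d_%d", j, k, m)]][idx]
    v1 <- raw1$maps[[sprintf("%d_%d_%d", j, k, m)]][idx]
    pred <- exp(1i * (pi / 2) * (m - k)) * v0
    expect_lt(Mod(v1 - pred) / max(Mod(v0), 1), 1e-10)
  }
})

test_that("singles scale linearly and composites quadratically with contrast", {
  set.seed(71)
  n <- 15
  base <- matrix(runif(n * n, -0.4, 0.4), n, n)
  img1 <- 0.5 + 0.5 * base
  img2 <- 0.5 + 0.25 * base    # half the contrast
  cfg <- feature_config(window = 9, use_magnitudes = FALSE)
  spec <- make_descriptor_spec(cfg)
  ns <- 2 * nrow(spec$singles)
  d1 <- extract_window_descriptor(img1, c(7, 7), cfg)
  d2 <- extract_window_descriptor(img2, c(7, 7), cfg)
  expect_equal(d2[1:ns], d1[1:ns] / 2, tolerance = 1e-10)
  expect_equal(d2[-(1:ns)], d1[-(1:ns)] / 4, tolerance = 1e-10)
})

test_that("vectorized descriptor extraction matches the naive loop pipeline", {
  set.seed(81)
  cfg <- feature_config(window = 9)
  for (rep in 1:3) {
    img <- matrix(runif(225), 15, 15)
    centre <- c(sample(4:10, 1), sample(4:10, 1))
    fast <- unname(extract_window_descriptor(img, centre, cfg))
    slow <- naive_descriptor(img, centre, cfg)
    expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-10)
  }
})
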