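# Preprocessing: ROI extraction, fusion-frame detection, background,
# truncation, variance stabilization.

test_that("extract_roi crops exactly and refuses to pad", {
  arr <- array(seq_len(20 * 24 * 3), dim = c(20, 24, 3))
  # full-image crop is the identity
  full <- extract_roi(arr, center = c(10, 12), size = c(19, 23))
  expect_equal(dim(full$data), c(19, 23, 3))
  roi <- extract_roi(arr, center = c(10, 12), size = c(5, 7))
  expect_equal(roi$origin, c(8L, 9L))
  # origin + size reconstructs the crop from the parent
  expect_identical(roi$data, arr[8:12, 9:15, , drop = FALSE])
  # overlapping ROIs agree on shared pixels (rows 9:12, cols 10:15)
  roi2 <- extract_roi(arr, center = c(11, 13), size = c(5, 7))
  expect_identical(roi$data[2:5, 2:7, ], roi2$data[1:4, 1:6, ])
  expect_error(extract_roi(arr, center = c(2, 12), size = c(5, 5)), "border")
  expect_error(extract_roi(arr, center = c(10, 23), size = c(5, 5)), "border")
})

test_that("detect_t0 finds the fusion frame of a rendered event", {
  sc <- scene_spec(image_dims = c(31, 31), T = 120,
                   spot = diffusion_params(0.5, 500, c(16, 16), t0 = 37),
                   noise_sigma = 1.5, seed = 4L)
  out <- render_analytic(sc)
  roi <- roi_series(out$seq$data)
  expect_equal(detect_t0(roi), 37)

  # monotone decay starts at the first frame
  decay <- sapply(1:30, function(t) render_frame(c(15, 15), t,
    diffusion_params(0.3, 100, c(8, 8)), optics_params()), simplify = "array")
  expect_equal(detect_t0(roi_series(decay)), 1L)

  # constant sequence: earliest frame by the tie rule
  expect_equal(detect_t0(roi_series(array(2, dim = c(5, 5, 9)))), 1L)
  expect_equal(detect_t0(roi_series(array(2, dim = c(5, 5, 9))), "total"), 1L)
})

test_that("estimate_background takes the pixelwise temporal median", {
  # constant background + transient early spot: exact recovery
  arr <- array(7, dim = c(9, 9, 30))
  arr[4:6, 4:6, 1:5] <- 50
  roi <- roi_series(arr)
  expect_equal(estimate_background(roi, 20, smooth = "none"),
               matrix(7, 9, 9))
  expect_equal(estimate_background(roi, 20, smooth = "plane"),
               matrix(7, 9, 9), tolerance = 1e-10)

  # n_frames = 1 returns that frame verbatim
  set.seed(6)
  arr2 <- array(stats::rnorm(9 * 9 * 4), dim = c(9, 9, 4))
  expect_equal(estimate_background(roi_series(arr2), 1, smooth = "none"),
               arr2[, , 4])

  # odd frame count on integer data stays integer-valued
  arr3 <- array(sample(1:10, 7 * 7 * 5, TRUE), dim = c(7, 7, 5))
  bg <- estimate_background(roi_series(arr3), 5, smooth = "none")
  expect_true(all(bg == round(bg)))

  expect_error(estimate_background(roi_series(arr3), 9), "n_frames")

  # plane smoothing reproduces a noiseless tilted-plane background exactly
  plane <- outer(0.2 * (1:9), 0.1 * (1:9), "+") + 3
  roi_p <- roi_series(array(rep(plane, 25), dim = c(9, 9, 25)))
  expect_equal(estimate_background(roi_p, 20, smooth = "plane"), plane,
               tolerance = 1e-10)
})

test_that("subtract_background is pixelwise, signed, and shape-checked", {
  arr <- array(5, dim = c(4, 4, 6))
  bg <- matrix(8, 4, 4)
  out <- subtract_background(roi_series(arr), bg)
  expect_equal(out$data, array(-3, dim = c(4, 4, 6)))  # no clipping
  expect_error(subtract_background(roi_series(arr), matrix(0, 3, 4)),
               "dimensions")
})

test_that("truncate_series keeps [t0, t0 + T_fit) and re-anchors t0", {
  arr <- array(seq_len(3 * 3 * 50), dim = c(3, 3, 50))
  roi <- roi_series(arr)
  expect_identical(truncate_series(roi, 1, 50)$data, arr)  # identity
  tr <- truncate_series(roi, 11, 20)
  expect_identical(tr$data, arr[, , 11:30, drop = FALSE])
  expect_equal(tr$t0, 1L)
  expect_warning(short <- truncate_series(roi, 41, 20), "keeping all")
  expect_equal(dim(short$data)[3], 10)  # min(T_fit, frames after t0)
  expect_error(truncate_series(roi, 0, 5), "t0")
  expect_error(truncate_series(roi, 51, 5), "t0")
})

test_that("generalized Anscombe: classical limit, monotonicity, clamping", {
  x <- seq(0, 50, by = 0.5)
  expect_equal(generalized_anscombe(x, gain = 1, sigma_read = 0, offset = 0),
               2 * sqrt(x + 3 / 8))
  y <- generalized_anscombe(seq(-5, 20, 0.1), gain = 2, sigma_read = 3,
                            offset = 1)
  expect_true(all(diff(y) >= 0))
  # below the domain floor the transform clamps at the floor value
  expect_equal(generalized_anscombe(-100, gain = 1, sigma_read = 0.1,
                                    offset = 0), 0)
  expect_error(generalized_anscombe(x, gain = 0), "positive")
  # shape preserved
  arr <- array(1:24, dim = c(2, 3, 4))
  expect_equal(dim(generalized_anscombe(arr, 2, 1, 0)), c(2, 3, 4))
})

test_that("the transform flattens Poisson-Gaussian noise across intensities", {
  set.seed(8)
  gain <- 2; sr <- 3; off <- 10
  lambdas <- c(10, 20, 40, 70, 100)  # 10x intensity range
  sds <- sapply(lambdas, function(l) {
    x <- gain * stats::rpois(2e4, l) + stats::rnorm(2e4, off, sr)
    stats::sd(generalized_anscombe(x, gain, sr, off))
  })
  expect_lt(max(sds) / min(sds) - 1, 0.10)
})

test_that("noise parameters are estimated robustly from dark pixels", {
  set.seed(9)
  img <- c(stats::rnorm(5e3, 100, 3), stats::rnorm(5e4, 1000, 30))
  np <- estimate_noise_params(img)
  expect_equal(np$offset, 100, tolerance = 0.05)
  expect_equal(np$sigma_read, 3, tolerance = 0.3)
})

test_that("the preprocessing pipeline is deterministic and spot-anchored", {
  sc <- scene_spec(image_dims = c(41, 41), T = 160,
                   spot = diffusion_params(0.4, 400, c(21.3, 20.6), t0 = 31),
                   background = 5, noise_sigma = 1, seed = 10L)
  out <- render_analytic(sc)
  cfg <- preprocess_config(roi_size = c(31, 31), T_fit = 100)
  r1 <- preprocess_roi(out$seq$data, c(21, 21), cfg)
  r2 <- preprocess_roi(out$seq$data, c(21, 21), cfg)
  expect_identical(r1, r2)
  expect_equal(dim(r1$data)[3], 100)
  # frame 1 of the output is the detected fusion frame (brightest)
  peaks <- apply(r1$data, 3, max)
  expect_equal(which.max(peaks), 1L)
})

test_that("background subtraction zeroes the fluctuation curve of pure background", {
  set.seed(13)
  sigma <- 1.2
  arr <- array(stats::rnorm(31 * 31 * 200, mean = 20, sd = sigma),
               dim = c(31, 31, 200))
  roi <- roi_series(arr)
  bg <- estimate_background(roi, 20)
  sub <- subtract_background(roi, bg)
  g <- empirical_autocorr(sub, max_lag = 10, variant = "fluctuation")
  expect_lt(max(abs(g$values)), 5 * sigma^2 / 31)
})

test_that("pipeline + ABC recovers the generating D end to end", {
  D_true <- 0.5
  sc <- scene_spec(image_dims = c(61, 61), T = 200,
                   spot = diffusion_params(D_true, 500, c(31.4, 30.7), t0 = 41),
                   background = list(b0 = 8, br = 0.05, bc = -0.04),
                   noise_sigma = peak_amp(D_true) / 8, seed = 14L)
  out <- render_analytic(sc)
  # fit over the full available post-fusion window (160 frames)
  res <- estimate_spot(out$seq$data, c(31, 31),
                       run_config(model = "g1", n_samples = 2e4, seed = 15,
                                  T_fit = 160L))
  expect_lt(abs(res$fit$d_mmse - D_true) / D_true, 0.3)
  expect_lt(abs(res$fit$d_map - D_true) / D_true, 0.3)
})
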