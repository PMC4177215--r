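test_that("image generation is seed-deterministic and validates input", {
  a <- generate_images(4, size = 32, seed = 9)
  b <- generate_images(4, size = 32, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, generate_images(4, size = 32, seed = 10)))
  expect_error(generate_images(0, size = 32), "at least 1")
  expect_error(generate_images(2, size = 32, kind = "fractal"), "arg")
  expect_true(all(a >= 0 & a <= 1))
  # generators leave the global RNG state alone
  set.seed(77); before <- .Random.seed
  invisible(generate_images(2, size = 32, seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("pink-noise images have a natural-image-like spectral slope", {
  imgs <- generate_images(20, size = 64, seed = 21)
  slope_of <- function(img) {
    A <- abs(stats::fft(img - mean(img)))
    n <- nrow(img)
    fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    rad <- sqrt(outer(fr^2, fr^2, "+"))
    keep <- rad > 0.02 & rad < 0.4
    stats::coef(stats::lm(log(A[keep]) ~ log(rad[keep])))[2]
  }
  slopes <- apply(imgs, 3, slope_of)
  expect_gt(mean(slopes), -1.4)
  expect_lt(mean(slopes), -0.6)
})

test_that("gabor-composite images render deterministically in [0,1]", {
  g <- generate_images(3, size = 32, kind = "gabor_composite", seed = 5)
  expect_identical(g, generate_images(3, size = 32, kind = "gabor_composite",
                                      seed = 5))
  expect_true(all(g >= 0 & g <= 1))
})

test_that("noiseless target responses equal the ground-truth signal exactly", {
  pyr <- tiny_pyramid(size = 32, frequencies = c(1, 2, 4))
  ftr <- gabor_features(random_images(40, 32, seed = 31), pyr)
  fte <- gabor_features(random_images(10, 32, seed = 32), pyr)
  e <- generate_erc(ftr, fte, n_voxels = 8, snr = Inf, latent_frac = 0,
                    seed = 3)
  expect_equal(e$train, e$ground_truth$signal_train, tolerance = 1e-12)
  expect_equal(e$test, e$ground_truth$signal_test, tolerance = 1e-12)
  # and the stored effective kernels reproduce the signal from features
  manual <- unclass(ftr) %*% e$ground_truth$kernels +
    rep(e$ground_truth$constants, each = nrow(ftr))
  expect_equal(unname(e$train), unname(manual), tolerance = 1e-10)
})

test_that("responses hit the requested signal-to-noise ratio", {
  pyr <- tiny_pyramid(size = 32, frequencies = c(1, 2, 4))
  ftr <- gabor_features(random_images(500, 32, seed = 33), pyr)
  fte <- gabor_features(random_images(10, 32, seed = 34), pyr)
  for (snr in c(1, 2)) {
    e <- generate_erc(ftr, fte, n_voxels = 12, snr = snr, seed = 4)
    resid <- e$train - e$ground_truth$signal_train
    emp <- apply(e$ground_truth$signal_train, 2, stats::sd) /
      apply(resid, 2, stats::sd)
    expect_true(all(abs(emp / snr - 1) < 0.15))
  }
})

test_that("synthetic regions are reproducible and labelled", {
  pyr <- tiny_pyramid(size = 32, frequencies = c(1, 2, 4))
  ftr <- gabor_features(random_images(60, 32, seed = 35), pyr)
  fte <- gabor_features(random_images(10, 32, seed = 36), pyr)
  e1 <- generate_erc(ftr, fte, n_voxels = 10, seed = 7)
  e2 <- generate_erc(ftr, fte, n_voxels = 10, seed = 7)
  expect_identical(e1$train, e2$train)
  expect_identical(e1$ground_truth$kernels, e2$ground_truth$kernels)
  expect_true(all(e1$ground_truth$roi %in% c("V1", "V2", "V3")))
  l1 <- generate_loc(e1, n_voxels = 6, seed = 8)
  l2 <- generate_loc(e1, n_voxels = 6, seed = 8)
  expect_identical(l1$train, l2$train)
  expect_error(generate_erc(ftr, fte, kernel_sparsity = 0), "sparsity")
  expect_error(generate_loc(e1, mixing_density = 2), "mixing_density")
})

test_that("a noise-free invertible mixture can be linearly inverted", {
  pyr <- tiny_pyramid(size = 32, frequencies = c(1, 2, 4))
  ftr <- gabor_features(random_images(80, 32, seed = 37), pyr)
  fte <- gabor_features(random_images(10, 32, seed = 38), pyr)
  e <- generate_erc(ftr, fte, n_voxels = 10, snr = Inf, seed = 9)
  l <- generate_loc(e, n_voxels = 10, mixing_density = 1, snr = Inf, seed = 10)
  # least-squares mapping from source back to target signals
  sig <- sweep(e$ground_truth$signal_train, 2, e$ground_truth$constants, "-")
  B <- qr.solve(l$train, sig)
  expect_lt(max(abs(l$train %*% B - sig)), 1e-6)
})

test_that("per-band SNR gradients scale voxel noise as configured", {
  pyr <- tiny_pyramid(size = 32, frequencies = c(1, 2, 4))
  ftr <- gabor_features(random_images(400, 32, seed = 39), pyr)
  fte <- gabor_features(random_images(10, 32, seed = 40), pyr)
  g <- 1.5
  e <- generate_erc(ftr, fte, n_voxels = 40, snr = 2, roi_snr_gradient = g,
                    seed = 11)
  resid <- e$train - e$ground_truth$signal_train
  emp <- apply(e$ground_truth$signal_train, 2, stats::sd) /
    apply(resid, 2, stats::sd)
  roi <- e$ground_truth$roi
  if (all(c("V1", "V3") %in% roi)) {
    expect_gt(mean(emp[roi == "V1"]), mean(emp[roi == "V3"]))
    expect_equal(mean(emp[roi == "V1"]) / (2 * (1 + g)), 1, tolerance = 0.15)
    expect_equal(mean(emp[roi == "V3"]) * (1 + g) / 2, 1, tolerance = 0.15)
  }
})
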