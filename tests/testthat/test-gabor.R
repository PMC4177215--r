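test_that("pyramid channel counts follow the tiling law", {
  # default configuration: six frequencies, eight orientations, luminance
  expect_equal(pyramid_size(gabor_pyramid()), 10921L)
  expect_equal(pyramid_size(gabor_pyramid(frequencies = 1)), 9L)
  expect_equal(pyramid_size(gabor_pyramid(frequencies = c(1, 2))), 41L)
  # count law on random configurations
  for (s in 1:6) {
    cfg <- with_seed_test(s, list(
      size = sample(c(32, 48, 64), 1),
      freqs = sort(sample(1:12, sample(2:4, 1))),
      oris = seq(0, 179, length.out = sample(2:8, 1)),
      lum = sample(c(TRUE, FALSE), 1)))
    pyr <- gabor_pyramid(image_size = cfg$size, frequencies = cfg$freqs,
                         orientations = cfg$oris,
                         include_luminance = cfg$lum)
    expect_equal(pyramid_size(pyr),
                 sum(cfg$freqs^2) * length(cfg$oris) + as.integer(cfg$lum))
  }
})

test_that("invalid pyramid configurations are rejected by name", {
  expect_error(gabor_pyramid(frequencies = c(1, 0)), "invalid frequency 0")
  expect_error(gabor_pyramid(frequencies = c(2, -4)), "invalid frequency -4")
  expect_error(gabor_pyramid(image_size = 32, frequencies = c(1, 32)),
               "invalid frequency 32.*Nyquist")
  expect_error(gabor_pyramid(orientations = c(0, 180)), "180")
  expect_error(gabor_pyramid(log_offset = 0), "log_offset")
})

test_that("channel ordering is luminance first, then frequency/grid/orientation", {
  pyr <- tiny_pyramid()
  ch <- pyr$channels
  expect_true(ch$is_luminance[1])
  bp <- ch[-1, ]
  expect_true(!is.unsorted(bp$frequency))
  f1 <- bp[bp$frequency == 2, ]
  key <- f1$grid_row * 2 + f1$grid_col + f1$orientation / 1000
  expect_true(!is.unsorted(key))
})

test_that("rendered wavelets have the analytic quadrature structure", {
  pyr <- tiny_pyramid()
  ch <- pyr$channels
  npix <- pyr$image_size^2
  for (k in which(!ch$is_luminance)) {
    w <- render_wavelet(pyr, k)
    expect_lt(abs(sum(w$odd)), 1e-8 * npix)
  }
  # envelope scales inversely with frequency
  expect_equal(ch$sigma[which(ch$frequency == 4)][1] /
                 ch$sigma[which(ch$frequency == 1)][1], 1 / 4)
  # even/odd orthogonality for wavelets whose envelope fits the canvas
  # (border cells are clipped by the canvas and are not quadrature-exact)
  interior <- which(ch$frequency == 4 &
                      ch$grid_row %in% 1:2 & ch$grid_col %in% 1:2)
  for (k in interior) {
    w <- render_wavelet(pyr, k)
    ip <- abs(sum(w$even * w$odd)) / sqrt(sum(w$even^2) * sum(w$odd^2))
    expect_lt(ip, 1e-3)
  }
  # luminance wavelet: uniform, unit sum, zero odd phase
  lum <- render_wavelet(pyr, 1)
  expect_equal(sum(lum$even), 1)
  expect_equal(length(unique(as.vector(lum$even))), 1L)
  expect_true(all(lum$odd == 0))
})

test_that("featurize matches the brute-force per-wavelet oracle", {
  pyr <- tiny_pyramid(size = 32, frequencies = c(1, 2, 4))
  imgs <- random_images(3, size = 32, seed = 11)
  got <- gabor_features(imgs, pyr)
  want <- featurize_oracle(imgs, pyr)
  expect_lt(max(abs(unclass(got) - want)), 1e-10)
  # chunked path agrees with the precomputed-bank path
  bank <- gabor_filter_bank(pyr)
  expect_equal(unclass(gabor_features(imgs, pyr, bank = bank)),
               unclass(got), tolerance = 1e-14)
})

test_that("an all-zero image yields all-zero features", {
  pyr <- tiny_pyramid(size = 32, frequencies = c(1, 2))
  f <- gabor_features(matrix(0, 32, 32), pyr)
  expect_true(all(f == 0))
})

test_that("featurize rejects malformed stimulus input", {
  pyr <- tiny_pyramid(size = 32, frequencies = c(1, 2))
  expect_error(gabor_features(matrix(0, 16, 16), pyr), "expects 32x32")
  bad <- matrix(0, 32, 32); bad[5, 5] <- NA
  expect_error(gabor_features(bad, pyr), "non-finite")
})

test_that("a matched grating drives its own orientation hardest", {
  size <- 64
  pyr <- gabor_pyramid(image_size = size, frequencies = 4,
                       orientations = c(45, 135), include_luminance = FALSE)
  px <- seq_len(size) - 0.5
  u <- outer(sin(pi / 4) * px, cos(pi / 4) * px, "+")
  grating <- 0.5 + 0.5 * cos(2 * pi * 4 / size * u)
  f <- gabor_features(grating, pyr)
  ch <- pyr$channels
  centre <- ch$grid_row %in% 1:2 & ch$grid_col %in% 1:2
  f45 <- f[1, centre & ch$orientation == 45]
  f135 <- f[1, centre & ch$orientation == 135]
  expect_true(all(f45 > f135))
})

test_that("features shift with the stimulus across the wavelet grid", {
  size <- 64
  pyr <- gabor_pyramid(image_size = size, frequencies = 8,
                       orientations = c(0, 90), include_luminance = FALSE)
  cell <- size / 8
  patch <- with_seed_test(5, matrix(runif(cell * cell), cell, cell))
  place <- function(r, c) {
    img <- matrix(0, size, size)
    img[(r * cell + 1):((r + 1) * cell), (c * cell + 1):((c + 1) * cell)] <- patch
    img
  }
  ch <- pyr$channels
  argmax_cell <- function(img) {
    f <- gabor_features(img, pyr)
    k <- which.max(f[1, ])
    c(ch$grid_row[k], ch$grid_col[k])
  }
  expect_equal(argmax_cell(place(3, 3)), c(3, 3))
  expect_equal(argmax_cell(place(3, 4)), c(3, 4))
})

test_that("raising contrast never lowers a band-pass feature", {
  pyr <- tiny_pyramid(size = 32, frequencies = c(1, 2, 4))
  img <- random_images(1, size = 32, seed = 3)[, , 1]
  f1 <- gabor_features(img, pyr)
  f2 <- gabor_features(2.5 * img, pyr)
  bp <- !pyr$channels$is_luminance
  expect_true(all(f2[1, bp] >= f1[1, bp]))
})
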