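# Small in-code fixtures shared across test files.

# Reduced pyramid used throughout the unit tests: 64 px, frequencies 1-4,
# 41 band-pass channels + luminance.
tiny_pyramid <- function(size = 64, frequencies = c(1, 2, 4), ...) {
  gabor_pyramid(image_size = size, frequencies = frequencies, ...)
}

random_images <- function(n, size = 64, seed = 1) {
  with_seed_test(seed, {
    array(runif(size * size * n), c(size, size, n),
          dimnames = list(NULL, NULL, sprintf("stim_%d", seq_len(n))))
  })
}

# Local seed sandboxing for test-side oracles.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Brute-force featurization oracle: renders every wavelet and computes the
# log quadrature magnitude directly, independently of gabor_features()'s
# chunked matrix path.
featurize_oracle <- function(images, pyramid) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1))
  n <- dim(images)[3]
  q <- nrow(pyramid$channels)
  out <- matrix(NA_real_, n, q)
  for (i in seq_len(n)) {
    img <- images[, , i]
    ctr <- img - mean(img)
    for (k in seq_len(q)) {
      w <- render_wavelet(pyramid, k)
      if (pyramid$channels$is_luminance[k]) {
        m <- abs(sum(img * w$even))
      } else {
        m <- sqrt(sum(ctr * w$even)^2 + sum(ctr * w$odd)^2)
      }
      out[i, k] <- log(pyramid$log_offset + m)
    }
  }
  out
}

# Build an encoding_model by hand from known kernels/constants (identity
# standardization), for testing predict()'s algebra in isolation.
manual_model <- function(kernels, constants) {
  q <- nrow(kernels); V <- ncol(kernels)
  structure(list(kernels = kernels, constants = constants,
                 center = rep(0, q), scale = rep(1, q), standardize = FALSE,
                 control = train_control(), channel_ids = rownames(kernels),
                 voxel_ids = colnames(kernels) %||% sprintf("v%d", seq_len(V)),
                 diagnostics = data.frame(voxel = sprintf("v%d", seq_len(V)),
                                          iterations = 0L, stop_mse = 0,
                                          degenerate = FALSE),
                 n_train = 0L, call = NULL),
            class = "encoding_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
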