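#' Construct a Gabor wavelet pyramid
#'
#' Builds the dictionary of Gabor wavelets used to featurize grayscale images
#' for stimulus encoding models. At each spatial frequency of `n` cycles per
#' field of view (FOV), wavelets tile the image on an `n` x `n` grid, and occur
#' at every requested orientation; an optional luminance-only channel (a
#' uniform filter covering the whole image) is prepended. With the defaults
#' (frequencies 1, 2, 4, 8, 16, 32 cycles/FOV and eight orientations) the
#' pyramid has (1 + 4 + 16 + 64 + 256 + 1024) * 8 + 1 = 10921 channels.
#'
#' Each wavelet is a Gaussian-enveloped sinusoid rendered as a quadrature pair
#' (cosine- and sine-phase). The envelope standard deviation is tied to the
#' carrier period so every frequency band has the same bandwidth in octaves:
#' `sigma = (image_size / frequency) * sqrt(log(2)/2) / pi * (2^b + 1) / (2^b - 1)`,
#' the standard Gabor half-amplitude bandwidth relation with `b =
#' bandwidth_octaves`.
#'
#' @param image_size Image side length in pixels (images must be
#'   `image_size` x `image_size`).
#' @param frequencies Integer spatial frequencies in cycles/FOV. Each must be
#'   positive and at most `image_size / 2` (Nyquist).
#' @param orientations Orientations in degrees, each in `[0, 180)`, measured
#'   counterclockwise from the horizontal axis.
#' @param bandwidth_octaves Half-amplitude frequency bandwidth of the Gaussian
#'   envelope, in octaves.
#' @param include_luminance Include the luminance-only channel?
#' @param log_offset Constant added inside the log when featurizing;
#'   must be positive. With the default 1 all features are non-negative.
#' @param field_of_view Field of view in degrees (metadata only; does not
#'   affect any computation).
#'
#' @return An object of class `gabor_pyramid`: a list with the configuration
#'   and a `channels` data frame (one row per wavelet, luminance channel
#'   first, then frequencies ascending, grid positions row-major, orientations
#'   ascending) with columns `frequency`, `grid_row`, `grid_col` (0-based),
#'   `orientation`, `is_luminance`, `sigma` (envelope s.d. in pixels).
#' @seealso [gabor_features()], [render_wavelet()]
#' @export
gabor_pyramid <- function(image_size = 128,
                          frequencies = c(1, 2, 4, 8, 16, 32),
                          orientations = seq(0, 157.5, by = 22.5),
                          bandwidth_octaves = 1,
                          include_luminance = TRUE,
                          log_offset = 1,
                          field_of_view = 20) {
  if (length(image_size) != 1L || !is.finite(image_size) || image_size <= 0 ||
      image_size != round(image_size))
    stop("image_size must be a positive integer", call. = FALSE)
  if (length(frequencies) < 1L || anyDuplicated(frequencies))
    stop("frequencies must be a non-empty set of distinct values", call. = FALSE)
  bad <- frequencies[!is.finite(frequencies) | frequencies <= 0 |
                       frequencies != round(frequencies) |
                       frequencies > image_size / 2]
  if (length(bad))
    stop(sprintf(
      "invalid frequency %s: frequencies must be positive integers <= image_size/2 (Nyquist, here %g)",
      paste(bad, collapse = ", "), image_size / 2), call. = FALSE)
  if (length(orientations) < 1L ||
      any(!is.finite(orientations) | orientations < 0 | orientations >= 180))
    stop("orientations must lie in [0, 180) degrees", call. = FALSE)
  if (length(log_offset) != 1L || !is.finite(log_offset) || log_offset <= 0)
    stop("log_offset must be positive", call. = FALSE)
  if (length(bandwidth_octaves) != 1L || !is.finite(bandwidth_octaves) ||
      bandwidth_octaves <= 0)
    stop("bandwidth_octaves must be positive", call. = FALSE)

  frequencies <- sort(frequencies)
  orientations <- sort(orientations)
  b <- bandwidth_octaves
  bw_k <- sqrt(log(2) / 2) / pi * (2^b + 1) / (2^b - 1)

  rows <- lapply(frequencies, function(f) {
    grid <- expand.grid(orientation = orientations,
                        grid_col = seq_len(f) - 1L,
                        grid_row = seq_len(f) - 1L)
    data.frame(frequency = f,
               grid_row = grid$grid_row, grid_col = grid$grid_col,
               orientation = grid$orientation,
               is_luminance = FALSE,
               sigma = image_size / f * bw_k)
  })
  channels <- do.call(rbind, rows)
  if (include_luminance) {
    lum <- data.frame(frequency = NA_real_, grid_row = NA_integer_,
                      grid_col = NA_integer_, orientation = NA_real_,
                      is_luminance = TRUE, sigma = NA_real_)
    channels <- rbind(lum, channels)
  }
  rownames(channels) <- NULL
  channels$channel_id <- channel_ids(channels)

  structure(list(image_size = as.integer(image_size),
                 frequencies = frequencies,
                 orientations = orientations,
                 bandwidth_octaves = bandwidth_octaves,
                 include_luminance = include_luminance,
                 log_offset = log_offset,
                 field_of_view = field_of_view,
                 channels = channels),
            class = "gabor_pyramid")
}

channel_ids <- function(channels) {
  ifelse(channels$is_luminance, "lum",
         sprintf("f%g_r%d_c%d_o%g", channels$frequency, channels$grid_row,
                 channels$grid_col, channels$orientation))
}

#' @export
print.gabor_pyramid <- function(x, ...) {
  cat("Gabor wavelet pyramid\n")
  cat(sprintf("  image size:   %d x %d px (FOV %g deg)\n",
              x$image_size, x$image_size, x$field_of_view))
  cat(sprintf("  frequencies:  %s cycles/FOV\n",
              paste(x$frequencies, collapse = ", ")))
  cat(sprintf("  orientations: %s deg\n",
              paste(x$orientations, collapse = ", ")))
  cat(sprintf("  luminance channel: %s\n",
              if (x$include_luminance) "yes" else "no"))
  cat(sprintf("  channels:     %d\n", nrow(x$channels)))
  invisible(x)
}

#' Number of channels in a pyramid
#' @param pyramid A [gabor_pyramid()].
#' @return Integer channel count.
#' @export
pyramid_size <- function(pyramid) {
  stopifnot(inherits(pyramid, "gabor_pyramid"))
  nrow(pyramid$channels)
}

#' Render one wavelet of a pyramid as a quadrature pair
#'
#' Renders the even-phase (cosine) and odd-phase (sine) components of a
#' wavelet on the full image canvas (no spatial cropping). Grid cell centers
#' sit at `(i + 0.5) / n` of the image extent; pixel centers at half-integer
#' coordinates. Band-pass components are rendered zero-mean (the residual DC
#' from canvas truncation is removed; this does not change any feature value
#' because images are mean-centered before band-pass filtering). The
#' luminance wavelet is a uniform filter with unit sum and an all-zero odd
#' component.
#'
#' @param pyramid A [gabor_pyramid()].
#' @param channel Channel index into `pyramid$channels` (1-based).
#' @return A list with `even` and `odd`, each an `image_size` x `image_size`
#'   matrix (rows indexing the vertical axis).
#' @export
render_wavelet <- function(pyramid, channel) {
  stopifnot(inherits(pyramid, "gabor_pyramid"))
  ch <- pyramid$channels
  if (length(channel) != 1L || channel < 1L || channel > nrow(ch))
    stop("channel index out of range", call. = FALSE)
  S <- pyramid$image_size
  spec <- ch[channel, ]
  if (spec$is_luminance) {
    return(list(even = matrix(1 / (S * S), S, S), odd = matrix(0, S, S)))
  }
  f <- spec$frequency
  # pixel centers at 0.5 .. S - 0.5; wavelet center at the grid cell center
  px <- seq_len(S) - 0.5
  cx <- (spec$grid_col + 0.5) * S / f
  cy <- (spec$grid_row + 0.5) * S / f
  dx <- px - cx           # column offsets (horizontal)
  dy <- px - cy           # row offsets (vertical)
  theta <- spec$orientation * pi / 180
  s2 <- 2 * spec$sigma^2
  env <- exp(-outer(dy^2, dx^2, "+") / s2)
  # carrier varies along the orientation axis: u = dx cos(theta) + dy sin(theta)
  u <- outer(sin(theta) * dy, cos(theta) * dx, "+")
  arg <- 2 * pi * f / S * u
  # Remove the residual DC the finite canvas leaves in each component. The
  # continuous-domain odd filter integrates to zero and the even filter to a
  # negligible constant, but truncation at the canvas edge reintroduces a DC
  # term, largest for border cells. Features are unaffected (images are
  # mean-centered before band-pass filtering), and the filters become exactly
  # insensitive to image DC.
  even <- env * cos(arg)
  odd <- env * sin(arg)
  list(even = even - mean(even), odd = odd - mean(odd))
}

#' Precompute the filter bank of a pyramid
#'
#' Stacks the rendered quadrature pairs as two `(image_size^2)` x `channels`
#' matrices so that featurization reduces to matrix products. For large
#' pyramids this can be memory-hungry (the default 10921-channel pyramid needs
#' about 2.9 GB); [gabor_features()] therefore builds the bank in chunks
#' unless one is supplied.
#'
#' @param pyramid A [gabor_pyramid()].
#' @param channels Optional channel indices (default: all).
#' @return List with matrices `even` and `odd` (pixels x channels, pixels in
#'   column-major order) and the channel indices used.
#' @export
gabor_filter_bank <- function(pyramid, channels = NULL) {
  stopifnot(inherits(pyramid, "gabor_pyramid"))
  channels <- channels %||% seq_len(nrow(pyramid$channels))
  S <- pyramid$image_size
  even <- matrix(0, S * S, length(channels))
  odd <- matrix(0, S * S, length(channels))
  for (k in seq_along(channels)) {
    w <- render_wavelet(pyramid, channels[k])
    even[, k] <- as.vector(w$even)
    odd[, k] <- as.vector(w$odd)
  }
  colnames(even) <- colnames(odd) <- pyramid$channels$channel_id[channels]
  list(even = even, odd = odd, channels = channels)
}

#' Gabor log-magnitude image features
#'
#' Transforms a stack of grayscale images into feature vectors: each image is
#' mean-subtracted (band-pass channels only), filtered with every wavelet's
#' quadrature pair, and each channel's response is the log-compressed
#' quadrature magnitude `log(log_offset + sqrt(e^2 + o^2))`, where `e` and `o`
#' are the pixelwise inner products of the image with the even- and odd-phase
#' filters. The luminance channel applies the uniform filter to the raw
#' (non-mean-subtracted) image, through the same log transform. Pixel values
#' are used as given and are expected on a common scale across images
#' (loaders in this package produce `[0, 1]`).
#'
#' @param images An `S x S x n` array, a single `S x S` matrix, or a list of
#'   matrices, with `S = pyramid$image_size`.
#' @param pyramid A [gabor_pyramid()].
#' @param bank Optional precomputed [gabor_filter_bank()] covering all
#'   channels (reuse it when featurizing many stacks with one pyramid).
#' @param chunk_size Number of wavelets rendered per block when no bank is
#'   supplied; bounds peak memory.
#' @return An `n x channels` feature matrix of class `feature_matrix` with
#'   channel ids as column names and stimulus ids (if present in `images`
#'   dimnames, else `stim_1 ...`) as row names. The pyramid is attached as
#'   attribute `"pyramid"`.
#' @export
gabor_features <- function(images, pyramid, bank = NULL, chunk_size = 512L) {
  stopifnot(inherits(pyramid, "gabor_pyramid"))
  img <- as_image_matrix(images, pyramid$image_size)   # n x S^2
  n <- nrow(img)
  ch <- pyramid$channels
  q <- nrow(ch)
  centered <- img - rowMeans(img)
  out <- matrix(NA_real_, n, q)
  colnames(out) <- ch$channel_id
  rownames(out) <- rownames(img) %||% sprintf("stim_%d", seq_len(n))

  featurize_block <- function(idx, bk) {
    e <- centered %*% bk$even
    o <- centered %*% bk$odd
    if (any(lum <- ch$is_luminance[idx])) {
      e[, lum] <- img %*% bk$even[, lum, drop = FALSE]
      o[, lum] <- 0
    }
    log(pyramid$log_offset + sqrt(e * e + o * o))
  }

  if (!is.null(bank)) {
    if (ncol(bank$even) != q)
      stop("supplied bank does not cover the full pyramid", call. = FALSE)
    out[] <- featurize_block(seq_len(q), bank)
  } else {
    starts <- seq(1L, q, by = chunk_size)
    for (s in starts) {
      idx <- s:min(s + chunk_size - 1L, q)
      out[, idx] <- featurize_block(idx, gabor_filter_bank(pyramid, idx))
    }
  }
  structure(out, pyramid = pyramid, class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d stimuli x %d channels\n", nrow(x), ncol(x)))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}
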