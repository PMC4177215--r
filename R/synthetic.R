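#' Generate synthetic grayscale stimulus images
#'
#' Produces deterministic stimulus stacks for simulation studies. Two kinds
#' are available: `"pink_noise"` images with a 1/f amplitude spectrum and
#' random phases (the second-order statistics of natural scenes), and
#' `"gabor_composite"` images built as sums of 3-10 randomly drawn wavelets
#' from a pyramid plus weak white noise (stimuli with known localized
#' structure). Every image is rescaled to `[0, 1]`.
#'
#' @param n Number of images (at least 1).
#' @param size Image side length in pixels.
#' @param kind `"pink_noise"` or `"gabor_composite"`.
#' @param seed Integer seed; the same seed reproduces the stack bit-exactly
#'   and global RNG state is left untouched.
#' @param pyramid Pyramid used to draw component wavelets for
#'   `"gabor_composite"` (default: a reduced pyramid at `size` with
#'   frequencies 1-8).
#' @return A `size x size x n` array with dimnames on the third axis
#'   (`stim_1`, ...).
#' @export
generate_images <- function(n, size = 128,
                            kind = c("pink_noise", "gabor_composite"),
                            seed = 1, pyramid = NULL) {
  kind <- match.arg(kind)
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be at least 1", call. = FALSE)
  n <- as.integer(n)
  rescale01 <- function(m) {
    rng <- range(m)
    if (rng[1] == rng[2]) return(matrix(0.5, nrow(m), ncol(m)))
    (m - rng[1]) / (rng[2] - rng[1])
  }
  out <- array(0, c(size, size, n),
               dimnames = list(NULL, NULL, sprintf("stim_%d", seq_len(n))))
  if (kind == "pink_noise") {
    # radial frequency grid of the DFT (cycles/image), DC set aside
    fr <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
    rad <- sqrt(outer(fr^2, fr^2, "+"))
    amp <- 1 / rad
    amp[1, 1] <- 0
    with_seed(seed, {
      for (i in seq_len(n)) {
        w <- matrix(stats::rnorm(size * size), size, size)
        img <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (size^2)
        out[, , i] <- rescale01(img)
      }
    })
  } else {
    pyramid <- pyramid %||% gabor_pyramid(
      image_size = size, frequencies = c(1, 2, 4, 8)[c(1, 2, 4, 8) <= size / 2])
    bandpass <- which(!pyramid$channels$is_luminance)
    with_seed(seed, {
      for (i in seq_len(n)) {
        k <- sample(3:10, 1)
        chans <- sample(bandpass, k, replace = TRUE)
        wts <- stats::rnorm(k)
        img <- matrix(0, size, size)
        for (j in seq_len(k)) {
          w <- render_wavelet(pyramid, chans[j])
          img <- img + wts[j] * w$even
        }
        img <- img + matrix(stats::rnorm(size * size, sd = 0.05 * max(abs(img), 1e-12)),
                            size, size)
        out[, , i] <- rescale01(img)
      }
    })
  }
  out
}

#' Simulate stimulus-driven voxel responses for a target region
#'
#' Instantiates the linear encoding model forward: each simulated voxel's
#' response is `y_v = X h_v + c_v + latent component + noise`, where `h_v` is
#' a sparse, spatially localized kernel over Gabor channels (nonzero weights
#' confined to one spatial neighborhood, 1-2 orientations, and 2 adjacent
#' frequency bands). The stimulus-driven signal (feature part plus an
#' optional latent part shared with downstream regions, see
#' [generate_loc()]) is scaled to unit standard deviation on the training
#' stimuli, and i.i.d. normal noise is added at `sd = 1/snr`. Test responses
#' emulate repeat-averaged measurements: the same noiseless signal plus the
#' average of `test_repeats` independent noise draws.
#'
#' Voxels are labelled `"V1"`, `"V2"`, or `"V3"` by their kernel's dominant
#' frequency band (high, mid, low frequency tercile of the pyramid), mimicking
#' the coarse-to-fine gradient across early retinotopic areas.
#'
#' @param features_train,features_test [gabor_features()] matrices for the
#'   training and test stimuli (same pyramid).
#' @param n_voxels Number of simulated voxels.
#' @param kernel_sparsity Fraction of channels with nonzero kernel weight
#'   (in `(0, 1]`); the nonzero set is the localized neighborhood above.
#' @param snr Per-voxel signal-to-noise ratio (signal s.d. / noise s.d.);
#'   `Inf` gives noiseless responses.
#' @param test_repeats Number of averaged repeats for test responses
#'   (effective test noise s.d. is `1/(snr * sqrt(test_repeats))`).
#' @param latent_frac Fraction of signal variance carried by a latent
#'   stimulus-driven component that is not a linear function of the features
#'   (shared, non-feature signal such as object-level structure; it is part
#'   of the signal [generate_loc()] mixes into a downstream region). Zero
#'   disables it; 1 removes the feature-driven part entirely, producing
#'   feature-independent voxels for negative controls.
#' @param roi_snr_gradient Frequency-band SNR gradient `g >= 0`: voxels in
#'   the high-frequency band ("V1") get `snr * (1 + g)`, the mid band keeps
#'   `snr`, and the low band ("V3") gets `snr / (1 + g)`. This emulates the
#'   empirical coarse-to-fine gradient in which early areas are most tightly
#'   driven by low-level image features; 0 (the default) gives every voxel
#'   the same SNR.
#' @param seed Integer seed.
#' @return A list of class `synthetic_erc`: `train` and `test` response
#'   matrices (stimuli x voxels), and `ground_truth` (class
#'   `synthetic_ground_truth`) holding effective kernels/constants on the
#'   feature scale, the noiseless signal matrices, ROI labels, latent
#'   loadings, and all generator parameters.
#' @export
generate_erc <- function(features_train, features_test, n_voxels = 60,
                         kernel_sparsity = 0.01, snr = 2, test_repeats = 13,
                         latent_frac = 0.3, roi_snr_gradient = 0, seed = 1) {
  if (roi_snr_gradient < 0)
    stop("roi_snr_gradient must be non-negative", call. = FALSE)
  if (!(kernel_sparsity > 0 && kernel_sparsity <= 1))
    stop("kernel_sparsity must lie in (0, 1]", call. = FALSE)
  if (!(snr > 0)) stop("snr must be positive", call. = FALSE)
  if (test_repeats < 1) stop("test_repeats must be >= 1", call. = FALSE)
  if (latent_frac < 0 || latent_frac > 1)
    stop("latent_frac must lie in [0, 1]", call. = FALSE)
  if (ncol(features_train) != ncol(features_test))
    stop("train and test features must share channels", call. = FALSE)
  pyr <- attr(features_train, "pyramid")
  if (is.null(pyr))
    stop("features must come from gabor_features() (pyramid attribute missing)",
         call. = FALSE)
  ch <- pyr$channels
  q <- ncol(features_train)
  p <- nrow(features_train)
  P <- nrow(features_test)
  freqs <- pyr$frequencies
  n_nonzero <- max(3L, round(kernel_sparsity * q))

  # frequency terciles: high -> V1, mid -> V2, low -> V3
  tercile <- cut(rank(freqs), breaks = 3, labels = FALSE)
  roi_of_freq <- c("V3", "V2", "V1")[tercile]
  names(roi_of_freq) <- as.character(freqs)

  gt <- with_seed(seed, {
    kernels <- matrix(0, q, n_voxels)
    base_freq <- character(n_voxels)
    for (v in seq_len(n_voxels)) {
      fi <- sample(seq_along(freqs), 1)
      f_pair <- unique(c(fi, if (fi < length(freqs)) fi + 1L else fi - 1L))
      f_pair <- f_pair[f_pair >= 1]
      oris <- sample(pyr$orientations, sample(1:2, 1))
      ctr <- stats::runif(2)  # (x, y) in [0,1] image fractions
      cand <- which(!ch$is_luminance &
                      ch$frequency %in% freqs[f_pair] &
                      ch$orientation %in% oris)
      # distance of each candidate's grid-cell center from the drawn center
      cx <- (ch$grid_col[cand] + 0.5) / ch$frequency[cand]
      cy <- (ch$grid_row[cand] + 0.5) / ch$frequency[cand]
      d <- sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2)
      sel <- cand[order(d)][seq_len(min(n_nonzero, length(cand)))]
      kernels[sel, v] <- stats::rnorm(length(sel))
      base_freq[v] <- as.character(freqs[fi])
    }
    constants <- stats::rnorm(n_voxels)
    n_latent <- if (latent_frac > 0) 3L else 0L
    latent_train <- if (n_latent) matrix(stats::rnorm(p * n_latent), p) else NULL
    latent_test <- if (n_latent) matrix(stats::rnorm(P * n_latent), P) else NULL
    loadings <- if (n_latent) matrix(stats::rnorm(n_latent * n_voxels), n_latent)
                else NULL
    list(kernels = kernels, constants = constants, base_freq = base_freq,
         latent_train = latent_train, latent_test = latent_test,
         loadings = loadings)
  })

  feat_tr <- unclass(features_train)
  feat_te <- unclass(features_test)
  sig_feat_tr <- feat_tr %*% gt$kernels
  sig_feat_te <- feat_te %*% gt$kernels
  # per-voxel scaling so the training signal has unit sd, split between the
  # feature-driven and latent parts by latent_frac
  sd_feat <- apply(sig_feat_tr, 2, stats::sd)
  sd_feat[sd_feat == 0] <- 1
  a <- sqrt(1 - latent_frac) / sd_feat
  scale_cols <- function(m, s) sweep(m, 2, s, "*")
  signal_tr <- scale_cols(sig_feat_tr, a)
  signal_te <- scale_cols(sig_feat_te, a)
  eff_kernels <- scale_cols(gt$kernels, a)
  if (!is.null(gt$loadings)) {
    lat_tr <- gt$latent_train %*% gt$loadings
    lat_te <- gt$latent_test %*% gt$loadings
    sd_lat <- apply(lat_tr, 2, stats::sd)
    sd_lat[sd_lat == 0] <- 1
    b <- sqrt(latent_frac) / sd_lat
    signal_tr <- signal_tr + scale_cols(lat_tr, b)
    signal_te <- signal_te + scale_cols(lat_te, b)
    loadings <- scale_cols(gt$loadings, b)
  } else loadings <- NULL
  signal_tr <- sweep(signal_tr, 2, gt$constants, "+")
  signal_te <- sweep(signal_te, 2, gt$constants, "+")

  roi <- roi_of_freq[gt$base_freq]
  snr_mult <- c(V1 = 1 + roi_snr_gradient, V2 = 1,
                V3 = 1 / (1 + roi_snr_gradient))[roi]
  snr_v <- snr * snr_mult
  noise_sd <- ifelse(is.infinite(snr_v), 0, 1 / snr_v)  # per-voxel vector
  vox_ids <- sprintf("erc_%d", seq_len(n_voxels))
  resp <- with_seed(derive_seed(seed, 1L), {
    draw <- function(nr) matrix(stats::rnorm(nr * n_voxels), nr) *
      rep(noise_sd, each = nr)
    tr <- signal_tr + draw(p)
    te_noise <- matrix(0, P, n_voxels)
    for (r in seq_len(test_repeats)) te_noise <- te_noise + draw(P)
    te <- signal_te + te_noise / test_repeats
    list(tr = tr, te = te)
  })
  dimnames(resp$tr) <- list(rownames(feat_tr), vox_ids)
  dimnames(resp$te) <- list(rownames(feat_te), vox_ids)
  dimnames(signal_tr) <- dimnames(resp$tr)
  dimnames(signal_te) <- dimnames(resp$te)

  names(roi) <- vox_ids
  rownames(eff_kernels) <- colnames(feat_tr)
  colnames(eff_kernels) <- vox_ids

  ground_truth <- structure(list(
    kernels = eff_kernels, constants = stats::setNames(gt$constants, vox_ids),
    latent_loadings = loadings, signal_train = signal_tr,
    signal_test = signal_te, roi = roi,
    params = list(n_voxels = n_voxels, kernel_sparsity = kernel_sparsity,
                  snr = snr, test_repeats = test_repeats,
                  latent_frac = latent_frac,
                  roi_snr_gradient = roi_snr_gradient, seed = seed)),
    class = "synthetic_ground_truth")
  structure(list(train = resp$tr, test = resp$te,
                 ground_truth = ground_truth),
            class = "synthetic_erc")
}

#' @export
print.synthetic_erc <- function(x, ...) {
  p <- x$ground_truth$params
  cat(sprintf(
    "Synthetic target-region responses: %d train / %d test stimuli x %d voxels\n",
    nrow(x$train), nrow(x$test), ncol(x$train)))
  cat(sprintf("  snr %.3g, %d test repeats, latent fraction %.2g, seed %d\n",
              p$snr, p$test_repeats, p$latent_frac, p$seed))
  cat("  ROI sizes:", paste(sprintf("%s=%d", names(table(x$ground_truth$roi)),
                                    table(x$ground_truth$roi)), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a source region as a noisy linear mixture of target signals
#'
#' Generates voxel responses for a source region (e.g. LOC) whose activity is
#' a sparse random linear mixture of the target region's *noise-free*
#' stimulus-driven signals, plus independent measurement noise. A linear
#' mapping from this region back to the target region therefore exists but is
#' noisy — the premise of an analogical (region-to-region) encoding model —
#' and shared stimulus-driven variance, not shared measurement noise, is what
#' links the two regions.
#'
#' @param erc A [generate_erc()] result.
#' @param n_voxels Number of source-region voxels.
#' @param mixing_density Fraction of target voxels mixed into each source
#'   voxel (in `(0, 1]`).
#' @param snr Per-voxel signal-to-noise ratio of the source region.
#' @param test_repeats Averaged repeats for test responses.
#' @param freq_bias Sampling bias over target voxels by their kernel's
#'   dominant frequency: each target voxel is drawn with probability
#'   proportional to `frequency^(-freq_bias)`. Positive values bias the
#'   mixture toward low-frequency (V3-like) target voxels; 0 is unbiased.
#' @param seed Integer seed.
#' @return A list of class `synthetic_loc` with `train` and `test` response
#'   matrices (stimuli x voxels) and the `mixing` matrix
#'   (target voxels x source voxels) applied to the noise-free signals.
#' @export
generate_loc <- function(erc, n_voxels = 80, mixing_density = 0.2, snr = 2,
                         test_repeats = 13, freq_bias = 0, seed = 1) {
  stopifnot(inherits(erc, "synthetic_erc"))
  if (!(mixing_density > 0 && mixing_density <= 1))
    stop("mixing_density must lie in (0, 1]", call. = FALSE)
  if (!(snr > 0)) stop("snr must be positive", call. = FALSE)
  gt <- erc$ground_truth
  sig_tr <- sweep(gt$signal_train, 2, gt$constants, "-")
  sig_te <- sweep(gt$signal_test, 2, gt$constants, "-")
  V <- ncol(sig_tr)
  k <- max(1L, round(mixing_density * V))
  # dominant frequency per target voxel (|weight|-weighted mean channel
  # frequency), for biased sampling
  chan_freq <- suppressWarnings(
    as.numeric(sub("^f([0-9.]+)_.*$", "\\1", rownames(gt$kernels))))
  dom_freq <- apply(abs(gt$kernels), 2, function(w) {
    w[is.na(chan_freq)] <- 0
    if (sum(w) == 0) return(1)
    sum(chan_freq * w, na.rm = TRUE) / sum(w)
  })
  prob <- dom_freq^(-freq_bias)
  prob <- prob / sum(prob)

  mixing <- with_seed(seed, {
    m <- matrix(0, V, n_voxels)
    for (v in seq_len(n_voxels)) {
      src <- sample.int(V, k, prob = prob)
      m[src, v] <- stats::rnorm(k)
    }
    m
  })
  loc_sig_tr <- sig_tr %*% mixing
  loc_sig_te <- sig_te %*% mixing
  sds <- apply(loc_sig_tr, 2, stats::sd)
  sds[sds == 0] <- 1
  loc_sig_tr <- sweep(loc_sig_tr, 2, sds, "/")
  loc_sig_te <- sweep(loc_sig_te, 2, sds, "/")
  mixing <- sweep(mixing, 2, sds, "/")

  noise_sd <- if (is.infinite(snr)) 0 else 1 / snr
  p <- nrow(loc_sig_tr); P <- nrow(loc_sig_te)
  resp <- with_seed(derive_seed(seed, 2L), {
    tr <- loc_sig_tr + matrix(stats::rnorm(p * n_voxels, sd = noise_sd), p)
    te_noise <- matrix(0, P, n_voxels)
    for (r in seq_len(test_repeats))
      te_noise <- te_noise + matrix(stats::rnorm(P * n_voxels, sd = noise_sd), P)
    te <- loc_sig_te + te_noise / test_repeats
    list(tr = tr, te = te)
  })
  vox_ids <- sprintf("loc_%d", seq_len(n_voxels))
  dimnames(resp$tr) <- list(rownames(sig_tr), vox_ids)
  dimnames(resp$te) <- list(rownames(sig_te), vox_ids)
  dimnames(mixing) <- list(colnames(sig_tr), vox_ids)
  structure(list(train = resp$tr, test = resp$te, mixing = mixing,
                 params = list(n_voxels = n_voxels,
                               mixing_density = mixing_density, snr = snr,
                               test_repeats = test_repeats,
                               freq_bias = freq_bias, seed = seed)),
            class = "synthetic_loc")
}

#' Generate a complete synthetic encoding study
#'
#' Convenience wrapper that draws stimuli, featurizes them, and simulates
#' coupled target-region ("ERC") and source-region ("LOC") responses. The
#' defaults define the package's desk-scale reference simulation: 800
#' training and 60 test stimuli at 128 x 128 pixels, a reduced pyramid with
#' frequencies 1-8 (681 channels), 60 target voxels at SNR 2 with 13-repeat
#' test averaging, 30% latent (non-feature) signal shared with an 80-voxel
#' source region. These stand in for the full-scale study design (1750/120
#' stimuli, 10921 channels) at a size a desktop fits.
#'
#' @param p_train,p_test Training / test stimulus counts.
#' @param image_size Stimulus side length in pixels.
#' @param frequencies Pyramid frequencies (cycles/FOV).
#' @param n_erc,n_loc Voxel counts for the two regions.
#' @param snr Signal-to-noise ratio of the target region.
#' @param snr_loc Signal-to-noise ratio of the source region (defaults to
#'   `snr`).
#' @param latent_frac Latent (non-feature) fraction of target signal
#'   variance.
#' @param roi_snr_gradient Frequency-band SNR gradient of the target region
#'   (see [generate_erc()]).
#' @param test_repeats Averaged repeats for test responses.
#' @param mixing_density Density of the target-to-source mixture.
#' @param freq_bias Low-frequency bias of the mixture (see [generate_loc()]).
#' @param kind Stimulus kind (see [generate_images()]).
#' @param seed Integer seed driving every stage.
#' @param bank Optional precomputed [gabor_filter_bank()] for the pyramid
#'   (reused across calls to avoid re-rendering).
#' @return A list of class `synthetic_study` with the pyramid, feature
#'   matrices (`features_train`, `features_test`), the [generate_erc()] and
#'   [generate_loc()] results (`erc`, `loc`), and the generator parameters.
#' @export
synthetic_study <- function(p_train = 800, p_test = 60, image_size = 128,
                            frequencies = c(1, 2, 4, 8), n_erc = 60,
                            n_loc = 80, snr = 2, snr_loc = snr,
                            latent_frac = 0.3, roi_snr_gradient = 0,
                            test_repeats = 13, mixing_density = 0.2,
                            freq_bias = 0, kind = "pink_noise", seed = 1,
                            bank = NULL) {
  pyr <- gabor_pyramid(image_size = image_size, frequencies = frequencies)
  imgs_tr <- generate_images(p_train, image_size, kind,
                             seed = derive_seed(seed, 10L))
  imgs_te <- generate_images(p_test, image_size, kind,
                             seed = derive_seed(seed, 11L))
  dimnames(imgs_te)[[3]] <- sprintf("test_%d", seq_len(p_test))
  feats_tr <- gabor_features(imgs_tr, pyr, bank = bank)
  feats_te <- gabor_features(imgs_te, pyr, bank = bank)
  erc <- generate_erc(feats_tr, feats_te, n_voxels = n_erc, snr = snr,
                      test_repeats = test_repeats, latent_frac = latent_frac,
                      roi_snr_gradient = roi_snr_gradient,
                      seed = derive_seed(seed, 12L))
  loc <- generate_loc(erc, n_voxels = n_loc, mixing_density = mixing_density,
                      snr = snr_loc, test_repeats = test_repeats,
                      freq_bias = freq_bias, seed = derive_seed(seed, 13L))
  structure(list(pyramid = pyr, features_train = feats_tr,
                 features_test = feats_te, erc = erc, loc = loc,
                 params = list(p_train = p_train, p_test = p_test,
                               image_size = image_size,
                               frequencies = frequencies, n_erc = n_erc,
                               n_loc = n_loc, snr = snr, snr_loc = snr_loc,
                               latent_frac = latent_frac,
                               roi_snr_gradient = roi_snr_gradient,
                               test_repeats = test_repeats,
                               mixing_density = mixing_density,
                               freq_bias = freq_bias, kind = kind,
                               seed = seed)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  p <- x$params
  cat("Synthetic encoding study\n")
  cat(sprintf("  stimuli: %d train / %d test (%s, %dx%d px)\n", p$p_train,
              p$p_test, p$kind, p$image_size, p$image_size))
  cat(sprintf("  features: %d channels (frequencies %s)\n",
              ncol(x$features_train), paste(p$frequencies, collapse = ",")))
  cat(sprintf("  regions: %d target voxels, %d source voxels, snr %.3g, seed %d\n",
              p$n_erc, p$n_loc, p$snr, p$seed))
  invisible(x)
}
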