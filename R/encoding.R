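#' Training control for encoding-model estimation
#'
#' Collects the tuning parameters of the per-voxel estimator: full-batch
#' gradient descent on squared error, halted by early stopping against a
#' held-out stopping set, repeated over bootstrap resamples of the estimation
#' rows and averaged. Early-stopped descent from a zero kernel shrinks
#' coefficient magnitudes, which is the regularization that makes the
#' estimator usable when channels outnumber stimuli.
#'
#' @param learning_rate Gradient step size on standardized channels. The loss
#'   is the sum (not mean) of squared errors, so stability requires
#'   `learning_rate < 2 / lambda_max(X'X)`; the default suits problems up to a
#'   few thousand stimuli. Halve it if the stopping-set error diverges
#'   immediately.
#' @param max_iters Hard iteration cap per bootstrap round.
#' @param stopping_fraction Fraction of training rows held out as the
#'   stopping set (drawn once per voxel; excluded from all gradients).
#' @param patience Consecutive non-improving stopping-set evaluations before
#'   descent halts.
#' @param eval_every Iterations between stopping-set evaluations.
#' @param n_bootstrap Bootstrap rounds; kernels and intercepts are averaged
#'   across rounds.
#' @param seed Integer seed. Every stochastic choice (stopping-set draw,
#'   bootstrap resampling) derives deterministically from `seed` and the
#'   voxel index, so refitting reproduces results bit-exactly.
#' @param standardize_channels Z-score each channel (using all training rows)
#'   before descent? Strongly recommended: it makes one learning rate
#'   workable across heterogeneous channels.
#' @return A list of class `train_control`.
#' @export
train_control <- function(learning_rate = 1e-4, max_iters = 5000,
                          stopping_fraction = 0.2, patience = 20,
                          eval_every = 10, n_bootstrap = 10, seed = 1,
                          standardize_channels = TRUE) {
  stopifnot(learning_rate > 0, max_iters >= 1,
            stopping_fraction > 0, stopping_fraction < 1,
            patience >= 1, eval_every >= 1, n_bootstrap >= 1,
            is.finite(seed))
  structure(list(learning_rate = learning_rate,
                 max_iters = as.integer(max_iters),
                 stopping_fraction = stopping_fraction,
                 patience = as.integer(patience),
                 eval_every = as.integer(eval_every),
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed),
                 standardize_channels = isTRUE(standardize_channels)),
            class = "train_control")
}

# Per-channel standardization statistics from all training rows. Channels
# with zero spread get scale 1 (their standardized values are constant zero
# after centering, so they receive no kernel weight).
standardization_stats <- function(X) {
  ctr <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  sc[!is.finite(sc) | sc == 0] <- 1
  list(center = ctr, scale = sc)
}

apply_standardization <- function(X, stats_) {
  sweep(sweep(X, 2, stats_$center, "-"), 2, stats_$scale, "/")
}

# Core single-voxel fit on an already-standardized design. Draws the
# stopping set and bootstrap indices from a voxel-specific sub-seed.
fit_voxel_core <- function(Xs, y, control, voxel_index = 1L) {
  p <- nrow(Xs)
  if (stats::sd(y) == 0) {
    return(list(kernel = rep(0, ncol(Xs)), constant = mean(y),
                iterations = 0L, stop_mse = 0, degenerate = TRUE))
  }
  vs <- derive_seed(control$seed, voxel_index)
  n_stop <- max(1L, round(control$stopping_fraction * p))
  if (n_stop >= p) stop("stopping set would consume all rows", call. = FALSE)
  draws <- with_seed(vs, {
    stop_idx <- sort(sample.int(p, n_stop))
    est_idx <- setdiff(seq_len(p), stop_idx)
    boot <- matrix(sample.int(length(est_idx),
                              length(est_idx) * control$n_bootstrap,
                              replace = TRUE),
                   ncol = control$n_bootstrap)
    list(stop_idx = stop_idx, est_idx = est_idx, boot = boot)
  })
  fit <- .gd_fit_voxel(Xs[draws$est_idx, , drop = FALSE], y[draws$est_idx],
                       Xs[draws$stop_idx, , drop = FALSE], y[draws$stop_idx],
                       draws$boot, control$learning_rate, control$max_iters,
                       control$eval_every, control$patience)
  list(kernel = as.vector(fit$kernel), constant = fit$constant,
       iterations = as.integer(round(mean(fit$iters))),
       stop_mse = mean(fit$stop_mse), degenerate = FALSE)
}

#' Fit a single voxel's linear encoding model
#'
#' Estimates one kernel/intercept pair for the linear model
#' `y = X h + c + noise` by bootstrap-averaged gradient descent with early
#' stopping (see [train_control()] for the protocol). This is the unit the
#' region-level fitter [fit_encoding()] repeats across voxels; use it
#' directly for single-voxel experiments.
#'
#' @param X Numeric design matrix, stimuli x channels (Gabor features for a
#'   stimulus encoding model, or another region's voxel patterns for an
#'   analogical one).
#' @param y Numeric response vector, one value per stimulus.
#' @param control A [train_control()].
#' @param voxel_index Index used to derive this voxel's sub-seed.
#' @return A list with `kernel` (standardized-channel scale), `constant`,
#'   `iterations`, `stop_mse`, `degenerate` (TRUE when `y` had zero
#'   variance, in which case the kernel is zero and the constant `mean(y)`),
#'   and the standardization `center`/`scale` used.
#' @export
fit_voxel <- function(X, y, control = train_control(), voxel_index = 1L) {
  check_finite_matrix(X, "X")
  if (!is.numeric(y) || length(y) != nrow(X))
    stop("y must be numeric with one value per row of X", call. = FALSE)
  if (!all(is.finite(y))) stop("y contains non-finite values", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 stimuli", call. = FALSE)
  st <- if (control$standardize_channels) standardization_stats(X)
        else list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- apply_standardization(X, st)
  out <- fit_voxel_core(Xs, y, control, voxel_index)
  if (out$degenerate)
    warning("response has zero variance; returning a degenerate fit",
            call. = FALSE)
  c(out, st)
}

#' Fit a multi-voxel linear encoding model
#'
#' Fits the linear model `y_v = X h_v + c_v + noise` independently for every
#' voxel (column) of the response matrix, using gradient descent with early
#' stopping averaged over bootstrap resamples. The design matrix may hold any
#' input channels: Gabor image features give a stimulus encoding model;
#' another region's voxel activity patterns give an analogical
#' (region-to-region) encoding model. No code path distinguishes the two.
#'
#' @param X Design matrix, stimuli x channels (a [gabor_features()] matrix, a
#'   response matrix, or any numeric matrix). Row names are stimulus ids,
#'   column names channel ids.
#' @param Y Response matrix, stimuli x voxels, with matching rows. If both
#'   `X` and `Y` carry row names they must agree (same stimuli, same order).
#' @param control A [train_control()].
#' @param verbose Report progress every 25 voxels?
#' @return An object of class `encoding_model`: kernels (channels x voxels,
#'   standardized scale), constants, the channel standardization statistics,
#'   per-voxel training diagnostics, and the control used. Methods:
#'   [predict.encoding_model()], [coef.encoding_model()], `print`, `summary`,
#'   `plot`, [residuals.encoding_model()].
#' @examples
#' X <- matrix(rnorm(200 * 12), 200, 12)
#' Y <- X %*% matrix(rnorm(12 * 3), 12, 3) + rnorm(600, sd = 0.5)
#' m <- fit_encoding(X, Y, train_control(n_bootstrap = 2, seed = 7))
#' stats::cor(predict(m, X)[, 1], Y[, 1])
#' @export
fit_encoding <- function(X, Y, control = train_control(), verbose = FALSE) {
  check_finite_matrix(X, "X")
  check_finite_matrix(Y, "Y")
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of stimulus rows", call. = FALSE)
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("stimulus ids of X and Y do not align", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 stimuli", call. = FALSE)

  st <- if (control$standardize_channels) standardization_stats(X)
        else list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- apply_standardization(X, st)
  V <- ncol(Y)
  kernels <- matrix(0, ncol(X), V)
  constants <- numeric(V)
  diag_df <- data.frame(voxel = colnames(Y) %||% sprintf("v%d", seq_len(V)),
                        iterations = integer(V), stop_mse = numeric(V),
                        degenerate = logical(V), stringsAsFactors = FALSE)
  for (v in seq_len(V)) {
    fv <- fit_voxel_core(Xs, Y[, v], control, voxel_index = v)
    kernels[, v] <- fv$kernel
    constants[v] <- fv$constant
    diag_df$iterations[v] <- fv$iterations
    diag_df$stop_mse[v] <- fv$stop_mse
    diag_df$degenerate[v] <- fv$degenerate
    if (verbose && v %% 25L == 0L)
      message(sprintf("fit_encoding: %d/%d voxels", v, V))
  }
  if (any(diag_df$degenerate))
    warning(sprintf("%d voxel(s) had zero response variance (degenerate fit)",
                    sum(diag_df$degenerate)), call. = FALSE)
  rownames(kernels) <- colnames(X)
  colnames(kernels) <- diag_df$voxel
  names(constants) <- diag_df$voxel
  structure(list(kernels = kernels, constants = constants,
                 center = st$center, scale = st$scale,
                 standardize = control$standardize_channels,
                 control = control, diagnostics = diag_df,
                 channel_ids = colnames(X), voxel_ids = diag_df$voxel,
                 n_train = nrow(X), call = match.call()),
            class = "encoding_model")
}

#' Predict activity patterns from an encoding model
#'
#' Applies the fitted per-voxel kernels to new design rows, reproducing the
#' training-time channel standardization. Row `i`, voxel `v` of the result is
#' `standardized(newdata[i, ]) . kernel_v + constant_v`.
#'
#' @param object An `encoding_model`.
#' @param newdata Design matrix with the same channels (columns) as training;
#'   if both carry column names they must match in order.
#' @param ... Unused.
#' @return Predicted response matrix, stimuli x voxels.
#' @export
predict.encoding_model <- function(object, newdata, ...) {
  check_finite_matrix(newdata, "newdata")
  if (ncol(newdata) != nrow(object$kernels))
    stop(sprintf("newdata has %d channels but the model was trained on %d",
                 ncol(newdata), nrow(object$kernels)), call. = FALSE)
  if (!is.null(colnames(newdata)) && !is.null(object$channel_ids) &&
      !identical(colnames(newdata), object$channel_ids))
    stop("channel ids of newdata do not match the training design",
         call. = FALSE)
  Xs <- apply_standardization(newdata,
                              list(center = object$center, scale = object$scale))
  pred <- Xs %*% object$kernels
  pred <- sweep(pred, 2, object$constants, "+")
  rownames(pred) <- rownames(newdata)
  pred
}

#' Extract encoding-model coefficients
#'
#' @param object An `encoding_model`.
#' @param scale `"raw"` returns kernels on the original channel scale with a
#'   matching intercept row (so `X %*% h + c` reproduces predictions without
#'   standardization); `"standardized"` returns them as stored.
#' @param ... Unused.
#' @return A `(channels + 1) x voxels` matrix whose first row,
#'   `"(Intercept)"`, holds the constants.
#' @export
coef.encoding_model <- function(object, scale = c("raw", "standardized"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") {
    return(rbind("(Intercept)" = object$constants, object$kernels))
  }
  raw <- object$kernels / object$scale
  icpt <- object$constants - as.vector(crossprod(raw, object$center))
  rbind("(Intercept)" = icpt, raw)
}

#' Residuals of an encoding model on given data
#'
#' The model does not store its training data (designs can be large), so
#' residuals are computed against supplied design/response pairs.
#'
#' @param object An `encoding_model`.
#' @param X Design matrix.
#' @param Y Observed response matrix aligned with `X`.
#' @param ... Unused.
#' @return Matrix `Y - predict(object, X)`.
#' @export
residuals.encoding_model <- function(object, X, Y, ...) {
  check_finite_matrix(Y, "Y")
  pred <- predict(object, X)
  if (!all(dim(pred) == dim(Y)))
    stop("Y does not match the predicted dimensions", call. = FALSE)
  Y - pred
}

#' @export
print.encoding_model <- function(x, ...) {
  cat("Linear voxel encoding model\n")
  cat(sprintf("  %d input channels -> %d voxels (fit on %d stimuli)\n",
              nrow(x$kernels), ncol(x$kernels), x$n_train))
  cat(sprintf("  estimator: gradient descent, early stopping (%d%% stopping set), %d bootstrap round(s)\n",
              round(100 * x$control$stopping_fraction), x$control$n_bootstrap))
  cat(sprintf("  median iterations/round: %d; median stopping-set MSE: %.4g\n",
              stats::median(x$diagnostics$iterations),
              stats::median(x$diagnostics$stop_mse)))
  if (any(x$diagnostics$degenerate))
    cat(sprintf("  degenerate voxels: %d\n", sum(x$diagnostics$degenerate)))
  invisible(x)
}

#' @export
summary.encoding_model <- function(object, ...) {
  kn <- sqrt(colSums(object$kernels^2))
  s <- list(n_channels = nrow(object$kernels),
            n_voxels = ncol(object$kernels),
            n_train = object$n_train,
            control = object$control,
            diagnostics = cbind(object$diagnostics, kernel_norm = kn))
  class(s) <- "summary.encoding_model"
  s
}

#' @export
print.summary.encoding_model <- function(x, ...) {
  cat(sprintf("Linear voxel encoding model: %d channels -> %d voxels (%d training stimuli)\n",
              x$n_channels, x$n_voxels, x$n_train))
  cat("Per-voxel training diagnostics:\n")
  print(summary(x$diagnostics[, c("iterations", "stop_mse", "kernel_norm")]))
  invisible(x)
}

#' Plot encoding-model training diagnostics
#'
#' Shows per-voxel stopping-set error against iterations used, a quick view
#' of which voxels converged and how strongly they are regularized.
#'
#' @param x An `encoding_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.encoding_model <- function(x, ...) {
  d <- x$diagnostics
  graphics::plot(d$iterations, d$stop_mse, xlab = "iterations per round",
                 ylab = "stopping-set MSE",
                 main = "Encoding model: per-voxel early stopping", ...)
  invisible(x)
}
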