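#' Correlation matrix between predicted and observed activity patterns
#'
#' For each pair (predicted image `n`, observed image `m`) computes the
#' Pearson correlation across voxels between the two activity patterns.
#' Element `(n, m)` of the result is the correlation between the predicted
#' pattern of image `n` and the observed pattern of image `m`; correct
#' identifications therefore live on the diagonal.
#'
#' @param predicted,observed Matrices, stimuli x voxels, with equal stimulus
#'   counts (at least 2) and matching voxels (column names, if present on
#'   both, must agree).
#' @return A `P x P` correlation matrix. Pairs involving a zero-variance
#'   (degenerate) pattern are set to 0 with a warning rather than NA, so a
#'   flat pattern never aborts a pipeline.
#' @export
pattern_correlation <- function(predicted, observed) {
  check_finite_matrix(predicted, "predicted")
  check_finite_matrix(observed, "observed")
  if (nrow(predicted) != nrow(observed))
    stop("predicted and observed must have equal stimulus counts", call. = FALSE)
  if (ncol(predicted) != ncol(observed))
    stop("predicted and observed must cover the same voxels", call. = FALSE)
  if (!is.null(colnames(predicted)) && !is.null(colnames(observed)) &&
      !identical(colnames(predicted), colnames(observed)))
    stop("voxel ids of predicted and observed do not match", call. = FALSE)
  if (nrow(predicted) < 2L) stop("need at least 2 stimuli", call. = FALSE)
  if (ncol(predicted) < 2L)
    stop("Pearson pattern correlation needs at least 2 voxels", call. = FALSE)
  deg_p <- apply(predicted, 1, stats::sd) == 0
  deg_o <- apply(observed, 1, stats::sd) == 0
  cm <- suppressWarnings(stats::cor(t(predicted), t(observed)))
  if (any(deg_p) || any(deg_o)) {
    warning(sprintf(
      "%d predicted and %d observed pattern(s) have zero variance; their correlations are set to 0",
      sum(deg_p), sum(deg_o)), call. = FALSE)
    cm[deg_p, ] <- 0
    cm[, deg_o] <- 0
  }
  cm
}

#' Identification from a prediction-observation correlation matrix
#'
#' Scores a correlation matrix by the column-maximum rule: observed image `m`
#' is correctly identified when the diagonal element `corr[m, m]` is the
#' strict maximum of column `m` (its own prediction beats every competitor;
#' ties count as incorrect). Accuracy is the fraction of correct columns.
#'
#' @param corr A square, finite correlation matrix as produced by
#'   [pattern_correlation()] (rows = predicted, columns = observed).
#' @return An object of class `identification_result`: `corr_matrix`,
#'   per-image `correct` flags, `n_correct`, `P`, and `accuracy`.
#' @examples
#' id <- identify_patterns(diag(10) * 0.5 + 0.1)
#' id$accuracy
#' @export
identify_patterns <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("corr must be a square matrix", call. = FALSE)
  if (!all(is.finite(corr)))
    stop("corr contains non-finite values", call. = FALSE)
  P <- ncol(corr)
  correct <- vapply(seq_len(P), function(m) {
    corr[m, m] > max(corr[-m, m])
  }, logical(1))
  structure(list(corr_matrix = corr, correct = correct,
                 n_correct = sum(correct), P = P,
                 accuracy = sum(correct) / P),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("Identification: %d/%d correct (%.1f%%); chance %.1f%% (1/%d)\n",
              x$n_correct, x$P, 100 * x$accuracy, 100 / x$P, x$P))
  invisible(x)
}

#' Plot an identification correlation matrix
#'
#' Displays the predicted-by-observed correlation matrix as an image with the
#' observed axis horizontal, mirroring the usual presentation where a visible
#' diagonal means successful identification.
#'
#' @param x An `identification_result`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.identification_result <- function(x, ...) {
  P <- x$P
  graphics::image(seq_len(P), seq_len(P), t(x$corr_matrix)[, P:1],
                  xlab = "observed image", ylab = "predicted image",
                  main = sprintf("Identification: %d/%d (%.1f%%)",
                                 x$n_correct, x$P, 100 * x$accuracy),
                  axes = FALSE, ...)
  graphics::axis(1); graphics::axis(2, at = seq_len(P), labels = rev(seq_len(P)))
  graphics::box()
  invisible(x)
}

#' Identification accuracy within sub-regions of interest
#'
#' Restricts predicted and observed patterns to each ROI's voxels and runs
#' the correlation-matrix identification there, e.g. to compare how well a
#' model predicts V1, V2, and V3 separately.
#'
#' @param predicted,observed Matrices, stimuli x voxels, as in
#'   [pattern_correlation()].
#' @param roi_labels Either a named list mapping ROI name to voxel ids
#'   (column names) or column indices, or a character vector of one ROI label
#'   per voxel.
#' @return Named list of [identify_patterns()] results, one per ROI. ROIs
#'   with no matching voxels are skipped with a warning; single-voxel ROIs
#'   are degenerate (Pearson needs two voxels) and yield a result with
#'   `accuracy = NA`.
#' @export
identify_by_roi <- function(predicted, observed, roi_labels) {
  if (!is.list(roi_labels)) {
    if (length(roi_labels) != ncol(predicted))
      stop("per-voxel roi_labels must have one label per voxel", call. = FALSE)
    roi_labels <- split(seq_len(ncol(predicted)), roi_labels)
  }
  out <- list()
  for (roi in names(roi_labels)) {
    vox <- roi_labels[[roi]]
    if (is.character(vox)) {
      if (is.null(colnames(predicted)))
        stop("roi voxel ids given but predictions carry no voxel names",
             call. = FALSE)
      vox <- match(vox, colnames(predicted))
      vox <- vox[!is.na(vox)]
    }
    if (length(vox) == 0L) {
      warning(sprintf("ROI '%s' matches no voxels; skipped", roi),
              call. = FALSE)
      next
    }
    if (length(vox) < 2L) {
      warning(sprintf(
        "ROI '%s' has a single voxel; pattern correlation undefined", roi),
        call. = FALSE)
      out[[roi]] <- structure(list(corr_matrix = NULL, correct = NULL,
                                   n_correct = NA_integer_,
                                   P = nrow(predicted), accuracy = NA_real_),
                              class = "identification_result")
      next
    }
    cm <- pattern_correlation(predicted[, vox, drop = FALSE],
                              observed[, vox, drop = FALSE])
    out[[roi]] <- identify_patterns(cm)
  }
  out
}
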