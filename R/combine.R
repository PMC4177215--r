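#' Combine predicted activity patterns from two encoding models
#'
#' Fuses two sets of predicted activity patterns for the same voxels and
#' stimuli, e.g. a stimulus encoding model's predictions with those of an
#' analogical region-to-region model. The default is the plain elementwise
#' average of the two predictions per voxel; `weight_a` generalizes this to a
#' convex combination, and `standardize = TRUE` z-scores each voxel's
#' predictions within each model first (useful when the two models predict on
#' different scales; off by default to keep the plain average).
#'
#' @param pred_a,pred_b Predicted response matrices, stimuli x voxels, with
#'   identical dimensions (and identical dimnames where present).
#' @param weight_a Weight on `pred_a`, in `[0, 1]`; `pred_b` gets
#'   `1 - weight_a`.
#' @param standardize Z-score each voxel's predictions per model before
#'   combining?
#' @return The combined response matrix.
#' @export
combine_predictions <- function(pred_a, pred_b, weight_a = 0.5,
                                standardize = FALSE) {
  check_finite_matrix(pred_a, "pred_a")
  check_finite_matrix(pred_b, "pred_b")
  if (!all(dim(pred_a) == dim(pred_b)))
    stop("pred_a and pred_b must have identical dimensions", call. = FALSE)
  for (d in 1:2) {
    na <- dimnames(pred_a)[[d]]; nb <- dimnames(pred_b)[[d]]
    if (!is.null(na) && !is.null(nb) && !identical(na, nb))
      stop("pred_a and pred_b ids do not align", call. = FALSE)
  }
  if (length(weight_a) != 1L || !is.finite(weight_a) ||
      weight_a < 0 || weight_a > 1)
    stop("weight_a must lie in [0, 1]", call. = FALSE)
  if (standardize) {
    zscore <- function(m) {
      sc <- apply(m, 2, stats::sd)
      sc[sc == 0] <- 1
      sweep(sweep(m, 2, colMeans(m), "-"), 2, sc, "/")
    }
    pred_a <- zscore(pred_a)
    pred_b <- zscore(pred_b)
  }
  weight_a * pred_a + (1 - weight_a) * pred_b
}
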