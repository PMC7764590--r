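#' Pixel-accuracy report against a reference mask
#'
#' Compares a predicted class map with a reference label mask.  Reference
#' pixels coded 0 (unlabeled) are excluded; accuracy is the fraction of
#' evaluated pixels whose predicted class matches the reference
#' (the recognition rate).
#'
#' @param pred A `SegmentationMap` or an integer class matrix (codes 1-3).
#' @param ref Integer reference mask (codes 0-3).
#' @return An `EvalReport`: list with `pixel_accuracy`, `confusion` (3 x 3
#'   counts, rows = reference, cols = prediction), `per_class_recall`,
#'   `n_evaluated` and `n_ignored`.
#' @export
pixel_accuracy <- function(pred, ref) {
  p <- if (is.list(pred)) pred$classes else pred
  if (!all(dim(p) == dim(ref))) stop("shape mismatch between prediction and reference")
  keep <- ref != 0L
  n_ignored <- sum(!keep)
  if (!any(keep)) stop("no evaluable pixels (reference all unlabeled)")
  r <- factor(ref[keep], levels = 1:3)
  q <- factor(p[keep], levels = 1:3)
  confusion <- table(reference = r, prediction = q)
  n <- sum(confusion)
  acc <- sum(diag(confusion)) / n
  recall <- diag(confusion) / rowSums(confusion)
  structure(list(pixel_accuracy = acc,
                 confusion = unclass(confusion),
                 per_class_recall = recall,
                 n_evaluated = n, n_ignored = n_ignored),
            class = "EvalReport")
}

#' Compare stage-1 and stage-2 segmentations against ground truth
#'
#' @param hctfs_map Stage-1 `SegmentationMap` (or class matrix).
#' @param cnn_map Stage-2 `SegmentationMap` (or class matrix).
#' @param gt Reference label mask (codes 0-3).
#' @return List with `hctfs` and `cnn` [pixel_accuracy()] reports and
#'   `accuracy_difference` (cnn minus hctfs).
#' @export
compare_methods <- function(hctfs_map, cnn_map, gt) {
  a <- pixel_accuracy(hctfs_map, gt)
  b <- pixel_accuracy(cnn_map, gt)
  list(hctfs = a, cnn = b,
       accuracy_difference = b$pixel_accuracy - a$pixel_accuracy)
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("pixel accuracy: %.4f (%d pixels evaluated, %d ignored)\n",
              x$pixel_accuracy, x$n_evaluated, x$n_ignored))
  cat("confusion (rows = reference, cols = prediction):\n")
  print(x$confusion)
  invisible(x)
}
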