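#' Confusion matrix for label masks
#'
#' Tallies a `(k+1) x (k+1)` matrix of pixel counts where entry `(i, j)` is the
#' number of pixels whose true class is `i` and predicted class is `j`
#' (0-based class indices; `k` object classes plus one background class).
#'
#' @param pred integer mask (matrix or vector) of predicted class indices in
#'   `0:k`.
#' @param truth integer mask of the same shape with true class indices.
#' @param k number of object classes (default 2, i.e. 3 classes in total).
#' @return An object of class `field_confusion`: an integer matrix with
#'   dimnames giving the class indices, truth in rows, prediction in columns.
#' @examples
#' cm <- confusion_matrix(c(0, 1, 2, 2), c(0, 1, 2, 1))
#' pixel_accuracy(cm)
#' @export
confusion_matrix <- function(pred, truth, k = 2L) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have the same number of pixels")
  }
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (anyNA(pred) || anyNA(truth)) stop("masks must not contain NA")
  if (any(pred < 0L | pred > k) || any(truth < 0L | truth > k)) {
    stop("label out of range [0, ", k, "]")
  }
  cls <- 0:k
  counts <- table(factor(truth, levels = cls), factor(pred, levels = cls))
  m <- matrix(as.integer(counts), k + 1L, k + 1L,
              dimnames = list(truth = cls, pred = cls))
  structure(m, class = c("field_confusion", "matrix"))
}

as_confusion <- function(m) {
  m <- unclass(as.matrix(m))
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("confusion matrix entries must be non-negative")
  m
}

#' Pixel accuracy
#'
#' Global pixel accuracy is the fraction of correctly classified pixels,
#' `sum(p_ii) / sum(p_ij)`; per-class pixel accuracy is the diagonal entry
#' divided by the row (truth) total. Classes with an empty truth row have
#' undefined per-class accuracy and are reported as `NA`.
#'
#' @param m a confusion matrix from [confusion_matrix()].
#' @return list with `global` (scalar) and `per_class` (numeric vector, `NA`
#'   for classes absent from the truth).
#' @export
pixel_accuracy <- function(m) {
  m <- as_confusion(m)
  total <- sum(m)
  if (total <= 0) stop("confusion matrix is empty")
  row_tot <- rowSums(m)
  per <- ifelse(row_tot > 0, diag(m) / row_tot, NA_real_)
  list(global = sum(diag(m)) / total, per_class = as.numeric(per))
}

#' Mean pixel accuracy (mPA)
#'
#' Unweighted mean of the per-class pixel accuracies over the classes that
#' actually occur in the truth.
#'
#' @inheritParams pixel_accuracy
#' @return scalar mPA.
#' @export
mean_pixel_accuracy <- function(m) {
  pa <- pixel_accuracy(m)$per_class
  if (all(is.na(pa))) stop("no class has truth pixels")
  mean(pa, na.rm = TRUE)
}

#' Intersection over union (IoU) and mIoU
#'
#' Per-class IoU is `p_ii / (row_i + col_i - p_ii)`, the ratio of the
#' intersection to the union of the predicted and true masks of that class.
#' Classes whose union is empty (never true and never predicted) are excluded
#' from the mean and reported as `NA`.
#'
#' @inheritParams pixel_accuracy
#' @return list with `per_class` (numeric vector) and `mean` (mIoU).
#' @export
iou <- function(m) {
  m <- as_confusion(m)
  inter <- diag(m)
  union <- rowSums(m) + colSums(m) - inter
  per <- ifelse(union > 0, inter / union, NA_real_)
  if (all(is.na(per))) stop("every class has an empty union")
  list(per_class = as.numeric(per), mean = mean(per, na.rm = TRUE))
}

#' @export
print.field_confusion <- function(x, ...) {
  cat("Confusion matrix (truth rows, prediction columns), ",
      sum(x), " pixels\n", sep = "")
  print(unclass(x))
  pa <- pixel_accuracy(x)
  io <- iou(x)
  cat(sprintf("PA %.4f  mPA %.4f  mIoU %.4f\n",
              pa$global, mean_pixel_accuracy(x), io$mean))
  invisible(x)
}
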