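# Segmentation evaluation: pixel accuracy, Dice, IoU, average Hausdorff
# distance, and rank-based ROC-AUC.

#' Pixel confusion counts between two binary masks
#'
#' @param pred,gt Binary 0/1 matrices of identical dimensions.
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
#' @examples
#' gt <- matrix(0, 3, 3); gt[1, 1:2] <- 1; gt[2, 1] <- 1
#' pr <- matrix(0, 3, 3); pr[1, 1:2] <- 1; pr[3, 2:3] <- 1; pr[2, 2] <- 1
#' confusion_counts(pr, gt)
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) {
    stop("pairing error: mask dimensions differ", call. = FALSE)
  }
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1))) {
    stop("masks must be binary (0/1)", call. = FALSE)
  }
  p <- pred == 1; g <- gt == 1
  structure(list(tp = sum(p & g), tn = sum(!p & !g),
                 fp = sum(p & !g), fn = sum(!p & g)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP", x$tp, "TN", x$tn, "FP", x$fp, "FN", x$fn, "\n")
  invisible(x)
}

#' Pixel accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts A [confusion_counts()].
#' @return Value in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  if (tot == 0) stop("accuracy undefined for zero pixels", call. = FALSE)
  (counts$tp + counts$tn) / tot
}

#' Dice score coefficient
#'
#' `2 TP / (FP + 2 TP + FN)`. When both masks are empty
#' (`TP = FP = FN = 0`) the score is 1 by convention.
#'
#' @param counts A [confusion_counts()].
#' @return Value in `[0, 1]`.
#' @export
dice <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$fp + 2 * counts$tp + counts$fn
  if (den == 0) return(1)
  2 * counts$tp / den
}

#' Intersection over union
#'
#' `TP / (FP + TP + FN)`; both-empty convention as in [dice()].
#'
#' @param counts A [confusion_counts()].
#' @return Value in `[0, 1]`.
#' @export
iou <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$fp + counts$tp + counts$fn
  if (den == 0) return(1)
  counts$tp / den
}

empty_mask_error <- function(which) {
  stop(errorCondition(
    paste0("average Hausdorff distance undefined: ", which, " mask has no foreground"),
    class = c("rda_empty_mask_error", "error", "condition")))
}

mask_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  (m == 1 & !inner) + 0
}

#' Average Hausdorff distance between two binary masks
#'
#' The mean of the two directed average nearest-neighbour distances between
#' the foreground point sets, in pixels:
#' `(mean_g d(g, P) + mean_p d(p, G)) / 2` with Euclidean distance between
#' pixel centers. Computed with an exact Euclidean distance transform.
#' Either mask empty raises a condition of class `rda_empty_mask_error`.
#'
#' @param pred,gt Binary 0/1 matrices of identical dimensions.
#' @param boundary If `TRUE`, reduce each mask to its 4-connected boundary
#'   pixels before measuring. Default `FALSE` (full point sets).
#' @return Non-negative distance in pixels.
#' @export
#' @examples
#' a <- matrix(0, 8, 8); a[1, 1] <- 1
#' b <- matrix(0, 8, 8); b[4, 5] <- 1  # offset (3, 4) -> distance 5
#' avg_hausdorff(a, b)
avg_hausdorff <- function(pred, gt, boundary = FALSE) {
  if (!identical(dim(pred), dim(gt))) {
    stop("pairing error: mask dimensions differ", call. = FALSE)
  }
  if (boundary) {
    pred <- mask_boundary(pred)
    gt <- mask_boundary(gt)
  }
  if (sum(pred) == 0) empty_mask_error("prediction")
  if (sum(gt) == 0) empty_mask_error("ground-truth")
  d_to_pred <- sqrt(.edt_sq_cpp(pred))
  d_to_gt <- sqrt(.edt_sq_cpp(gt))
  (mean(d_to_pred[gt == 1]) + mean(d_to_gt[pred == 1])) / 2
}

#' ROC area under the curve for a pixel probability map
#'
#' Mann-Whitney rank formulation: the probability that a uniformly random
#' foreground pixel scores higher than a uniformly random background pixel,
#' ties counted one half.
#'
#' @param prob Numeric matrix (or vector) of scores.
#' @param gt Binary 0/1 matrix (or vector) of the same length.
#' @return Value in `[0, 1]`; errors if `gt` contains a single class.
#' @export
roc_auc <- function(prob, gt) {
  p <- as.numeric(prob); g <- as.numeric(gt)
  stopifnot(length(p) == length(g), all(g %in% c(0, 1)))
  n1 <- sum(g == 1); n0 <- sum(g == 0)
  if (n1 == 0 || n0 == 0) {
    stop(errorCondition("AUC undefined: ground truth has a single class",
                        class = c("rda_single_class_error", "error", "condition")))
  }
  r <- rank(p)
  (sum(r[g == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate predicted masks against ground truth
#'
#' One tibble row per pair with the four segmentation metrics (plus AUC when
#' probability maps are supplied). Undefined average distances (empty masks)
#' are recorded as `NA`.
#'
#' @param pred List of binary prediction masks.
#' @param gt List of binary ground-truth masks.
#' @param prob Optional list of probability maps matching `pred`.
#' @param ids Optional identifiers; defaults to `1..n`.
#' @return A tibble with columns `slice_id`, `acc`, `dsc`, `iou`, `avgdist`
#'   (and `auc`).
#' @export
evaluate_masks <- function(pred, gt, prob = NULL, ids = NULL) {
  stopifnot(length(pred) == length(gt))
  if (is.null(ids)) ids <- as.character(seq_along(pred))
  rows <- purrr::pmap(list(pred, gt, ids, seq_along(pred)), function(p, g, id, i) {
    cc <- confusion_counts(p, g)
    ad <- tryCatch(avg_hausdorff(p, g), rda_empty_mask_error = function(e) NA_real_)
    row <- tibble::tibble(slice_id = id, acc = accuracy(cc), dsc = dice(cc),
                          iou = iou(cc), avgdist = ad)
    if (!is.null(prob)) {
      row$auc <- tryCatch(roc_auc(prob[[i]], g),
                          rda_single_class_error = function(e) NA_real_)
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Summarise a metrics table
#'
#' Mean of each metric across slices (the layout used for cohort-level
#' reporting).
#'
#' @param metrics A tibble from [evaluate_masks()].
#' @return One-row tibble of means (NA distances dropped).
#' @export
summarise_metrics <- function(metrics) {
  dplyr::summarise(metrics,
                   dplyr::across(dplyr::where(is.numeric),
                                 ~ mean(.x, na.rm = TRUE)))
}
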