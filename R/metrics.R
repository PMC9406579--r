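# Segmentation evaluation: confusion counts, pixel accuracy, Dice,
# intersection-over-union, average Hausdorff distance and ROC AUC.

#' Pixelwise confusion counts
#'
#' @param pred,gt Binary masks (values in `{0, 1}`) on the same grid.
#' @return List of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`;
#'   the four counts sum to the number of pixels.
#' @export
confusion_counts <- function(pred, gt) {
  check_same_grid(pred, gt, c("pred", "gt"))
  check_mask(pred, "pred"); check_mask(gt, "gt")
  tp <- sum(pred == 1 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

as_counts <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(c)))
  c
}

#' Pixel accuracy: (TP + TN) / (TP + TN + FP + FN)
#'
#' Because the true-negative background dominates most CT slices, accuracy is
#' systematically more flattering than Dice or IoU on the same counts.
#'
#' @param c Confusion counts from [confusion_counts()].
#' @export
accuracy <- function(c) {
  c <- as_counts(c)
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) stop("accuracy undefined for zero evaluated pixels", call. = FALSE)
  (c$tp + c$tn) / total
}

#' Dice similarity coefficient: 2TP / (2TP + FP + FN)
#'
#' Overlap similarity in `[0, 1]`; 1 is a perfect segmentation, 0 a disjoint
#' one. When both masks are empty the coefficient is defined as 1 (perfect
#' agreement) with a warning.
#'
#' @inheritParams accuracy
#' @export
dice <- function(c) {
  c <- as_counts(c)
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) {
    warning("both masks empty; Dice defined as 1", call. = FALSE)
    return(1)
  }
  2 * c$tp / denom
}

#' Intersection over union (Jaccard): TP / (TP + FP + FN)
#'
#' Related to Dice by `IoU = DSC / (2 - DSC)`. Both-empty masks give 1 with
#' a warning.
#'
#' @inheritParams accuracy
#' @export
iou <- function(c) {
  c <- as_counts(c)
  denom <- c$tp + c$fp + c$fn
  if (denom == 0) {
    warning("both masks empty; IoU defined as 1", call. = FALSE)
    return(1)
  }
  c$tp / denom
}

# Coordinates (row, col) of the boundary pixels of a binary mask.
boundary_points <- function(mask) {
  which(boundary_mask(mask) == 1, arr.ind = TRUE)
}

#' Average Hausdorff distance between two masks
#'
#' Boundary-sensitive segmentation error: with `G` and `S` the boundary
#' point sets of `gt` and `pred` (mask minus its 4-connectivity erosion),
#' returns `(mean_g min_s d(g, s) + mean_s min_g d(s, g)) / 2` with Euclidean
#' distances — the symmetric mean of the two directed average distances. By
#' construction it is symmetric in its arguments and zero exactly when the
#' boundary sets coincide. Distances are in pixels, or in millimetres when a
#' per-axis `spacing` is supplied.
#'
#' The implementation uses an exact Euclidean distance transform of each
#' boundary set (anisotropic spacings fall back to explicit nearest-neighbour
#' search).
#'
#' @param gt,pred Non-empty binary masks on the same grid.
#' @param spacing Optional length-2 numeric, physical size of a pixel along
#'   (row, column) in mm.
#' @param points `"boundary"` (default) measures between boundary sets;
#'   `"mask"` measures between the full pixel sets.
#' @return Non-negative distance.
#' @export
average_hausdorff <- function(gt, pred, spacing = NULL,
                              points = c("boundary", "mask")) {
  points <- match.arg(points)
  check_same_grid(gt, pred, c("gt", "pred"))
  check_mask(gt, "gt"); check_mask(pred, "pred")
  if (sum(gt) == 0 || sum(pred) == 0) {
    stop("average Hausdorff distance is undefined for an empty mask", call. = FALSE)
  }
  pts <- function(m) {
    if (points == "boundary") boundary_points(m) else which(m == 1, arr.ind = TRUE)
  }
  G <- pts(gt); S <- pts(pred)
  if (is.null(spacing) || isTRUE(all(spacing == spacing[1]))) {
    scale <- if (is.null(spacing)) 1 else spacing[1]
    d_to <- function(P, other_set_mask) {
      # distance transform: 1 everywhere except 0 on the target point set
      target <- matrix(1, nrow(gt), ncol(gt))
      target[other_set_mask] <- 0
      dm <- as.matrix(EBImage::distmap(target, metric = "euclidean"))
      mean(dm[P]) * scale
    }
    maskG <- G; maskS <- S
    g_to_s <- d_to(G, maskS)
    s_to_g <- d_to(S, maskG)
  } else {
    sy <- spacing[1]; sx <- spacing[2]
    directed <- function(A, B) {
      dy <- outer(A[, 1] * sy, B[, 1] * sy, "-")
      dx <- outer(A[, 2] * sx, B[, 2] * sx, "-")
      mean(sqrt(apply(dy^2 + dx^2, 1, min)))
    }
    g_to_s <- directed(G, S)
    s_to_g <- directed(S, G)
  }
  (g_to_s + s_to_g) / 2
}

#' ROC AUC of a probability map against a binary mask
#'
#' Area under the ROC curve over all thresholds, computed through the
#' rank-statistic (Mann-Whitney) formulation: the probability that a random
#' positive pixel scores above a random negative one, ties counted half.
#' Invariant under strictly monotone transforms of `prob`.
#'
#' @param prob Numeric map with values in `[0, 1]`.
#' @param gt Binary mask containing both classes.
#' @export
roc_auc <- function(prob, gt) {
  check_same_grid(prob, gt, c("prob", "gt"))
  check_mask(gt, "gt")
  if (any(prob < 0 | prob > 1)) stop("'prob' must lie in [0, 1]", call. = FALSE)
  np <- sum(gt == 1); nn <- sum(gt == 0)
  if (np == 0 || nn == 0) {
    stop("ROC AUC is undefined when the ground truth has a single class",
         call. = FALSE)
  }
  r <- rank(as.vector(prob))
  (sum(r[gt == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate one case: all metrics from a probability map
#'
#' Binarizes `prob` at `threshold` (`prob >= threshold`) and computes pixel
#' accuracy, Dice, IoU, average Hausdorff distance and ROC AUC against the
#' ground truth. Undefined metrics (AVGDIST with an empty mask, AUC with a
#' single-class ground truth) are reported as `NA` rather than failing the
#' case.
#'
#' @param prob Probability map in `[0, 1]`.
#' @param gt Binary ground-truth mask on the same grid.
#' @param threshold Binarization threshold in `[0, 1]`.
#' @param spacing Optional pixel spacing passed to [average_hausdorff()].
#' @return One-row tibble: `acc`, `dsc`, `iou`, `avgdist`, `auc`.
#' @export
evaluate_case <- function(prob, gt, threshold = 0.5, spacing = NULL) {
  check_same_grid(prob, gt, c("prob", "gt"))
  check_mask(gt, "gt")
  pred <- (prob >= threshold) * 1
  cc <- confusion_counts(pred, gt)
  avg <- if (sum(pred) == 0 || sum(gt) == 0) {
    NA_real_
  } else {
    average_hausdorff(gt, pred, spacing = spacing)
  }
  auc <- if (sum(gt) == 0 || sum(gt) == length(gt)) {
    NA_real_
  } else {
    roc_auc(prob, gt)
  }
  both_empty <- (cc$tp + cc$fp + cc$fn) == 0
  tibble::tibble(acc = accuracy(cc),
                 dsc = if (both_empty) 1 else dice(cc),
                 iou = if (both_empty) 1 else iou(cc),
                 avgdist = avg,
                 auc = auc)
}

#' Aggregate per-case metrics
#'
#' Unweighted mean of the per-case metrics; cases where a metric is undefined
#' (`NA`) are excluded from that metric's mean and counted.
#'
#' @param cases Tibble of per-case metrics ([evaluate_case()] rows).
#' @return One-row tibble of means plus `n_cases`, `n_missing_avgdist`,
#'   `n_missing_auc`.
#' @export
aggregate_metrics <- function(cases) {
  tibble::tibble(
    acc = mean(cases$acc),
    dsc = mean(cases$dsc),
    iou = mean(cases$iou),
    avgdist = mean(cases$avgdist, na.rm = TRUE),
    auc = mean(cases$auc, na.rm = TRUE),
    n_cases = nrow(cases),
    n_missing_avgdist = sum(is.na(cases$avgdist)),
    n_missing_auc = sum(is.na(cases$auc))
  )
}
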