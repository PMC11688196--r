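# Object-level segmentation evaluation: greedy IoU matching, detection
# accuracy TP / (TP + FP + FN), Dice and IoU overlap scores, and segmenter
# comparison by Welch's t-test.

#' Match predicted objects to ground-truth objects
#'
#' Greedy matching on descending pairwise IoU among candidate pairs at or
#' above the threshold; each object participates in at most one pair.
#' Unmatched predictions are false positives, unmatched ground-truth objects
#' false negatives.
#'
#' @param gt,pred Lists of simple polygons (n x 2 matrices), e.g. from
#'   [read_polygons()].
#' @param iou_threshold Minimum IoU for a valid match (default 0.5).
#' @param mode,pixel Overlap computation, see [polygon_iou()].
#' @return An object of class `match_counts`: `tp`, `fp`, `fn` and a
#'   `matched_pairs` tibble (`gt_id`, `pred_id`, `iou`).
#' @export
match_objects <- function(gt, pred, iou_threshold = 0.5,
                          mode = c("area", "raster"), pixel = 0.346) {
  mode <- match.arg(mode)
  gt <- lapply(gt, as_xy_matrix)
  pred <- lapply(pred, as_xy_matrix)
  bb <- function(p) c(range(p[, 1]), range(p[, 2]))
  gb <- lapply(gt, bb); pb <- lapply(pred, bb)
  cand <- list()
  for (i in seq_along(gt)) {
    for (j in seq_along(pred)) {
      # bounding boxes must overlap for IoU > 0
      if (gb[[i]][1] > pb[[j]][2] || pb[[j]][1] > gb[[i]][2] ||
          gb[[i]][3] > pb[[j]][4] || pb[[j]][3] > gb[[i]][4]) next
      iou <- polygon_iou(gt[[i]], pred[[j]], mode = mode, pixel = pixel)
      if (iou >= iou_threshold) {
        cand[[length(cand) + 1]] <- c(i, j, iou)
      }
    }
  }
  pairs <- tibble::tibble(gt_id = integer(), pred_id = integer(), iou = numeric())
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
    used_gt <- logical(length(gt)); used_pred <- logical(length(pred))
    keep <- logical(nrow(cm))
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, 1]; j <- cm[r, 2]
      if (!used_gt[i] && !used_pred[j]) {
        used_gt[i] <- TRUE; used_pred[j] <- TRUE; keep[r] <- TRUE
      }
    }
    cm <- cm[keep, , drop = FALSE]
    pairs <- tibble::tibble(gt_id = as.integer(cm[, 1]),
                            pred_id = as.integer(cm[, 2]), iou = cm[, 3])
  }
  structure(
    list(tp = nrow(pairs), fp = length(pred) - nrow(pairs),
         fn = length(gt) - nrow(pairs), matched_pairs = pairs,
         iou_threshold = iou_threshold),
    class = "match_counts"
  )
}

#' @export
print.match_counts <- function(x, ...) {
  cat("<match_counts> tp =", x$tp, " fp =", x$fp, " fn =", x$fn,
      " (IoU >=", x$iou_threshold, ")\n")
  invisible(x)
}

#' Detection accuracy
#'
#' `TP / (TP + FP + FN)`: the fraction of all involved objects that were
#' correctly detected. Undefined (NA) when there are no objects at all.
#'
#' @param counts A `match_counts` object (or list with `tp`, `fp`, `fn`).
#' @return A number in `[0, 1]`, or `NA` for an empty problem.
#' @export
seg_accuracy <- function(counts) {
  denom <- counts$tp + counts$fp + counts$fn
  if (denom == 0) return(NA_real_)
  counts$tp / denom
}

#' Overlap scores of matched object pairs
#'
#' Per matched pair, IoU and the Dice coefficient `DSC = 2 IoU / (1 + IoU)`;
#' summarised as the mean over matched pairs.
#'
#' @param counts A `match_counts` object.
#' @return A list of class `seg_score`: `per_pair` tibble (with `dsc`
#'   column added), `accuracy`, `mean_iou`, `mean_dsc`.
#' @export
overlap_scores <- function(counts) {
  pairs <- counts$matched_pairs
  pairs$dsc <- 2 * pairs$iou / (1 + pairs$iou)
  structure(
    list(
      per_pair = pairs,
      accuracy = seg_accuracy(counts),
      mean_iou = if (nrow(pairs)) mean(pairs$iou) else NA_real_,
      mean_dsc = if (nrow(pairs)) mean(pairs$dsc) else NA_real_
    ),
    class = "seg_score"
  )
}

#' @export
print.seg_score <- function(x, ...) {
  cat(sprintf("<seg_score> accuracy %.4f | IoU %.4f | DSC %.4f (%d pairs)\n",
              x$accuracy, x$mean_iou, x$mean_dsc, nrow(x$per_pair)))
  invisible(x)
}

#' Evaluate one predicted segmentation against ground truth
#'
#' Convenience wrapper around [match_objects()] and [overlap_scores()].
#'
#' @inheritParams match_objects
#' @return A one-row tibble: `tp`, `fp`, `fn`, `accuracy`, `mean_iou`,
#'   `mean_dsc`.
#' @export
evaluate_segmentation <- function(gt, pred, iou_threshold = 0.5,
                                  mode = c("area", "raster"), pixel = 0.346) {
  counts <- match_objects(gt, pred, iou_threshold, mode = mode, pixel = pixel)
  sc <- overlap_scores(counts)
  tibble::tibble(tp = counts$tp, fp = counts$fp, fn = counts$fn,
                 accuracy = sc$accuracy, mean_iou = sc$mean_iou,
                 mean_dsc = sc$mean_dsc)
}

p_value_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 0.1 ~ "*",
    TRUE ~ "ns"
  )
}

#' Compare two segmenters' per-image scores
#'
#' Unpaired Welch's t-test on the per-image score vectors of two segmenters
#' (e.g. a pretrained model versus a refined one), with the conventional
#' asterisk rendering of the p-value.
#'
#' @param scores_a,scores_b Numeric per-image score vectors.
#' @param alpha Significance threshold.
#' @return A one-row stat-result tibble with a `stars` column.
#' @export
compare_segmenters <- function(scores_a, scores_b, alpha = 0.05) {
  out <- welch_ttest(scores_a, scores_b, alpha = alpha)
  out$stars <- p_value_stars(out$p_value)
  out
}
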