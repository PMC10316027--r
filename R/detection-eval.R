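# Detection-quality evaluation: IoU, precision/recall, COCO-style average
# precision, regression agreement and confusion matrices.

#' Intersection over union of two boxes
#'
#' Boxes are `c(xmin, ymin, xmax, ymax)` in the internal 0-based half-open
#' convention; disjoint boxes score 0.
#'
#' @param a,b numeric length-4 boxes.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    abort("degenerate box", class = "aircanopy_validation_error")
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# vectorized IoU matrix between two box tibbles/data frames
iou_matrix <- function(pa, pb) {
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(matrix(0, nrow(pa), nrow(pb)))
  ix <- pmax(0, outer(pa$xmax, pb$xmax, pmin) - outer(pa$xmin, pb$xmin, pmax))
  iy <- pmax(0, outer(pa$ymax, pb$ymax, pmin) - outer(pa$ymin, pb$ymin, pmax))
  inter <- ix * iy
  area_a <- (pa$xmax - pa$xmin) * (pa$ymax - pa$ymin)
  area_b <- (pb$xmax - pb$xmin) * (pb$ymax - pb$ymin)
  inter / (outer(area_a, area_b, `+`) - inter)
}

#' Greedy score-ordered matching of detections to ground truth
#'
#' Predictions are visited in descending score (ties by index) and matched
#' to the unmatched truth with the highest IoU at or above `iou_thresh`
#' (IoU ties broken by truth index).  Each truth and each prediction is
#' matched at most once.
#'
#' @param preds tibble with box columns and `score`.
#' @param truths tibble with box columns.
#' @param iou_thresh matching threshold in `[0, 1]`.
#' @return list with `tp`, `fp`, `fn` counts and a `matched_pairs` tibble
#'   (`pred_idx`, `truth_idx`, `iou`).
#' @export
match_detections <- function(preds, truths, iou_thresh = 0.5) {
  np <- nrow(preds); nt <- nrow(truths)
  ord <- if (np) order(-preds$score, seq_len(np)) else integer(0)
  iou <- iou_matrix(preds, truths)
  used <- rep(FALSE, nt)
  pairs <- list()
  for (i in ord) {
    if (!nt) break
    cand <- which(!used & iou[i, ] >= iou_thresh)
    if (!length(cand)) next
    best <- cand[which.max(iou[i, cand])]   # which.max: first max = lowest index
    used[best] <- TRUE
    pairs[[length(pairs) + 1L]] <- tibble(pred_idx = i, truth_idx = best,
                                          iou = iou[i, best])
  }
  mp <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble(pred_idx = integer(0), truth_idx = integer(0), iou = numeric(0))
  list(tp = nrow(mp), fp = np - nrow(mp), fn = nt - nrow(mp),
       matched_pairs = mp)
}

#' Precision and recall from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; degenerate denominators give
#' 0 with `degenerate = TRUE`.
#'
#' @param m a match result (list with `tp`, `fp`, `fn`), e.g. from
#'   [match_detections()].
#' @return one-row tibble with `precision`, `recall`, `degenerate`.
#' @export
precision_recall <- function(m) {
  degenerate <- (m$tp + m$fp) == 0L || (m$tp + m$fn) == 0L
  p <- if ((m$tp + m$fp) == 0L) 0 else m$tp / (m$tp + m$fp)
  r <- if ((m$tp + m$fn) == 0L) 0 else m$tp / (m$tp + m$fn)
  tibble(precision = p, recall = r, degenerate = degenerate)
}

#' Average precision of a scored detection set
#'
#' Greedy score-ordered matching at `iou_thresh`, then the area under the
#' all-points-interpolated precision-recall curve (precision at each recall
#' level replaced by the maximum precision at any equal-or-higher recall).
#'
#' @inheritParams match_detections
#' @return list (`ap_result`) with `ap`, `pr_curve` tibble
#'   (`recall`, `precision`), `iou_thresh`, and `undefined` flag when there
#'   are no ground-truth boxes.
#' @export
average_precision <- function(preds, truths, iou_thresh = 0.5) {
  nt <- nrow(truths)
  if (nt == 0L)
    return(structure(list(ap = NA_real_, pr_curve = tibble(recall = numeric(0),
                                                           precision = numeric(0)),
                          iou_thresh = iou_thresh, undefined = TRUE),
                     class = "ap_result"))
  np <- nrow(preds)
  if (np == 0L)
    return(structure(list(ap = 0, pr_curve = tibble(recall = 0, precision = 0),
                          iou_thresh = iou_thresh, undefined = FALSE),
                     class = "ap_result"))
  m <- match_detections(preds, truths, iou_thresh)
  ord <- order(-preds$score, seq_len(np))
  is_tp <- seq_len(np) %in% m$matched_pairs$pred_idx
  tp_cum <- cumsum(is_tp[ord])
  fp_cum <- cumsum(!is_tp[ord])
  recall <- tp_cum / nt
  precision <- tp_cum / (tp_cum + fp_cum)
  # all-points interpolation
  interp <- rev(cummax(rev(precision)))
  rc <- c(0, recall)
  ap <- sum((rc[-1] - rc[-length(rc)]) * interp)
  structure(list(ap = ap,
                 pr_curve = tibble(recall = recall, precision = interp),
                 iou_thresh = iou_thresh, undefined = FALSE),
            class = "ap_result")
}

#' COCO-style AP summaries
#'
#' `ap_at()` evaluates a single IoU threshold (AP50, AP75, ...); `coco_map()`
#' averages AP over IoU 0.50:0.05:0.95.
#'
#' @inheritParams match_detections
#' @param thresholds IoU thresholds to average over.
#' @return scalar AP / mAP.
#' @export
coco_map <- function(preds, truths, thresholds = seq(0.5, 0.95, by = 0.05)) {
  mean(vapply(thresholds,
              function(t) average_precision(preds, truths, t)$ap, numeric(1)))
}

#' @rdname coco_map
#' @param iou_thresh single IoU threshold.
#' @export
ap_at <- function(preds, truths, iou_thresh) {
  average_precision(preds, truths, iou_thresh)$ap
}

#' Agreement between predicted and reference values
#'
#' Coefficient of determination `R2 = 1 - SSres/SStot` and root mean square
#' error.
#'
#' @param pred,truth equal-length numeric vectors, length >= 2; `truth`
#'   must have nonzero variance.
#' @return one-row tibble with `r2`, `rmse`, `n`.
#' @export
r2_rmse <- function(pred, truth) {
  if (length(pred) != length(truth))
    abort("pred and truth lengths differ", class = "aircanopy_validation_error")
  if (length(truth) < 2L || stats::var(truth) == 0)
    abort("truth must have nonzero variance (length >= 2)",
          class = "aircanopy_validation_error")
  ss_res <- sum((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  tibble(r2 = 1 - ss_res / ss_tot,
         rmse = sqrt(mean((pred - truth)^2)),
         n = length(truth))
}

#' Confusion matrix and per-class accuracy
#'
#' Rows are truth, columns are prediction; per-class accuracy is the
#' diagonal over the row sum.
#'
#' @param pred_labels,true_labels vectors of labels drawn from `classes`.
#' @param classes class levels (fixes row/column order).
#' @return list with `matrix` and `per_class_accuracy` tibble.
#' @export
confusion_matrix <- function(pred_labels, true_labels, classes) {
  unknown <- setdiff(unique(c(pred_labels, true_labels)), classes)
  if (length(unknown))
    abort(paste("labels outside the class set:", paste(unknown, collapse = ", ")),
          class = "aircanopy_validation_error")
  m <- table(factor(true_labels, levels = classes),
             factor(pred_labels, levels = classes))
  m <- unclass(m)
  names(dimnames(m)) <- c("truth", "prediction")
  rs <- rowSums(m)
  acc <- ifelse(rs > 0, diag(m) / rs, NA_real_)
  list(matrix = m,
       per_class_accuracy = tibble(class = classes, accuracy = as.numeric(acc)))
}
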