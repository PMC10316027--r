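test_that("box IoU matches hand-computed areas", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 2, 2), c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_error(box_iou(c(0, 0, 0, 2), c(0, 0, 2, 2)),
               class = "aircanopy_validation_error")
})

test_that("precision and recall follow the TP/FP/FN counts", {
  pr <- precision_recall(list(tp = 3, fp = 1, fn = 0))
  expect_equal(pr$precision, 0.75); expect_equal(pr$recall, 1)
  pr2 <- precision_recall(list(tp = 5, fp = 0, fn = 0))
  expect_equal(c(pr2$precision, pr2$recall), c(1, 1))
  pr3 <- precision_recall(list(tp = 0, fp = 0, fn = 4))
  expect_equal(pr3$precision, 0); expect_true(pr3$degenerate)
})

test_that("average precision reproduces hand-computed PR areas", {
  truths <- tibble::tibble(xmin = c(0, 20), ymin = 0, xmax = c(10, 30),
                           ymax = 10)
  # ranks 1 and 3 hit, rank 2 is a false positive
  preds <- tibble::tibble(xmin = c(0, 50, 20), ymin = c(0, 50, 0),
                          xmax = c(10, 60, 30), ymax = c(10, 60, 10),
                          score = c(0.9, 0.8, 0.7))
  ap <- average_precision(preds, truths, 0.5)
  expect_equal(ap$ap, 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)

  perfect <- average_precision(dplyr::mutate(truths, score = c(0.3, 0.9)),
                               truths, 0.5)
  expect_equal(perfect$ap, 1)
  none <- average_precision(preds[0, ], truths, 0.5)
  expect_equal(none$ap, 0)
  undef <- average_precision(preds, truths[0, ], 0.5)
  expect_true(undef$undefined)
})

test_that("AP is invariant to monotone score transforms and ordered in IoU", {
  truths <- random_boxes(6, seed = 31)
  preds <- random_boxes(9, seed = 32)
  withr::with_seed(33, preds$score <- runif(9))
  ap1 <- average_precision(preds, truths, 0.3)$ap
  preds2 <- preds; preds2$score <- plogis(5 * preds$score - 2)
  expect_equal(average_precision(preds2, truths, 0.3)$ap, ap1)
  for (pair in list(c(0.3, 0.5), c(0.5, 0.75))) {
    lo <- average_precision(preds, truths, pair[1])$ap
    hi <- average_precision(preds, truths, pair[2])$ap
    expect_lte(hi, lo)
  }
})

# exhaustive oracles for small instances: the maximum-cardinality match
# count, and the full enumeration of injective assignments selecting the
# lexicographically best per-prediction IoU sequence in score order (the
# definition the greedy matcher implements)
exhaustive_max_tp <- function(preds, truths, thresh) {
  ok <- aircanopy:::iou_matrix(preds, truths) >= thresh
  np <- nrow(preds); nt <- nrow(truths)
  best <- 0L
  rec <- function(p, used, count) {
    best <<- max(best, count)
    if (p > np) return(invisible(NULL))
    rec(p + 1L, used, count)
    for (t in which(!used & ok[p, ])) {
      used[t] <- TRUE
      rec(p + 1L, used, count + 1L)
      used[t] <- FALSE
    }
  }
  rec(1L, rep(FALSE, nt), 0L)
  best
}

exhaustive_lex_match <- function(preds, truths, thresh) {
  iou <- aircanopy:::iou_matrix(preds, truths)
  np <- nrow(preds); nt <- nrow(truths)
  ord <- order(-preds$score, seq_len(np))
  best <- NULL
  rec <- function(r, used, vals, assign) {
    if (r > np) {
      if (is.null(best) || lex_gt(vals, best$vals)) best <<- list(
        vals = vals, assign = assign)
      return(invisible(NULL))
    }
    p <- ord[r]
    rec(r + 1L, used, c(vals, -1), c(assign, NA_integer_))
    for (t in seq_len(nt)) {
      if (!used[t] && iou[p, t] >= thresh) {
        used[t] <- TRUE
        # tie-break on equal IoU by lower truth index: subtract an epsilon
        rec(r + 1L, used, c(vals, iou[p, t] - t * 1e-12),
            c(assign, t))
        used[t] <- FALSE
      }
    }
  }
  lex_gt <- function(a, b) {
    d <- a - b
    nz <- which(abs(d) > 1e-15)
    length(nz) > 0 && d[nz[1]] > 0
  }
  rec(1L, rep(FALSE, nt), numeric(0), integer(0))
  tibble::tibble(pred_idx = ord[!is.na(best$assign)],
                 truth_idx = best$assign[!is.na(best$assign)])
}

test_that("the greedy matcher equals its exhaustive enumeration oracle", {
  for (seed in 1:40) {
    withr::with_seed(seed, {
      np <- sample(1:4, 1); nt <- sample(1:4, 1)
    })
    preds <- random_boxes(np, size = 40, seed = 100 + seed)
    truths <- random_boxes(nt, size = 40, seed = 200 + seed)
    if (np > 0) withr::with_seed(300 + seed, preds$score <- runif(np))
    m <- match_detections(preds, truths, 0.25)
    oracle <- exhaustive_lex_match(preds, truths, 0.25)
    expect_equal(m$tp, nrow(oracle))
    expect_equal(m$matched_pairs[order(m$matched_pairs$pred_idx),
                                 c("pred_idx", "truth_idx")],
                 oracle[order(oracle$pred_idx), ],
                 ignore_attr = TRUE)
    # greedy can never beat the optimal assignment
    expect_lte(m$tp, exhaustive_max_tp(preds, truths, 0.25))
    expect_equal(m$tp + m$fp, np)
    expect_equal(m$tp + m$fn, nt)
  }
})

test_that("R2 and RMSE follow their definitions", {
  expect_equal(r2_rmse(c(1, 2, 3), c(1, 2, 3))$r2, 1)
  expect_equal(r2_rmse(c(1, 2, 3), c(1, 2, 3))$rmse, 0)
  shifted <- r2_rmse(c(2, 3, 4), c(1, 2, 3))
  expect_equal(shifted$rmse, 1)
  res <- r2_rmse(c(1, 2, 4), c(1, 2, 3))
  expect_equal(res$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(res$r2, 0.5, tolerance = 1e-12)
  expect_error(r2_rmse(1:3, 1:4), class = "aircanopy_validation_error")
  expect_error(r2_rmse(1:3, c(2, 2, 2)), class = "aircanopy_validation_error")
})

test_that("confusion matrices count rows as truth and columns as prediction", {
  classes <- c("high", "medium", "low")
  perfect <- confusion_matrix(rep(classes, 4), rep(classes, 4), classes)
  expect_equal(unname(diag(perfect$matrix)), rep(4L, 3))
  expect_equal(perfect$per_class_accuracy$accuracy, rep(1, 3))

  all_high <- confusion_matrix(rep("high", 9), rep(classes, 3), classes)
  expect_equal(all_high$per_class_accuracy$accuracy, c(1, 0, 0))

  truth <- rep(classes, each = 4)
  pred <- truth
  pred[c(1, 5, 9)] <- c("medium", "low", "high")   # one error per class
  cm <- confusion_matrix(pred, truth, classes)
  expect_equal(cm$per_class_accuracy$accuracy, rep(3 / 4, 3))
  expect_error(confusion_matrix(c("high", "unknown"), c("high", "low"), classes),
               class = "aircanopy_validation_error")
})
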