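test_that("protonet emits k non-negative prototypes at P3 resolution", {
  withr::with_seed(1, p3 <- array(rnorm(20 * 20 * 24), c(20, 20, 24)))
  pr <- protonet(p3, k = 8)
  expect_equal(dim(pr$tensor), c(20, 20, 8))
  expect_true(all(pr$tensor >= 0))
  pr2 <- protonet(p3, k = 8, weights = pr$weights)
  expect_identical(pr$tensor, pr2$tensor)
  pru <- protonet(p3, k = 8, upsample = TRUE)
  expect_equal(dim(pru$tensor), c(40, 40, 8))
})

test_that("the prediction head emits 5 anchors per location at every level", {
  withr::with_seed(2, p_levels <- stats::setNames(
    lapply(c(20, 10, 5, 3, 2), function(s) array(rnorm(s * s * 16), c(s, s, 16))),
    paste0("P", 3:7)))
  dets <- prediction_head(p_levels, k = 4, input_size = 160)
  expect_equal(nrow(dets), 5 * (400 + 100 + 25 + 9 + 4))
  expect_true(all(lengths(dets$mask_coeffs) == 4))
  expect_true(all(dets$score > 0 & dets$score < 1))
  an <- aircanopy:::anchor_table(c(P3 = 20, P4 = 10, P5 = 5, P6 = 3, P7 = 2),
                                 160)
  sq <- an[an$level == "P3" & an$anchor == 1, ]
  expect_equal(sq$w, sq$h)                    # aspect-ratio-1 anchor is square
  expect_equal(unique(round(sq$w, 9)), 3 * 160 / 20)
})

test_that("fast NMS suppresses by any higher-scoring box, sequential by kept", {
  dom <- tibble::tibble(xmin = c(0, 1), ymin = 0, xmax = c(10, 11), ymax = 10,
                        score = c(0.9, 0.8))
  expect_equal(nrow(fast_nms(dom, 0.5)), 1L)
  expect_equal(fast_nms(dom, 0.5)$score, 0.9)

  # chain A > B > C with IoU(A,B) = IoU(B,C) = 0.6, IoU(A,C) < 0.5
  chain <- tibble::tibble(
    xmin = c(0, 2.5, 2.5), ymin = c(0, 0, 2.5),
    xmax = c(10, 12.5, 12.5), ymax = c(10, 10, 12.5),
    score = c(0.9, 0.8, 0.7))
  expect_equal(box_iou(as.numeric(chain[1, 1:4]), as.numeric(chain[2, 1:4])),
               0.6, tolerance = 1e-9)
  expect_equal(box_iou(as.numeric(chain[2, 1:4]), as.numeric(chain[3, 1:4])),
               0.6, tolerance = 1e-9)
  expect_lt(box_iou(as.numeric(chain[1, 1:4]), as.numeric(chain[3, 1:4])), 0.5)
  expect_equal(fast_nms(chain, 0.5)$score, 0.9)             # keeps only A
  expect_equal(sequential_nms(chain, 0.5)$score, c(0.9, 0.7)) # keeps A and C

  empty <- chain[0, ]
  expect_equal(nrow(fast_nms(empty, 0.5)), 0L)
})

test_that("fast NMS output is a subset, pairwise-separated and idempotent", {
  dets <- random_boxes(40, size = 60, seed = 41)
  withr::with_seed(42, dets$score <- runif(40))
  kept <- fast_nms(dets, 0.4)
  expect_true(all(kept$score %in% dets$score))
  if (nrow(kept) > 1) {
    iou <- aircanopy:::iou_matrix(kept, kept)
    diag(iou) <- 0
    expect_lte(max(iou), 0.4)
  }
  again <- fast_nms(kept, 0.4)
  expect_equal(again, kept)
})

test_that("mask assembly crops, thresholds and saturates as specified", {
  proto <- array(0, c(10, 10, 2))
  proto[, , 1] <- 8                          # all-large-positive prototype
  det <- list(box = c(8, 8, 32, 32), score = 0.9, mask_coeffs = c(1, 0))
  seg <- assemble_mask(proto, det, c(40, 40))
  expect_s3_class(seg, "plot_segmentation")
  inside <- seg$mask[10:31, 10:31]
  expect_true(all(inside))
  expect_false(any(seg$mask[1:5, ]))          # outside the box

  zero <- list(box = c(8, 8, 32, 32), score = 0.9, mask_coeffs = c(0, 0))
  seg0 <- assemble_mask(proto, zero, c(40, 40))
  expect_false(any(seg0$mask))                # sigmoid 0.5 fails strict >
  expect_error(assemble_mask(proto, list(box = c(0, 0, 5, 5), score = 1,
                                         mask_coeffs = c(1, 0, 0)),
                             c(40, 40)),
               class = "aircanopy_shape_error")
})

test_that("mask assembly is monotone in the coefficient of a positive prototype", {
  withr::with_seed(3, proto <- array(abs(rnorm(100)), c(10, 10, 1)))
  det <- function(cf) list(box = c(0, 0, 40, 40), score = 1, mask_coeffs = cf)
  sizes <- vapply(c(0.5, 1, 2, 4), function(cf)
    sum(assemble_mask(proto, det(cf), c(40, 40))$mask), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("central-plot selection prefers the centroid nearest the centre", {
  mk_seg <- function(x0, x1, y0, y1, score) {
    mask <- matrix(FALSE, 100, 100); mask[y0:y1, x0:x1] <- TRUE
    structure(list(mask = mask, box = c(x0, y0, x1, y1), score = score,
                   found = TRUE), class = "plot_segmentation")
  }
  centred <- mk_seg(35, 65, 35, 65, 0.51)
  corner <- mk_seg(2, 30, 2, 30, 0.99)
  sel <- aircanopy:::select_central_segmentation(list(corner, centred),
                                                 c(100, 100))
  expect_equal(sel$score, 0.51)
  # ties on distance break by score
  twin_lo <- mk_seg(35, 65, 35, 65, 0.4)
  sel2 <- aircanopy:::select_central_segmentation(list(twin_lo, centred),
                                                  c(100, 100))
  expect_equal(sel2$score, 0.51)
})

test_that("training with zero learning rate leaves the loss constant", {
  sc <- fixture_scenes()[[1]]
  m <- train_plot_model(list(sc), hyper = list(iterations = 3, lr = 0,
                                               seed = 42))
  expect_length(m$loss_history, 3L)
  expect_equal(diff(m$loss_history), c(0, 0), tolerance = 1e-12)
  expect_error(train_plot_model(list()), class = "aircanopy_validation_error")
})

test_that("training histories are identical across runs with one seed", {
  sc <- fixture_scenes()[[1]]
  h <- list(iterations = 4, lr = 0.003, seed = 9)
  m1 <- train_plot_model(list(sc), h)
  m2 <- train_plot_model(list(sc), h)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("the desk model overfits small scenes to mask IoU >= 0.7", {
  model <- trained_plot_model()
  expect_lt(tail(model$loss_history, 1), model$loss_history[1])
  ious <- vapply(fixture_scenes(), function(sc) {
    seg <- segment_central_plot(sc$image, model, 0.5)
    if (!isTRUE(seg$found)) return(0)
    mask_iou(seg$mask, scene_truth_mask(sc))
  }, numeric(1))
  expect_true(all(ious >= 0.7))
})

test_that("a pure-soil scene yields an explicit absence signal", {
  model <- trained_plot_model()
  # soil texture drawn with a different seed than the training negative
  seg <- segment_central_plot(fixture_soil_image(60), model, 0.5)
  expect_false(seg$found)
  # while the real scenes still segment confidently
  seg2 <- segment_central_plot(fixture_scenes()[[1]]$image, model, 0.5)
  expect_true(seg2$found)
})

test_that("model checkpoints round-trip through a single serialized file", {
  model <- trained_plot_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  sc <- fixture_scenes()[[1]]
  a <- segment_central_plot(sc$image, model, 0.3)
  b <- segment_central_plot(sc$image, back, 0.3)
  expect_identical(a$mask, b$mask)
  expect_equal(a$score, b$score)
})
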