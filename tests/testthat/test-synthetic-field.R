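test_that("scene generation is deterministic and exact by construction", {
  p <- scene_params(seed = 11, spike_count = 30)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$image, b$image)
  expect_identical(a$spike_boxes, b$spike_boxes)
  expect_equal(a$true_count, 30L)
  expect_equal(nrow(a$spike_boxes), a$true_count)

  empty <- generate_scene(scene_params(seed = 1, spike_count = 0))
  expect_equal(empty$true_count, 0L)
  expect_equal(nrow(empty$spike_boxes), 0L)

  many <- generate_scene(scene_params(seed = 2, spike_count = 120,
                                      image_size = c(256, 256),
                                      plot_rect = c(128, 128, 170, 170, 0)))
  expect_equal(nrow(many$spike_boxes), 120L)
})

test_that("spike boxes lie inside the plot polygon's bounding box", {
  sc <- generate_scene(scene_params(seed = 5, spike_count = 50))
  v <- sc$plot_polygon$vertices[[1]]
  expect_true(all(sc$spike_boxes$xmin >= min(v$x) - 1e-9))
  expect_true(all(sc$spike_boxes$xmax <= max(v$x) + 1e-9))
  expect_true(all(sc$spike_boxes$ymin >= min(v$y) - 1e-9))
  expect_true(all(sc$spike_boxes$ymax <= max(v$y) + 1e-9))
})

test_that("an unplaceable spike count raises a placement error", {
  expect_error(generate_scene(scene_params(seed = 1, spike_count = 5000)),
               class = "aircanopy_placement_error")
})

test_that("re-measuring rendered ellipse centres recovers the ground truth", {
  # sparse placement so ground-truth boxes are pairwise disjoint and each
  # box isolates one rendered ellipse; spikes are the most yellow objects,
  # so the centroid of the yellow-saturated pixels estimates the centre
  for (seed in c(1, 4, 9, 21)) {
    sc <- generate_scene(scene_params(seed = seed, spike_count = 12,
                                      image_size = c(200, 200),
                                      plot_rect = c(100, 100, 150, 150, 0),
                                      spike_axes = c(4, 6, 2, 3),
                                      max_overlap = 0))
    io <- aircanopy:::iou_matrix(sc$spike_boxes, sc$spike_boxes)
    diag(io) <- 0
    expect_equal(max(io), 0)
    yel <- (sc$image[, , 1] + sc$image[, , 2]) / 2 - sc$image[, , 3]
    errs <- vapply(seq_len(nrow(sc$spike_boxes)), function(r) {
      b <- sc$spike_boxes[r, ]
      ys <- (floor(b$ymin) + 1):ceiling(b$ymax)
      xs <- (floor(b$xmin) + 1):ceiling(b$xmax)
      sub <- yel[ys, xs]
      bright <- sub >= 0.75 * max(sub)
      px <- which(bright, arr.ind = TRUE)
      cx <- mean(xs[px[, 2]] - 0.5); cy <- mean(ys[px[, 1]] - 0.5)
      truth <- sc$spikes[r, ]
      sqrt((cx - truth["cx"])^2 + (cy - truth["cy"])^2)
    }, numeric(1))
    expect_lt(max(errs), 1)
  }
})

test_that("identity augmentations change nothing", {
  sc <- generate_scene(scene_params(seed = 3, spike_count = 20))
  rot0 <- augment_scene(sc, "rotation", list(angle = 0))
  expect_identical(rot0$image, sc$image)
  expect_identical(rot0$spike_boxes, sc$spike_boxes)
  sp0 <- augment_scene(sc, "salt_pepper", list(fraction = 0), seed = 4)
  expect_identical(sp0$image, sc$image)
  expect_error(augment_scene(sc, "warp"), class = "aircanopy_argument_error")
})

test_that("luminance scales brightness and salt-and-pepper flips pixels", {
  sc <- generate_scene(scene_params(seed = 3, spike_count = 10))
  bright <- augment_scene(sc, "luminance", list(gain = 1.3))
  expect_gt(mean(bright$image), mean(sc$image))
  noisy <- augment_scene(sc, "salt_pepper", list(fraction = 0.05), seed = 9)
  changed <- mean(noisy$image[, , 1] != sc$image[, , 1])
  expect_gt(changed, 0.02); expect_lt(changed, 0.10)
  expect_identical(noisy$spike_boxes, sc$spike_boxes)
})

test_that("rotation keeps annotations registered with the image", {
  sc <- generate_scene(scene_params(seed = 7, spike_count = 15))
  for (angle in c(10, 30)) {
    rot <- augment_scene(sc, "rotation", list(angle = angle))
    expect_equal(rot$true_count, nrow(rot$spike_boxes))
    # re-detect each rotated spike as bright pixels inside its remapped box;
    # the measured extent must overlap the remapped box strongly
    lum <- 0.299 * rot$image[, , 1] + 0.587 * rot$image[, , 2] +
      0.114 * rot$image[, , 3]
    ious <- vapply(seq_len(nrow(rot$spike_boxes)), function(r) {
      b <- rot$spike_boxes[r, ]
      ys <- max(1, floor(b$ymin - 2)):min(160, ceiling(b$ymax + 2))
      xs <- max(1, floor(b$xmin - 2)):min(160, ceiling(b$xmax + 2))
      sub <- lum[ys, xs]
      bright <- sub >= stats::quantile(sub, 0.7)
      px <- which(bright, arr.ind = TRUE)
      meas <- c(min(xs[px[, 2]]) - 1, min(ys[px[, 1]]) - 1,
                max(xs[px[, 2]]), max(ys[px[, 1]]))
      box_iou(meas, c(b$xmin, b$ymin, b$xmax, b$ymax))
    }, numeric(1))
    expect_gt(stats::median(ious), 0.5)
    expect_gt(mean(ious >= 0.4), 0.8)
  }
})

test_that("mosaic composes four scenes and sums their counts", {
  scenes <- lapply(1:4, function(i)
    generate_scene(scene_params(seed = 30 + i,
                                spike_count = c(10, 20, 30, 40)[i])))
  mos <- augment_scene(scenes, "mosaic")
  expect_equal(mos$true_count, 100L)
  expect_equal(dim(mos$image), dim(scenes[[1]]$image))
  # every remapped box falls inside its quadrant's half-canvas
  expect_true(all(mos$spike_boxes$xmax <= 160 + 1e-9))
  expect_error(augment_scene(scenes[1:3], "mosaic"),
               class = "aircanopy_argument_error")
})

test_that("scene bundles write PNG + COCO + VOC that re-read consistently", {
  sc <- generate_scene(scene_params(seed = 12, spike_count = 8))
  dir <- withr::local_tempdir()
  paths <- write_scene_bundle(sc, dir, "fix")
  img <- png::readPNG(paths["png"])
  expect_equal(dim(img), dim(sc$image))
  polys <- read_coco_polygons(paths["coco"])
  expect_equal(nrow(polys), 1L)
  boxes <- read_voc_boxes(paths["voc"])
  expect_equal(nrow(boxes), 8L)
})
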