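test_that("COCO polygon round-trip is lossless and counts entries", {
  polys <- dplyr::bind_rows(
    polygon_annotation("img1.png", "plot",
                       data.frame(x = c(10, 60, 60, 10), y = c(10, 10, 40, 40))),
    polygon_annotation("img1.png", "plot",
                       data.frame(x = c(70, 95, 80), y = c(5, 20, 45))),
    polygon_annotation("img2.png", "plot",
                       data.frame(x = c(0, 50, 50, 0), y = c(0, 0, 30, 30))))
  path <- withr::local_tempfile(fileext = ".json")
  write_coco_polygons(polys, path,
                      image_sizes = list(`img1.png` = c(50, 100),
                                         `img2.png` = c(40, 60)))
  back <- read_coco_polygons(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$image_id, polys$image_id)
  expect_equal(back$label, polys$label)
  for (i in 1:3)
    expect_equal(as.data.frame(back$vertices[[i]]),
                 as.data.frame(polys$vertices[[i]]), tolerance = 1e-12)
})

test_that("degenerate and self-intersecting polygons are rejected", {
  expect_error(polygon_annotation("a", "plot", data.frame(x = c(0, 1), y = c(0, 1))),
               class = "aircanopy_validation_error")
  # bow-tie
  expect_error(polygon_annotation("a", "plot",
                                  data.frame(x = c(0, 10, 0, 10),
                                             y = c(0, 10, 10, 0))),
               class = "aircanopy_validation_error")
  expect_error(read_coco_polygons(file.path(tempdir(), "nope.json")),
               class = "aircanopy_io_error")
})

test_that("RLE-style segmentations raise an unsupported-format error", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- list(images = list(list(id = 1, file_name = "x.png", height = 10,
                                 width = 10)),
              annotations = list(list(id = 1, image_id = 1, category_id = 1,
                                      segmentation = list(size = c(10, 10),
                                                          counts = "abc"))),
              categories = list(list(id = 1, name = "plot")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_coco_polygons(path), class = "aircanopy_format_error",
               regexp = "annotation 1")
})

test_that("VOC conversion maps 1-based inclusive to 0-based half-open", {
  boxes <- box_annotation("img.png", "spike", 0, 0, 10, 10)
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc_boxes(boxes, path, image_size = c(20, 20))
  back <- read_voc_boxes(path)
  # written as (1,1,10,10) in VOC convention, read back unchanged
  expect_equal(back$xmin, 0); expect_equal(back$ymin, 0)
  expect_equal(back$xmax, 10); expect_equal(back$ymax, 10)

  xml <- xml2::read_xml(path)
  expect_equal(xml2::xml_text(xml2::xml_find_first(xml, "//bndbox/xmin")), "1")
  expect_equal(xml2::xml_text(xml2::xml_find_first(xml, "//bndbox/xmax")), "10")
})

test_that("a VOC fixture with many objects round-trips with full count", {
  n <- 25L
  withr::with_seed(99, {
    x <- runif(n, 0, 80); y <- runif(n, 0, 80)
    boxes <- box_annotation("scene.png", "spike", x, y, x + runif(n, 2, 10),
                            y + runif(n, 2, 10))
  })
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc_boxes(boxes, path, image_size = c(100, 100))
  back <- read_voc_boxes(path)
  expect_equal(nrow(back), n)
  expect_equal(back$xmin, boxes$xmin, tolerance = 1e-9)
  expect_equal(back$ymax, boxes$ymax, tolerance = 1e-9)
})

test_that("degenerate boxes are rejected", {
  expect_error(box_annotation("a", "spike", 5, 0, 5, 10),
               class = "aircanopy_validation_error")
})

test_that("trait CSV writes one row per record and round-trips", {
  recs <- trait_record(sprintf("plot_%d", 1:5), snpm2 = c(400, 420, 390, 500, 455),
                       coverage = runif(5, 0.7, 0.95), exr = rnorm(5, 0.05, 0.01),
                       ndyi = runif(5, 0.4, 0.7), vari = runif(5, 0.2, 0.4),
                       asm = runif(5, 0.1, 0.3),
                       glcm_dissimilarity = runif(5, 1, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  expect_equal(write_trait_csv(recs, path), 5L)
  expect_length(readLines(path), 6L)      # header + 5 data rows
  back <- read_trait_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(recs), tolerance = 1e-9)
  expect_error(write_trait_csv(recs[0, ], path),
               class = "aircanopy_validation_error")
})

test_that("trait record range invariants are enforced", {
  expect_error(trait_record("p", -1, 0.5, 0, 0, 0, 0.5, 1),
               class = "aircanopy_validation_error")
  expect_error(trait_record("p", 10, 1.2, 0, 0, 0, 0.5, 1),
               class = "aircanopy_validation_error")
  expect_error(trait_record("p", 10, 0.5, 0, 0, 0, 0, 1),
               class = "aircanopy_validation_error")
})
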