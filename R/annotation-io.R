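#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# ---- internal geometry / validation helpers --------------------------------

# segments (p1,p2) and (p3,p4) proper intersection test (shared endpoints ok)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  seg <- function(i) list(xy[i, ], xy[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges share a vertex
      a <- seg(i); b <- seg(j)
      if (segments_cross(a[[1]], a[[2]], b[[1]], b[[2]]))
        return(FALSE)
    }
  }
  TRUE
}

validate_polygon <- function(vertices, image_size = NULL, where = "polygon") {
  vertices <- as.matrix(vertices[, c("x", "y")])
  if (nrow(vertices) < 3L)
    abort(sprintf("%s has fewer than 3 vertices", where),
          class = "aircanopy_validation_error")
  if (!polygon_is_simple(vertices))
    abort(sprintf("%s is self-intersecting", where),
          class = "aircanopy_validation_error")
  if (!is.null(image_size)) {
    if (any(vertices[, 1] < 0) || any(vertices[, 2] < 0) ||
        any(vertices[, 1] > image_size[2]) || any(vertices[, 2] > image_size[1]))
      abort(sprintf("%s has vertices outside the image bounds", where),
            class = "aircanopy_validation_error")
  }
  invisible(vertices)
}

validate_boxes <- function(boxes, image_size = NULL, where = "box") {
  bad <- boxes$xmin >= boxes$xmax | boxes$ymin >= boxes$ymax
  if (any(bad))
    abort(sprintf("%s %s degenerate after conversion (xmin >= xmax or ymin >= ymax)",
                  where, paste(which(bad), collapse = ",")),
          class = "aircanopy_validation_error")
  if (!is.null(image_size)) {
    out <- boxes$xmin < 0 | boxes$ymin < 0 |
      boxes$xmax > image_size[2] | boxes$ymax > image_size[1]
    if (any(out))
      abort(sprintf("%s %s outside image bounds", where,
                    paste(which(out), collapse = ",")),
            class = "aircanopy_validation_error")
  }
  invisible(boxes)
}

#' Construct box annotations
#'
#' Boxes are held internally in 0-based, half-open pixel coordinates
#' (`xmin <= x < xmax`); readers and writers convert at the boundary so the
#' rest of the package never sees a dialect-specific convention.
#'
#' @param image_id,label character vectors (recycled).
#' @param xmin,ymin,xmax,ymax numeric box edges, 0-based half-open.
#' @return a tibble with one row per box.
#' @export
box_annotation <- function(image_id, label, xmin, ymin, xmax, ymax) {
  out <- tibble(image_id = as.character(image_id), label = as.character(label),
                xmin = as.double(xmin), ymin = as.double(ymin),
                xmax = as.double(xmax), ymax = as.double(ymax))
  validate_boxes(out)
  out
}

#' Construct polygon annotations
#'
#' @param image_id,label character scalars.
#' @param vertices a data frame (or matrix) of `x`, `y` vertex coordinates in
#'   0-based pixels, at least 3 rows, describing a simple polygon.
#' @return a one-row tibble with a `vertices` list-column.
#' @export
polygon_annotation <- function(image_id, label, vertices) {
  vertices <- as_tibble(as.data.frame(vertices))
  names(vertices)[1:2] <- c("x", "y")
  validate_polygon(vertices)
  tibble(image_id = as.character(image_id), label = as.character(label),
         vertices = list(vertices))
}

# ---- COCO-style polygon JSON -----------------------------------------------

#' Read and write COCO-style polygon annotations
#'
#' `read_coco_polygons()` parses a COCO-dialect JSON file
#' (`images`/`annotations`/`categories` with polygon `segmentation` entries)
#' into a tibble of polygon annotations; coordinates stay 0-based pixels.
#' Run-length-encoded segmentations are not supported and raise an error
#' naming the offending entry.  `write_coco_polygons()` is the inverse and
#' round-trips losslessly.
#'
#' @param path file path.
#' @return a tibble with columns `image_id`, `label` and a `vertices`
#'   list-column; the image table (id, file name, width, height) is attached
#'   as attribute `"images"`.
#' @export
read_coco_polygons <- function(path) {
  if (!file.exists(path))
    abort(sprintf("annotation file not found: %s", path),
          class = "aircanopy_io_error")
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  imgs <- purrr::map_dfr(doc$images, function(im)
    tibble(id = im$id, file_name = im$file_name %||% NA_character_,
           width = im$width, height = im$height))
  cats <- purrr::map_dfr(doc$categories, function(ct)
    tibble(id = ct$id, name = ct$name))
  out <- purrr::imap_dfr(doc$annotations, function(an, i) {
    seg <- an$segmentation
    if (is.null(seg) || !is.null(seg$counts))
      abort(sprintf("annotation %d: RLE segmentations are not supported", i),
            class = "aircanopy_format_error")
    ring <- unlist(seg[[1]])
    if (length(ring) < 6L || length(ring) %% 2L != 0L)
      abort(sprintf("annotation %d: segmentation is not a valid polygon", i),
            class = "aircanopy_validation_error")
    v <- tibble(x = ring[seq(1, length(ring), 2)],
                y = ring[seq(2, length(ring), 2)])
    im <- imgs[imgs$id == an$image_id, ]
    validate_polygon(v, image_size = if (nrow(im)) c(im$height, im$width),
                     where = sprintf("annotation %d", i))
    image_id <- if (nrow(im) && !is.na(im$file_name)) im$file_name else
      as.character(an$image_id)
    tibble(image_id = image_id,
           label = cats$name[match(an$category_id, cats$id)],
           vertices = list(v))
  })
  attr(out, "images") <- imgs
  out
}

#' @rdname read_coco_polygons
#' @param polygons a tibble of polygon annotations (see
#'   [polygon_annotation()]).
#' @param image_sizes named list or data frame mapping `image_id` to
#'   `c(height, width)`; recorded in the JSON `images` block.
#' @export
write_coco_polygons <- function(polygons, path, image_sizes = NULL) {
  stopifnot(nrow(polygons) >= 1L)
  ids <- unique(polygons$image_id)
  size_of <- function(id) {
    if (is.null(image_sizes)) c(0L, 0L) else unlist(image_sizes[[id]])
  }
  images <- purrr::imap(ids, function(id, i) {
    s <- size_of(id)
    list(id = i, file_name = id, height = s[1], width = s[2])
  })
  labels <- unique(polygons$label)
  categories <- purrr::imap(labels, function(lb, i) list(id = i, name = lb))
  annotations <- purrr::imap(seq_len(nrow(polygons)), function(r, i) {
    v <- polygons$vertices[[r]]
    list(id = i,
         image_id = match(polygons$image_id[r], ids),
         category_id = match(polygons$label[r], labels),
         segmentation = list(as.vector(rbind(v$x, v$y))),
         iscrowd = 0L)
  })
  jsonlite::write_json(list(images = images, annotations = annotations,
                            categories = categories),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- PASCAL VOC XML --------------------------------------------------------

#' Read and write VOC-style box annotations
#'
#' `read_voc_boxes()` parses a PASCAL VOC XML file into a box tibble,
#' converting the VOC 1-based inclusive convention to the internal 0-based
#' half-open one (`xmin - 1`, `xmax` unchanged).  `write_voc_boxes()` applies
#' the inverse conversion, so write-then-read is the identity.
#'
#' @param path XML file path.
#' @return tibble of box annotations (see [box_annotation()]).
#' @export
read_voc_boxes <- function(path) {
  if (!file.exists(path))
    abort(sprintf("annotation file not found: %s", path),
          class = "aircanopy_io_error")
  doc <- xml2::read_xml(path)
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  size <- xml2::xml_find_first(doc, "./size")
  image_size <- if (!inherits(size, "xml_missing")) {
    c(as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height"))),
      as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width"))))
  }
  objs <- xml2::xml_find_all(doc, "./object")
  num <- function(o, fld)
    as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0("./bndbox/", fld))))
  out <- purrr::map_dfr(objs, function(o) {
    tibble(image_id = fname,
           label = xml2::xml_text(xml2::xml_find_first(o, "./name")),
           xmin = num(o, "xmin") - 1, ymin = num(o, "ymin") - 1,
           xmax = num(o, "xmax"), ymax = num(o, "ymax"))
  })
  validate_boxes(out, image_size = image_size, where = "object")
  out
}

#' @rdname read_voc_boxes
#' @param boxes a box tibble in internal coordinates.
#' @param image_size `c(height, width)` written into the `<size>` block.
#' @export
write_voc_boxes <- function(boxes, path, image_size = c(0L, 0L)) {
  stopifnot(nrow(boxes) >= 1L)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", boxes$image_id[1])
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "height", as.character(image_size[1]))
  xml2::xml_add_child(sz, "width", as.character(image_size[2]))
  xml2::xml_add_child(sz, "depth", "3")
  for (r in seq_len(nrow(boxes))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", boxes$label[r])
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(boxes$xmin[r] + 1, digits = 15))
    xml2::xml_add_child(bb, "ymin", format(boxes$ymin[r] + 1, digits = 15))
    xml2::xml_add_child(bb, "xmax", format(boxes$xmax[r], digits = 15))
    xml2::xml_add_child(bb, "ymax", format(boxes$ymax[r], digits = 15))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---- trait records and CSV -------------------------------------------------

trait_columns <- c("snpm2", "coverage", "exr", "ndyi", "vari", "asm",
                   "glcm_dissimilarity")

#' Construct per-plot trait records
#'
#' A trait record carries the seven canopy-level traits of one plot: spike
#' number per square metre (SNpM2), vegetation canopy coverage fraction,
#' the ExR, NDYI and VARI spectral indices, and the GLCM angular second
#' moment (ASM) and dissimilarity texture statistics.
#'
#' @param plot_id identifier.
#' @param snpm2 spikes per square metre, `>= 0`.
#' @param coverage vegetation cover fraction in `[0, 1]`.
#' @param exr,ndyi,vari unitless spectral indices.
#' @param asm angular second moment in `(0, 1]`.
#' @param glcm_dissimilarity unitless, `>= 0`.
#' @return a tibble with one row per record, columns in fixed order.
#' @export
trait_record <- function(plot_id, snpm2, coverage, exr, ndyi, vari, asm,
                         glcm_dissimilarity) {
  out <- tibble(plot_id = as.character(plot_id), snpm2 = as.double(snpm2),
                coverage = as.double(coverage), exr = as.double(exr),
                ndyi = as.double(ndyi), vari = as.double(vari),
                asm = as.double(asm),
                glcm_dissimilarity = as.double(glcm_dissimilarity))
  ok <- stats::complete.cases(out[, trait_columns])
  chk <- out[ok, ]
  if (any(chk$snpm2 < 0) || any(chk$coverage < 0 | chk$coverage > 1) ||
      any(chk$asm <= 0 | chk$asm > 1) || any(chk$glcm_dissimilarity < 0))
    abort("trait record violates its range invariants",
          class = "aircanopy_validation_error")
  out
}

#' Read and write the plot trait table
#'
#' Fixed column order (`plot_id` then the seven traits), comma delimiter,
#' `.` decimal separator, UTF-8 — so a written table re-reads bit-stably.
#'
#' @param records trait tibble as built by [trait_record()]; non-empty.
#' @param path CSV path.
#' @return `write_trait_csv()` returns the number of data rows written;
#'   `read_trait_csv()` returns the trait tibble.
#' @export
write_trait_csv <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L)
    abort("no trait records to write", class = "aircanopy_validation_error")
  cols <- c("plot_id", trait_columns)
  missing <- setdiff(cols, names(records))
  if (length(missing))
    abort(paste("trait records are missing columns:",
                paste(missing, collapse = ", ")),
          class = "aircanopy_validation_error")
  readr::write_csv(records[, cols], path, progress = FALSE)
  nrow(records)
}

#' @rdname write_trait_csv
#' @export
read_trait_csv <- function(path) {
  if (!file.exists(path))
    abort(sprintf("trait table not found: %s", path),
          class = "aircanopy_io_error")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(plot_id = readr::col_character(),
                                          .default = readr::col_double()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
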