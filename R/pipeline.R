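# End-to-end orchestration: plot segmentation -> spike detection -> trait
# extraction -> CSV export, for single images and lexicographic batches.

#' Pipeline configuration
#'
#' @param plot_model a trained `plot_model` or a checkpoint path.
#' @param spike_model a trained `spike_model` or a checkpoint path.
#' @param score_thresh plot-detection score threshold.
#' @param conf_thresh spike objectness threshold.
#' @param nms_iou spike NMS IoU threshold.
#' @param plot_area_m2 plot ground area (default 2.25 = 1.5 m x 1.5 m).
#' @param mask_dilate_px binary dilation (px) applied to the plot mask
#'   before it masks the spike-detector input, so spikes straddling the
#'   mask boundary are not clipped; traits still use the undilated mask.
#' @param glcm_levels grey levels for the texture traits.
#' @param output_dir where overlays / CSV / logs are written.
#' @param overlays write overlay images?
#' @param seed integer seed recorded with the run.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(plot_model, spike_model, score_thresh = 0.3,
                            conf_thresh = 0.5, nms_iou = 0.45,
                            plot_area_m2 = 2.25, mask_dilate_px = 4L,
                            glcm_levels = 32L,
                            output_dir = tempfile("aircanopy_out_"),
                            overlays = TRUE, seed = 1L) {
  stopifnot(score_thresh >= 0, score_thresh <= 1,
            conf_thresh >= 0, conf_thresh <= 1,
            nms_iou >= 0, nms_iou <= 1, plot_area_m2 > 0)
  if (is.character(plot_model)) plot_model <- load_model(plot_model)
  if (is.character(spike_model)) spike_model <- load_model(spike_model)
  structure(list(plot_model = plot_model, spike_model = spike_model,
                 score_thresh = score_thresh, conf_thresh = conf_thresh,
                 nms_iou = nms_iou, plot_area_m2 = plot_area_m2,
                 mask_dilate_px = as.integer(mask_dilate_px),
                 glcm_levels = glcm_levels, output_dir = output_dir,
                 overlays = overlays, seed = as.integer(seed)),
            class = "pipeline_config")
}

read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("png")) png::readPNG(path)
  else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      abort("the jpeg package is required to read JPG images",
            class = "aircanopy_io_error")
    jpeg::readJPEG(path)
  } else abort(sprintf("unsupported image format: %s", path),
               class = "aircanopy_io_error")
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

draw_box_overlay <- function(image, boxes, color = c(1, 0, 0), width = 1L) {
  d <- dim(image)
  for (r in seq_len(nrow(boxes))) {
    x0 <- max(1L, round(boxes$xmin[r])); x1 <- min(d[2], round(boxes$xmax[r]))
    y0 <- max(1L, round(boxes$ymin[r])); y1 <- min(d[1], round(boxes$ymax[r]))
    if (x1 <= x0 || y1 <= y0) next
    for (ch in 1:3) {
      image[y0:min(y0 + width - 1L, y1), x0:x1, ch] <- color[ch]
      image[max(y1 - width + 1L, y0):y1, x0:x1, ch] <- color[ch]
      image[y0:y1, x0:min(x0 + width - 1L, x1), ch] <- color[ch]
      image[y0:y1, max(x1 - width + 1L, x0):x1, ch] <- color[ch]
    }
  }
  image
}

draw_mask_overlay <- function(image, mask, color = c(0, 0.6, 1),
                              alpha = 0.35) {
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * color[ch]
    image[, , ch] <- plane
  }
  image
}

# square-kernel binary dilation by r one-pixel passes
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  for (i in seq_len(r)) {
    up <- rbind(mask[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, mask[-h, , drop = FALSE])
    lf <- cbind(mask[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, mask[, -w, drop = FALSE])
    mask <- mask | up | dn | lf | rt
  }
  mask
}

flagged_record <- function(plot_id, flag) {
  rec <- trait_record(plot_id, NA_real_, NA_real_, NA_real_, NA_real_,
                      NA_real_, NA_real_, NA_real_)
  rec$flag <- flag
  rec
}

#' Analyse a single aerial image
#'
#' Segments the central plot, detects spikes inside it, computes the seven
#' traits and (optionally) writes two overlay images: the segmented plot
#' and the detected spikes with red boxes.  A missing plot yields a flagged
#' record with empty traits, not an error.
#'
#' @param image_path image file (PNG/JPG) or an H x W x 3 array.
#' @param cfg a [pipeline_config()].
#' @param plot_id record identifier (defaults to the file stem).
#' @return list with `record` (one-row trait tibble plus `flag` column),
#'   `segmentation`, `detections`, `overlays` (paths or NULL).
#' @export
run_single <- function(image_path, cfg, plot_id = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(image_path)) {
    plot_id <- plot_id %||% tools::file_path_sans_ext(basename(image_path))
    image <- read_rgb_image(image_path)
  } else {
    plot_id <- plot_id %||% "image"
    image <- image_path
  }
  seg <- segment_central_plot(image, cfg$plot_model, cfg$score_thresh)
  if (!isTRUE(seg$found) || !any(seg$mask))
    return(list(record = flagged_record(plot_id, "no_plot_found"),
                segmentation = seg, detections = NULL, overlays = NULL))
  d <- dim(image)
  # dilate the mask a few px for the detector input only: spikes straddling
  # a slightly tight mask boundary would otherwise be clipped and missed
  det_mask <- dilate_mask(seg$mask, cfg$mask_dilate_px)
  masked <- image
  for (ch in 1:3) masked[, , ch] <- masked[, , ch] * det_mask
  px <- which(det_mask, arr.ind = TRUE)
  y0 <- min(px[, 1]); y1 <- max(px[, 1]); x0 <- min(px[, 2]); x1 <- max(px[, 2])
  crop <- masked[y0:y1, x0:x1, , drop = FALSE]
  dets <- detect_spikes(crop, cfg$spike_model, cfg$conf_thresh, cfg$nms_iou)
  if (nrow(dets)) {
    dets$xmin <- dets$xmin + x0 - 1L; dets$xmax <- dets$xmax + x0 - 1L
    dets$ymin <- dets$ymin + y0 - 1L; dets$ymax <- dets$ymax + y0 - 1L
  }
  record <- extract_traits(image, seg$mask, spike_count = nrow(dets),
                           plot_area_m2 = cfg$plot_area_m2,
                           plot_id = plot_id, glcm_levels = cfg$glcm_levels)
  record$flag <- "ok"
  overlays <- NULL
  if (isTRUE(cfg$overlays)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    seg_path <- file.path(cfg$output_dir, paste0(plot_id, "_plot.png"))
    png::writePNG(draw_mask_overlay(image, seg$mask), seg_path)
    det_path <- file.path(cfg$output_dir, paste0(plot_id, "_spikes.png"))
    png::writePNG(draw_box_overlay(image, dets), det_path)
    overlays <- c(segmentation = seg_path, detections = det_path)
  }
  list(record = record, segmentation = seg, detections = dets,
       overlays = overlays)
}

#' Analyse a directory of aerial images
#'
#' Processes every PNG/JPG in `input_dir` in lexicographic order, writing
#' one CSV row per image (flagged rows included: a failed or plot-less
#' image never aborts the batch) and a line-delimited JSON status log with
#' per-stage timing.
#'
#' @param input_dir directory with at least one image.
#' @param cfg a [pipeline_config()].
#' @return list with `records` tibble, `csv` path, `log` path, `results`
#'   (per-file outputs).
#' @export
run_batch <- function(input_dir, cfg) {
  files <- sort(list.files(input_dir, pattern = "\\.(png|jpg|jpeg)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files))
    abort(sprintf("no images found in %s", input_dir),
          class = "aircanopy_io_error")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "batch_log.jsonl")
  con <- file(log_path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  results <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(run_single(f, cfg),
                    error = function(e) list(
                      record = flagged_record(
                        tools::file_path_sans_ext(basename(f)),
                        paste0("error: ", conditionMessage(e))),
                      segmentation = NULL, detections = NULL,
                      overlays = NULL))
    elapsed <- proc.time()[["elapsed"]] - t0
    writeLines(jsonlite::toJSON(list(
      file = basename(f), flag = res$record$flag,
      n_spikes = if (is.null(res$detections)) 0L else nrow(res$detections),
      seconds = round(elapsed, 3)), auto_unbox = TRUE), con)
    results[[i]] <- res
  }
  records <- dplyr::bind_rows(lapply(results, function(r) r$record))
  csv_path <- file.path(cfg$output_dir, "traits.csv")
  readr::write_csv(records[, c("plot_id", trait_columns, "flag")], csv_path,
                   progress = FALSE, na = "")
  list(records = records, csv = csv_path, log = log_path, results = results)
}
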