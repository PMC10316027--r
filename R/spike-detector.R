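# Single-class anchor-based spike detector (YOLO-style): a small strided
# trunk with detection heads at three scales (strides 4, 8, 16 at desk
# scale), three anchors per cell, per-anchor outputs (tx, ty, tw, th, obj).
# Spike counts divided by the plot ground area give SNpM2.

spike_profiles <- function(profile, seed) {
  switch(profile,
    desk = list(
      input_size = 160L,
      widths = c(16L, 24L, 32L, 48L),
      depths = c(1L, 1L, 1L),
      head_width = 32L,
      anchors = list(matrix(c(11, 11, 13, 6, 6, 13), 3, 2, byrow = TRUE),
                     matrix(c(22, 22, 26, 12, 12, 26), 3, 2, byrow = TRUE),
                     matrix(c(44, 44, 52, 24, 24, 52), 3, 2, byrow = TRUE)),
      seed = seed),
    standard = list(
      input_size = 640L,
      widths = c(48L, 96L, 192L, 384L),
      depths = c(3L, 3L, 3L),
      head_width = 192L,
      anchors = list(matrix(c(12, 16, 19, 36, 40, 28), 3, 2, byrow = TRUE),
                     matrix(c(36, 75, 76, 55, 72, 146), 3, 2, byrow = TRUE),
                     matrix(c(142, 110, 192, 243, 459, 401), 3, 2,
                            byrow = TRUE)),
      seed = seed),
    abort(sprintf("unknown spike-detector profile '%s'", profile),
          class = "aircanopy_config_error"))
}

#' Build the spike-detection model
#'
#' An anchor-based one-class detector with heads at three scales.  The desk
#' profile is a reduced-depth/width variant that overfits small synthetic
#' plots on a CPU in minutes; the standard profile mirrors the full-scale
#' layout (640 px input, the usual three-scale anchor ladder, wider and
#' deeper trunk).
#'
#' @param profile `"desk"` or `"standard"`.
#' @param seed weight-initialization seed.
#' @param config optional profile-config override (see the `spike_profiles`
#'   internals for the fields).
#' @return a `spike_model`.
#' @export
build_spike_detector <- function(profile = c("desk", "standard"), seed = 7L,
                                 config = NULL) {
  if (is.null(config)) {
    profile <- profile[1]
    config <- spike_profiles(profile, seed)
  } else {
    profile <- config$profile %||% "desk"
    needed <- c("input_size", "widths", "depths", "head_width", "anchors",
                "seed")
    if (!all(needed %in% names(config)))
      abort(paste("spike-detector config is missing:",
                  paste(setdiff(needed, names(config)), collapse = ", ")),
            class = "aircanopy_config_error")
  }
  w <- config$widths
  withr::with_seed(config$seed, {
    stem <- nn_conv_layer(3L, w[1], k = 3L, stride = 2L, act = "relu")
    down1 <- nn_conv_layer(w[1], w[2], k = 3L, stride = 2L, act = "relu")  # s4
    b1 <- lapply(seq_len(config$depths[1]), function(i)
      nn_conv_layer(w[2], w[2], k = 3L, act = "relu"))
    down2 <- nn_conv_layer(w[2], w[3], k = 3L, stride = 2L, act = "relu")  # s8
    b2 <- lapply(seq_len(config$depths[2]), function(i)
      nn_conv_layer(w[3], w[3], k = 3L, act = "relu"))
    down3 <- nn_conv_layer(w[3], w[4], k = 3L, stride = 2L, act = "relu")  # s16
    b3 <- lapply(seq_len(config$depths[3]), function(i)
      nn_conv_layer(w[4], w[4], k = 3L, act = "relu"))
    heads <- lapply(w[2:4], function(cw) list(
      tower = nn_conv_layer(cw, config$head_width, k = 3L, act = "relu"),
      out = nn_conv_layer(config$head_width, 3L * 5L, k = 1L,
                          act = "linear")))
  })
  structure(list(profile = profile, cfg = config,
                 input_size = config$input_size,
                 strides = c(4L, 8L, 16L),
                 stem = stem, downs = list(down1, down2, down3),
                 blocks = list(b1, b2, b3), heads = heads,
                 loss_history = numeric(0)),
            class = "spike_model")
}

spike_model_layers <- function(model)
  collect_layers(list(model$stem, model$downs, model$blocks, model$heads))

spike_forward <- function(model, image, tape = NULL) {
  tape <- tape %||% ad_tape()
  x <- ad_node(tape, pad_to_input(image, model$input_size))
  x <- layer_forward(tape, model$stem, x)
  outs <- vector("list", 3L)
  for (s in 1:3) {
    x <- layer_forward(tape, model$downs[[s]], x)
    for (blk in model$blocks[[s]]) {
      y <- layer_forward(tape, blk, x)
      x <- ad_add(tape, y, x)
    }
    t <- layer_forward(tape, model$heads[[s]]$tower, x)
    outs[[s]] <- layer_forward(tape, model$heads[[s]]$out, t)
  }
  list(tape = tape, outs = outs)
}

# decode one scale's raw output [h, w, 3*5] into a detection tibble
decode_spike_scale <- function(raw, stride, anchors, conf_thresh) {
  d <- dim(raw)
  h <- d[1]; w <- d[2]
  rows <- NULL
  for (a in 1:3) {
    ch <- (a - 1L) * 5L
    tx <- 1 / (1 + exp(-raw[, , ch + 1L]))
    ty <- 1 / (1 + exp(-raw[, , ch + 2L]))
    tw <- pmin(pmax(raw[, , ch + 3L], -4), 4)
    th <- pmin(pmax(raw[, , ch + 4L], -4), 4)
    obj <- 1 / (1 + exp(-raw[, , ch + 5L]))
    keep <- which(obj >= conf_thresh)
    if (!length(keep)) next
    i <- (keep - 1L) %% h + 1L
    j <- (keep - 1L) %/% h + 1L
    cx <- (j - 1 + tx[keep]) * stride
    cy <- (i - 1 + ty[keep]) * stride
    bw <- anchors[a, 1] * exp(tw[keep])
    bh <- anchors[a, 2] * exp(th[keep])
    rows <- dplyr::bind_rows(rows, tibble(
      xmin = cx - bw / 2, ymin = cy - bh / 2,
      xmax = cx + bw / 2, ymax = cy + bh / 2,
      score = obj[keep], class_id = 1L, label = "spike"))
  }
  rows
}

#' Detect wheat spikes in a segmented plot image
#'
#' Resizes the (masked) plot crop to the model input, runs the detector,
#' decodes all three scales, keeps detections at or above `conf_thresh` and
#' applies class-agnostic sequential NMS.  Box coordinates are mapped back
#' to the crop's pixel frame.
#'
#' @param plot_image H x W x 3 array: the central plot crop with non-plot
#'   pixels zeroed.
#' @param model a trained `spike_model`.
#' @param conf_thresh minimum objectness score.
#' @param nms_iou NMS IoU threshold.
#' @return detection tibble (`xmin/ymin/xmax/ymax`, `score`, `label`),
#'   sorted by descending score.
#' @export
detect_spikes <- function(plot_image, model, conf_thresh = 0.5,
                          nms_iou = 0.45) {
  d <- dim(plot_image)
  lb <- letterbox_to_input(plot_image, model$input_size)
  fwd <- spike_forward(model, lb$image)
  dets <- purrr::map2_dfr(fwd$outs, seq_along(fwd$outs), function(node, s)
    decode_spike_scale(node$value, model$strides[s],
                       model$cfg$anchors[[s]], conf_thresh) %||% tibble())
  if (!nrow(dets)) return(tibble(xmin = numeric(0), ymin = numeric(0),
                                 xmax = numeric(0), ymax = numeric(0),
                                 score = numeric(0), class_id = integer(0),
                                 label = character(0)))
  dets <- sequential_nms(dets, nms_iou, top_k = 1000L)
  # map back from model input frame to the crop frame
  dets$xmin <- (dets$xmin - lb$origin[1]) / lb$scale
  dets$xmax <- (dets$xmax - lb$origin[1]) / lb$scale
  dets$ymin <- (dets$ymin - lb$origin[2]) / lb$scale
  dets$ymax <- (dets$ymax - lb$origin[2]) / lb$scale
  dets
}

# place a crop on the model's square input canvas at native scale when it
# fits, shrinking (never enlarging) otherwise; keeps spike geometry aligned
# with the anchor ladder
letterbox_to_input <- function(image, side, origin = c(0L, 0L)) {
  d <- dim(image)
  scale <- min(1, side / d[1], side / d[2])
  img <- image
  if (scale < 1) {
    nh <- max(1L, floor(d[1] * scale)); nw <- max(1L, floor(d[2] * scale))
    scale <- min(nh / d[1], nw / d[2])
    res <- array(0, c(nh, nw, 3))
    for (ch in 1:3) res[, , ch] <- resize_bilinear(image[, , ch], nh, nw)
    img <- res
  }
  canvas <- array(0, c(side, side, 3))
  dd <- dim(img)
  oy <- min(origin[2], side - dd[1]); ox <- min(origin[1], side - dd[2])
  canvas[oy + seq_len(dd[1]), ox + seq_len(dd[2]), ] <- img
  list(image = canvas, scale = scale, origin = c(ox, oy))
}

# assignment of ground-truth boxes to (scale, anchor, cell): best anchor by
# shape IoU, greedily, one anchor slot per GT
assign_spike_targets <- function(boxes, model) {
  if (!nrow(boxes)) return(NULL)
  shape_iou <- function(w1, h1, w2, h2) {
    inter <- pmin(w1, w2) * pmin(h1, h2)
    inter / (w1 * h1 + w2 * h2 - inter)
  }
  out <- list()
  taken <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(boxes))) {
    bw <- boxes$xmax[r] - boxes$xmin[r]
    bh <- boxes$ymax[r] - boxes$ymin[r]
    cx <- (boxes$xmin[r] + boxes$xmax[r]) / 2
    cy <- (boxes$ymin[r] + boxes$ymax[r]) / 2
    cand <- purrr::map_dfr(1:3, function(s) {
      an <- model$cfg$anchors[[s]]
      tibble(scale = s, anchor = 1:3,
             iou = shape_iou(bw, bh, an[, 1], an[, 2]))
    })
    cand <- cand[order(-cand$iou), ]
    placed <- FALSE
    for (q in seq_len(nrow(cand))) {
      s <- cand$scale[q]; a <- cand$anchor[q]
      stride <- model$strides[s]
      gsz <- model$input_size %/% stride
      j <- pmin(pmax(floor(cx / stride) + 1L, 1L), gsz)
      i <- pmin(pmax(floor(cy / stride) + 1L, 1L), gsz)
      key <- paste(s, a, i, j, sep = "_")
      if (is.null(taken[[key]])) {
        taken[[key]] <- TRUE
        an <- model$cfg$anchors[[s]]
        out[[length(out) + 1L]] <- tibble(
          scale = s, anchor = a, i = i, j = j,
          tx = cx / stride - (j - 1), ty = cy / stride - (i - 1),
          tw = log(bw / an[a, 1]), th = log(bh / an[a, 2]))
        placed <- TRUE
        break
      }
    }
    # a GT that finds no free slot is dropped from the loss (dense packing)
  }
  dplyr::bind_rows(out)
}

# precompute per-scale objectness targets/weights and coordinate-loss
# indices for one training example.  Negative anchors whose box overlaps
# any ground-truth spike moderately (IoU > ignore_iou) are ignored: they
# see spike pixels without owning the spike, so supervising them as
# background stalls training in dense scenes.
spike_example_targets <- function(boxes, targets, model, ignore_iou = 0.99) {
  npos_total <- max(1L, if (is.null(targets)) 0L else nrow(targets))
  out <- vector("list", 3L)
  for (s in 1:3) {
    stride <- model$strides[s]
    gsz <- model$input_size %/% stride
    h <- gsz; w <- gsz
    obj_t <- array(0, c(h, w, 15L))
    obj_w <- array(0, c(h, w, 15L))
    an <- model$cfg$anchors[[s]]
    cell_cx <- (rep(seq_len(w), each = h) - 0.5) * stride
    cell_cy <- (rep(seq_len(h), times = w) - 0.5) * stride
    for (a in 1:3) {
      abox <- tibble(xmin = cell_cx - an[a, 1] / 2, ymin = cell_cy - an[a, 2] / 2,
                     xmax = cell_cx + an[a, 1] / 2, ymax = cell_cy + an[a, 2] / 2)
      max_iou <- if (nrow(boxes)) apply(iou_matrix(abox, boxes), 1, max)
                 else numeric(h * w)
      wplane <- ifelse(max_iou > ignore_iou, 0, 1)
      obj_w[, , (a - 1L) * 5L + 5L] <- matrix(wplane, h, w)
    }
    tsel <- if (is.null(targets)) NULL else targets[targets$scale == s, ]
    coord <- NULL
    if (!is.null(tsel) && nrow(tsel)) {
      pos_lin <- tsel$i + (tsel$j - 1L) * h +
        ((tsel$anchor - 1L) * 5L + 4L) * h * w
      # in a cell that owns a ground truth, the two unassigned anchor slots
      # are explicit negatives (not ignored): otherwise they fire as
      # unsupervised duplicates that NMS cannot merge
      for (a in 1:3) {
        dup <- tsel$i + (tsel$j - 1L) * h + ((a - 1L) * 5L + 4L) * h * w
        dup <- setdiff(dup, pos_lin)
        obj_w[dup] <- 1
      }
      obj_t[pos_lin] <- 1
      obj_w[pos_lin] <- 0          # positives weighted separately below
      n_neg <- sum(obj_w > 0)
      obj_w <- obj_w * (1.5 / max(n_neg, 1L))
      obj_w[pos_lin] <- 2 / npos_total
      base <- (tsel$anchor - 1L) * 5L
      sp <- (tsel$j - 1L) * h + tsel$i
      idx_of <- function(ch) sp + (ch - 1L) * h * w
      coord <- list(
        xy_idx = c(idx_of(base + 1L), idx_of(base + 2L)),
        xy_t = c(tsel$tx, tsel$ty),
        xy_w = rep(2 / npos_total, 2L * nrow(tsel)),
        wh_idx = c(idx_of(base + 3L), idx_of(base + 4L)),
        wh_t = c(tsel$tw, tsel$th),
        wh_w = rep(1 / npos_total, 2L * nrow(tsel)))
    } else {
      n_neg <- sum(obj_w > 0)
      obj_w <- obj_w * (1.5 / max(n_neg, 1L))
    }
    out[[s]] <- list(obj_t = obj_t, obj_w = obj_w,
                     neg_mask = obj_w > 0 & obj_t == 0, coord = coord)
  }
  out
}

spike_loss <- function(model, fwd, scale_targets) {
  tape <- fwd$tape
  losses <- list()
  for (s in 1:3) {
    node <- fwd$outs[[s]]
    st <- scale_targets[[s]]
    # on top of the uniform negative weight, concentrate extra mass on the
    # currently highest-scoring negatives so persistent false positives
    # receive gradients comparable to the positives
    obj_w <- st$obj_w
    neg_lin <- which(st$neg_mask)
    if (length(neg_lin)) {
      npos <- max(1L, sum(st$obj_t == 1))
      k <- min(3L * npos, length(neg_lin))
      hard <- neg_lin[order(-node$value[neg_lin])[seq_len(k)]]
      obj_w[hard] <- obj_w[hard] + 1.5 / k
    }
    losses[[length(losses) + 1L]] <-
      ad_bce_logits(tape, node, st$obj_t, obj_w)
    if (!is.null(st$coord)) {
      sig_part <- ad_sigmoid(tape, ad_gather(tape, node, st$coord$xy_idx))
      losses[[length(losses) + 1L]] <-
        ad_smooth_l1(tape, sig_part, st$coord$xy_t, st$coord$xy_w)
      wh <- ad_gather(tape, node, st$coord$wh_idx)
      losses[[length(losses) + 1L]] <-
        ad_smooth_l1(tape, wh, st$coord$wh_t, st$coord$wh_w)
    }
  }
  ad_sum_nodes(tape, losses)
}

#' Train the spike detector
#'
#' SGD with momentum on objectness BCE plus smooth-L1 coordinate losses.
#' Deterministic for a fixed seed.
#'
#' @param dataset list of examples: each `list(image, boxes)` with `boxes`
#'   a box tibble in image coordinates, or a `canopy_scene` (its plot crop
#'   is used; see [scene_plot_crop()]).
#' @param hyper overrides for `iterations` (300), `lr` (0.001),
#'   `momentum` (0.9), `seed` (7), `profile` (`"desk"`), and `jitter`
#'   (list of letterbox origins cycled over iterations; default no jitter).
#' @param model optionally continue training.
#' @return trained `spike_model` with `$loss_history`.
#' @export
train_spike_detector <- function(dataset, hyper = list(), model = NULL) {
  if (length(dataset) == 0L)
    abort("empty training dataset", class = "aircanopy_validation_error")
  h <- utils::modifyList(list(iterations = 300L, lr = 0.001, momentum = 0.9,
                              seed = 7L, profile = "desk"), hyper)
  model <- model %||% build_spike_detector(h$profile, seed = h$seed)
  # optional translation jitter: each example can be letterboxed at several
  # sub-cell origins, cycled over iterations, trading per-phase convergence
  # for tolerance to the small crop-origin shifts a predicted (rather than
  # ground-truth) plot mask induces at inference time
  jitters <- h$jitter %||% list(c(0L, 0L))
  preps <- lapply(dataset, function(ex) {
    if (inherits(ex, "canopy_scene")) ex <- scene_plot_crop(ex)
    lapply(jitters, function(jt) {
      lb <- letterbox_to_input(ex$image, model$input_size, origin = jt)
      boxes <- ex$boxes
      boxes$xmin <- boxes$xmin * lb$scale + lb$origin[1]
      boxes$xmax <- boxes$xmax * lb$scale + lb$origin[1]
      boxes$ymin <- boxes$ymin * lb$scale + lb$origin[2]
      boxes$ymax <- boxes$ymax * lb$scale + lb$origin[2]
      targets <- assign_spike_targets(boxes, model)
      list(image = lb$image,
           targets = spike_example_targets(boxes, targets, model))
    })
  })
  layers <- spike_model_layers(model)
  for (it in seq_len(h$iterations)) {
    variant <- (it - 1L) %% length(jitters) + 1L
    tot <- 0
    for (ex_prep in preps) {
      prep <- ex_prep[[variant]]
      fwd <- spike_forward(model, prep$image)
      loss <- spike_loss(model, fwd, prep$targets)
      ad_backward(fwd$tape, loss)
      accumulate_grads(layers)
      tot <- tot + loss$value
    }
    apply_sgd(layers, h$lr, h$momentum, scale = 1 / length(preps))
    model$loss_history <- c(model$loss_history, tot / length(preps))
  }
  model
}

#' Ground-truth plot crop of a synthetic scene
#'
#' Crops the scene to the central plot's bounding box, zeroes non-plot
#' pixels, and shifts the spike boxes into the crop frame.
#'
#' @param scene a `canopy_scene`.
#' @return list with `image`, `boxes`, `offset`.
#' @export
scene_plot_crop <- function(scene) {
  v <- scene$plot_polygon$vertices[[1]]
  d <- dim(scene$image)
  x0 <- max(1L, floor(min(v$x)) + 1L); x1 <- min(d[2], ceiling(max(v$x)))
  y0 <- max(1L, floor(min(v$y)) + 1L); y1 <- min(d[1], ceiling(max(v$y)))
  mask <- polygon_mask(v, d[1:2])
  img <- scene$image
  for (ch in 1:3) img[, , ch] <- img[, , ch] * mask
  crop <- img[y0:y1, x0:x1, , drop = FALSE]
  boxes <- scene$spike_boxes
  if (nrow(boxes)) {
    boxes$xmin <- boxes$xmin - (x0 - 1L); boxes$xmax <- boxes$xmax - (x0 - 1L)
    boxes$ymin <- boxes$ymin - (y0 - 1L); boxes$ymax <- boxes$ymax - (y0 - 1L)
  }
  list(image = crop, boxes = boxes, offset = c(x0 - 1L, y0 - 1L))
}

#' Spike number per square metre
#'
#' @param count non-negative spike count.
#' @param plot_area_m2 plot ground area in square metres; the default
#'   2.25 corresponds to a 1.5 m x 1.5 m breeding plot.
#' @return spikes per square metre.
#' @export
snpm2 <- function(count, plot_area_m2 = 2.25) {
  if (any(plot_area_m2 <= 0))
    abort("plot area must be positive", class = "aircanopy_validation_error")
  if (any(count < 0))
    abort("count must be non-negative", class = "aircanopy_validation_error")
  count / plot_area_m2
}
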