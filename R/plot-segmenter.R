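# YOLACT-style plot instance segmentation: a ProtoNet branch generating k
# shared prototype masks from P3, an anchor-based prediction head emitting
# class scores, box regressions and per-anchor mask coefficients at every
# pyramid level, Fast NMS, and linear mask assembly with 0.5 thresholding.

ANCHOR_RATIOS <- c(1, 1 / 2, 2, 1 / 3, 3)
BOX_VARIANCES <- c(0.1, 0.2)

# ---- anchors ---------------------------------------------------------------

# anchor table for one pyramid: rows ordered level, then ratio, then
# positions column-major (row index fastest) — matching the layout of the
# flattened head outputs
anchor_table <- function(level_sizes, input_size, scale_factor = 3) {
  purrr::imap_dfr(level_sizes, function(hl, lv) {
    stride <- input_size / hl
    scale <- scale_factor * stride
    purrr::imap_dfr(ANCHOR_RATIOS, function(r, a) {
      aw <- scale * sqrt(r); ah <- scale / sqrt(r)
      i <- rep(seq_len(hl), times = hl)
      j <- rep(seq_len(hl), each = hl)
      tibble(level = lv, anchor = a, i = i, j = j,
             cx = (j - 0.5) * stride, cy = (i - 0.5) * stride,
             w = aw, h = ah)
    })
  })
}

anchor_boxes <- function(an) {
  tibble(xmin = an$cx - an$w / 2, ymin = an$cy - an$h / 2,
         xmax = an$cx + an$w / 2, ymax = an$cy + an$h / 2)
}

decode_boxes <- function(an, deltas, input_size) {
  cx <- an$cx + deltas[, 1] * BOX_VARIANCES[1] * an$w
  cy <- an$cy + deltas[, 2] * BOX_VARIANCES[1] * an$h
  w <- an$w * exp(pmin(pmax(deltas[, 3] * BOX_VARIANCES[2], -6), 6))
  h <- an$h * exp(pmin(pmax(deltas[, 4] * BOX_VARIANCES[2], -6), 6))
  tibble(xmin = pmin(pmax(cx - w / 2, 0), input_size),
         ymin = pmin(pmax(cy - h / 2, 0), input_size),
         xmax = pmin(pmax(cx + w / 2, 0), input_size),
         ymax = pmin(pmax(cy + h / 2, 0), input_size))
}

encode_boxes <- function(an, gt) {
  gw <- gt[3] - gt[1]; gh <- gt[4] - gt[2]
  gx <- (gt[1] + gt[3]) / 2; gy <- (gt[2] + gt[4]) / 2
  cbind((gx - an$cx) / an$w / BOX_VARIANCES[1],
        (gy - an$cy) / an$h / BOX_VARIANCES[1],
        log(gw / an$w) / BOX_VARIANCES[2],
        log(gh / an$h) / BOX_VARIANCES[2])
}

# ---- public ops ------------------------------------------------------------

#' ProtoNet prototype masks
#'
#' Generates `k` non-negative prototype maps from the P3 feature map with a
#' small fully convolutional branch (final ReLU enforces non-negativity).
#'
#' @param p3 H x W x C feature array (the P3 level).
#' @param k number of prototypes, `>= 1`.
#' @param weights optional branch weights for reuse.
#' @param seed weight-initialization seed.
#' @param upsample if `TRUE`, prototypes are emitted at twice the P3
#'   resolution (the convention used inside the full pipeline); the default
#'   keeps P3 resolution.
#' @return a `prototype_masks` object: list with `tensor` (h x w x k,
#'   all `>= 0`), `k` and `weights`.
#' @export
protonet <- function(p3, k = 8L, weights = NULL, seed = 1L,
                     upsample = FALSE) {
  stopifnot(k >= 1L)
  p3 <- as_feature_array(p3)
  w <- weights %||% new_protonet(dim(p3)[3], k, seed)
  tape <- ad_tape()
  out <- protonet_forward(tape, w, ad_node(tape, p3), upsample)
  structure(list(tensor = out$value, k = k, weights = w),
            class = "prototype_masks")
}

new_protonet <- function(cin, k, seed = 1L) {
  withr::with_seed(seed, list(
    conv1 = nn_conv_layer(cin, cin, k = 3L, act = "relu"),
    conv2 = nn_conv_layer(cin, cin, k = 3L, act = "relu"),
    out = nn_conv_layer(cin, k, k = 1L, act = "relu")))
}

protonet_forward <- function(tape, w, p3, upsample = TRUE) {
  y <- layer_forward(tape, w$conv2, layer_forward(tape, w$conv1, p3))
  if (upsample) y <- ad_upsample2(tape, y)
  layer_forward(tape, w$out, y)
}

new_pred_head <- function(fw, k, seed = 1L, n_anchors = length(ANCHOR_RATIOS)) {
  withr::with_seed(seed, list(
    tower = nn_conv_layer(fw, fw, k = 3L, act = "relu"),
    cls = nn_conv_layer(fw, n_anchors, k = 3L, act = "linear"),
    box = nn_conv_layer(fw, n_anchors * 4L, k = 3L, act = "linear"),
    coef = nn_conv_layer(fw, n_anchors * k, k = 3L, act = "tanh")))
}

head_forward <- function(tape, head, feats) {
  lapply(feats, function(p) {
    t <- layer_forward(tape, head$tower, p)
    list(cls = layer_forward(tape, head$cls, t),
         box = layer_forward(tape, head$box, t),
         coef = layer_forward(tape, head$coef, t))
  })
}

# flatten per-level head outputs into per-anchor rows aligned with
# anchor_table() ordering
flatten_head <- function(level_out, n_anchors, per_anchor) {
  do.call(rbind, lapply(level_out, function(v) {
    d <- dim(v)
    do.call(rbind, lapply(seq_len(n_anchors), function(a) {
      cols <- (a - 1L) * per_anchor + seq_len(per_anchor)
      matrix(v[, , cols], d[1] * d[2], per_anchor)
    }))
  }))
}

#' Anchor-based prediction head
#'
#' Runs the shared prediction tower over the pyramid levels P3-P7.  Every
#' pyramid location carries 5 anchors with aspect ratios 1, 1/2, 2, 1/3, 3
#' (one scale per level); each anchor emits a class score, a box regression
#' relative to the anchor, and `k` mask coefficients.
#'
#' @param p_levels named list of P3..P7 feature arrays (equal channel
#'   width).
#' @param k mask coefficients per anchor.
#' @param input_size input image side in px (anchor geometry).
#' @param weights optional head weights.
#' @param seed weight-initialization seed.
#' @return tibble of pre-NMS detections: decoded `xmin/ymin/xmax/ymax`,
#'   `score`, `class_id`, `level`, `anchor`, and a `mask_coeffs`
#'   list-column.
#' @export
prediction_head <- function(p_levels, k = 8L, input_size = NULL,
                            weights = NULL, seed = 1L) {
  stopifnot(all(paste0("P", 3:7) %in% names(p_levels)))
  p_levels <- p_levels[paste0("P", 3:7)]
  sizes <- vapply(p_levels, function(p) dim(p)[1], numeric(1))
  input_size <- input_size %||% (8 * sizes[1])
  fw <- dim(p_levels[[1]])[3]
  head <- weights %||% new_pred_head(fw, k, seed)
  tape <- ad_tape()
  nodes <- lapply(p_levels, function(p) ad_node(tape, p))
  out <- head_forward(tape, head, nodes)
  an <- anchor_table(sizes, input_size)
  na <- length(ANCHOR_RATIOS)
  cls <- flatten_head(lapply(out, function(o) o$cls$value), na, 1L)
  box <- flatten_head(lapply(out, function(o) o$box$value), na, 4L)
  coef <- flatten_head(lapply(out, function(o) o$coef$value), na, k)
  dets <- decode_boxes(an, box, input_size)
  dets$score <- 1 / (1 + exp(-cls[, 1]))
  dets$class_id <- 1L
  dets$level <- an$level
  dets$anchor <- an$anchor
  dets$mask_coeffs <- lapply(seq_len(nrow(coef)), function(r) coef[r, ])
  dets
}

#' Fast non-maximum suppression
#'
#' Matrix-form NMS: a detection is suppressed when its IoU with *any*
#' higher-scoring detection — kept or not — exceeds `iou_thresh`.  Slightly
#' more aggressive than sequential NMS (a suppressed box can still suppress
#' others), which is what makes it one matrix operation.
#'
#' @param dets detection tibble with box columns and `score`.
#' @param iou_thresh suppression threshold in `[0, 1]`.
#' @param top_k maximum detections returned.
#' @return the kept detections, sorted by descending score; every kept pair
#'   has IoU `<= iou_thresh`.
#' @export
fast_nms <- function(dets, iou_thresh = 0.5, top_k = 100L) {
  if (is.null(dets) || nrow(dets) == 0L) return(dets)
  ord <- order(-dets$score, seq_len(nrow(dets)))
  d <- dets[ord, ]
  iou <- iou_matrix(d, d)
  iou[lower.tri(iou, diag = TRUE)] <- 0          # only higher-scoring rows
  keep <- apply(iou, 2, max) <= iou_thresh
  out <- d[keep, ]
  utils::head(out, top_k)
}

#' Sequential (greedy) non-maximum suppression
#'
#' The classical variant: only *kept* detections suppress.
#'
#' @inheritParams fast_nms
#' @export
sequential_nms <- function(dets, iou_thresh = 0.5, top_k = 100L) {
  if (is.null(dets) || nrow(dets) == 0L) return(dets)
  ord <- order(-dets$score, seq_len(nrow(dets)))
  d <- dets[ord, ]
  iou <- iou_matrix(d, d)
  n <- nrow(d)
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[iou[i, ] > iou_thresh] <- FALSE
  }
  utils::head(d[keep, ], top_k)
}

resize_bilinear <- function(m, oh, ow) {
  h <- nrow(m); w <- ncol(m)
  ys <- (seq_len(oh) - 0.5) * h / oh + 0.5
  xs <- (seq_len(ow) - 0.5) * w / ow + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(xs), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y1, x0, drop = FALSE]
  cc <- m[y0, x1, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  fym <- matrix(fy, oh, ow); fxm <- matrix(fx, oh, ow, byrow = TRUE)
  (a * (1 - fym) + b * fym) * (1 - fxm) + (cc * (1 - fym) + d * fym) * fxm
}

#' Assemble an instance mask from prototypes and coefficients
#'
#' The mask logits are the coefficient-weighted linear combination of the
#' prototype maps; a sigmoid, bilinear upsampling to image size, cropping
#' to the detection box and strict 0.5 thresholding give the binary mask.
#'
#' @param prototypes a `prototype_masks` object (or h x w x k array).
#' @param det one detection: a one-row tibble (or list) with the box and
#'   `mask_coeffs` of length k.
#' @param image_size `c(H, W)` of the output mask.
#' @param threshold sigmoid threshold (strict `>`).
#' @return a `plot_segmentation`: list with binary `mask` (H x W), `box`,
#'   `score`, `found = TRUE`.
#' @export
assemble_mask <- function(prototypes, det, image_size, threshold = 0.5) {
  tensor <- if (inherits(prototypes, "prototype_masks")) prototypes$tensor
            else prototypes
  k <- dim(tensor)[3]
  coef <- if (is.data.frame(det)) det$mask_coeffs[[1]] else det$mask_coeffs
  if (length(coef) != k)
    abort(sprintf("got %d mask coefficients for %d prototypes",
                  length(coef), k),
          class = "aircanopy_shape_error")
  box <- if (is.data.frame(det)) c(det$xmin, det$ymin, det$xmax, det$ymax)
         else det$box
  logits <- matrix(tensor, prod(dim(tensor)[1:2]), k) %*% coef
  prob <- 1 / (1 + exp(-matrix(logits, dim(tensor)[1], dim(tensor)[2])))
  up <- resize_bilinear(prob, image_size[1], image_size[2])
  mask <- up > threshold
  # crop: zero outside the (slightly dilated) detection box
  pad <- 2L
  x0 <- max(1L, floor(box[1]) + 1L - pad); x1 <- min(image_size[2], ceiling(box[3]) + pad)
  y0 <- max(1L, floor(box[2]) + 1L - pad); y1 <- min(image_size[1], ceiling(box[4]) + pad)
  crop <- matrix(FALSE, image_size[1], image_size[2])
  if (x1 >= x0 && y1 >= y0) crop[y0:y1, x0:x1] <- TRUE
  structure(list(mask = mask & crop, box = box,
                 score = if (is.data.frame(det)) det$score else det$score,
                 found = TRUE),
            class = "plot_segmentation")
}

# ---- full model ------------------------------------------------------------

#' Build a plot-segmentation model
#'
#' The desk profile (160 px input, 8 prototypes, single reduced-width
#' Res2Net-CBAM block per stage) trains on a CPU in minutes; the standard
#' profile mirrors the full-scale working configuration (550 px input
#' padded to 576, 32 prototypes, deeper stages).
#'
#' @param profile `"desk"` or `"standard"`.
#' @param seed weight-initialization seed.
#' @param config optional [backbone_config()] override.
#' @param prototypes optional prototype-count override.
#' @return a `plot_model`.
#' @export
build_plot_model <- function(profile = c("desk", "standard"), seed = 42L,
                             config = NULL, prototypes = NULL) {
  profile <- match.arg(profile)
  if (is.null(config)) {
    config <- if (profile == "desk")
      backbone_config(input_size = 160L, seed = seed)
    else
      backbone_config(input_size = 550L, stem_width = 16L,
                      stage_channels = c(32L, 64L, 96L, 128L),
                      stage_depths = c(2L, 2L, 2L, 2L),
                      fpn_width = 64L, reduction = 16L, seed = seed)
  }
  k <- prototypes %||% (if (profile == "desk") 8L else 32L)
  backbone <- build_backbone_fpn(config)
  proto <- withr::with_seed(seed + 1L, new_protonet(config$fpn_width, k))
  head <- withr::with_seed(seed + 2L, new_pred_head(config$fpn_width, k))
  input_size <- 32L * as.integer(ceiling(config$input_size / 32))
  structure(list(profile = profile, cfg = config, k = k,
                 input_size = input_size,
                 backbone = backbone, proto = proto, head = head,
                 loss_history = numeric(0)),
            class = "plot_model")
}

plot_model_layers <- function(model)
  collect_layers(list(model$backbone[c("stem", "stages", "lat", "smooth",
                                       "p6", "p7")],
                      model$proto, model$head))

#' Conv-layer specs of an instantiated model
#'
#' Enumerates the model's convolution layers as a [layer_spec()] tibble
#' (spatial sizes unset), e.g. to cross-check [count_params()] against the
#' actual weight arrays.
#'
#' @param model a model with conv layers (`plot_model`, `spike_model`,
#'   `backbone_fpn`).
#' @return layer tibble.
#' @export
model_layer_specs <- function(model) {
  layers <- if (inherits(model, "plot_model")) plot_model_layers(model)
            else if (inherits(model, "spike_model")) spike_model_layers(model)
            else collect_layers(model)
  purrr::map_dfr(layers, function(L)
    layer_spec(L$spec$k, L$spec$cin, L$spec$cout, 1L, 1L))
}

plot_forward <- function(model, image, tape = NULL) {
  tape <- tape %||% ad_tape()
  feats <- backbone_forward(model$backbone, image, tape)
  p <- feats[paste0("P", 3:7)]
  proto <- protonet_forward(tape, model$proto, feats$P3, upsample = TRUE)
  head_out <- head_forward(tape, model$head, p)
  list(tape = tape, feats = feats, proto = proto, head = head_out,
       sizes = vapply(p, function(n) dim(n$value)[1], numeric(1)))
}

plot_model_anchors <- function(model, sizes) {
  key <- paste(sizes, collapse = "_")
  if (is.null(model$anchors) || !identical(model$anchor_key, key)) {
    an <- anchor_table(sizes, model$input_size)
    an$idx <- seq_len(nrow(an))
    return(an)
  }
  model$anchors
}

# ---- training --------------------------------------------------------------

prep_plot_example <- function(example, input_size) {
  if (inherits(example, "canopy_scene")) {
    image <- example$image
    poly <- example$plot_polygon$vertices[[1]]
  } else {
    image <- example$image
    poly <- example$polygon       # NULL marks a negative (plot-free) example
  }
  img <- pad_to_input(image, input_size)
  if (is.null(poly))
    return(list(image = img, mask = NULL, box = NULL))
  side <- dim(img)[1]
  mask <- polygon_mask(poly, c(side, side))
  box <- c(min(poly$x), min(poly$y), max(poly$x), max(poly$y))
  list(image = img, mask = mask, box = box)
}


downsample_mask <- function(mask, out_side) {
  f <- nrow(mask) / out_side
  idx <- function(o) pmin(pmax(floor((o - 0.5) * f) + 1L, 1L), nrow(mask))
  # average over f x f blocks via cumulative sums for exactness
  cs <- apply(apply(mask, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  block_sum <- function(y0, y1, x0, x1) {
    s <- cs[y1, x1]
    if (y0 > 1) s <- s - cs[y0 - 1, x1]
    if (x0 > 1) s <- s - cs[y1, x0 - 1]
    if (y0 > 1 && x0 > 1) s <- s + cs[y0 - 1, x0 - 1]
    s
  }
  out <- matrix(0, out_side, out_side)
  bounds <- round(seq(0, nrow(mask), length.out = out_side + 1))
  for (i in seq_len(out_side)) for (j in seq_len(out_side)) {
    y0 <- bounds[i] + 1; y1 <- bounds[i + 1]
    x0 <- bounds[j] + 1; x1 <- bounds[j + 1]
    out[i, j] <- block_sum(y0, y1, x0, x1) / ((y1 - y0 + 1) * (x1 - x0 + 1))
  }
  out
}

plot_loss <- function(model, prep, fwd, anchors, n_mask_anchors = 4L) {
  tape <- fwd$tape
  # negative (plot-free) example: suppress the hardest anchor scores
  if (is.null(prep$box)) {
    cls_flat <- flatten_head(lapply(fwd$head, function(o) o$cls$value),
                             length(ANCHOR_RATIOS), 1L)[, 1]
    keep <- order(-cls_flat)[seq_len(min(32L, length(cls_flat)))]
    wts <- numeric(length(cls_flat))
    # negatives are a minority of the batch; weight them up so the
    # "one object per frame" prior cannot dominate
    wts[keep] <- 3 / length(keep)
    losses <- list()
    offset <- 0L
    for (lv in seq_along(fwd$head)) {
      node <- fwd$head[[lv]]$cls
      nlv <- length(node$value)
      sel <- (offset + 1L):(offset + nlv)
      if (any(wts[sel] > 0)) {
        w_arr <- array(wts[sel], dim(node$value))
        losses[[length(losses) + 1L]] <-
          ad_bce_logits(tape, node, array(0, dim(node$value)), w_arr)
      }
      offset <- offset + nlv
    }
    return(ad_sum_nodes(tape, losses))
  }
  an_box <- anchor_boxes(anchors)
  gt <- prep$box
  iou <- iou_matrix(an_box, tibble(xmin = gt[1], ymin = gt[2],
                                   xmax = gt[3], ymax = gt[4]))[, 1]
  pos <- iou >= 0.5
  pos[which.max(iou)] <- TRUE
  neg <- iou < 0.4
  npos <- sum(pos)

  losses <- list()
  # classification: BCE over every level's logits with a weight array;
  # negatives hard-mined at 3:1
  cls_flat <- flatten_head(lapply(fwd$head, function(o) o$cls$value),
                           length(ANCHOR_RATIOS), 1L)[, 1]
  n_neg_keep <- min(3L * npos, sum(neg))
  neg_idx <- which(neg)[order(-cls_flat[neg])[seq_len(n_neg_keep)]]
  wts <- numeric(length(cls_flat))
  wts[pos] <- 1 / npos
  wts[neg_idx] <- 1 / n_neg_keep
  tgt <- as.numeric(pos)
  # split weights back per level to apply on each level's node
  offset <- 0L
  for (lv in seq_along(fwd$head)) {
    node <- fwd$head[[lv]]$cls
    nlv <- length(node$value)
    sel <- (offset + 1L):(offset + nlv)
    if (any(wts[sel] > 0)) {
      w_arr <- array(level_unflatten(wts[sel], dim(node$value)), dim(node$value))
      t_arr <- array(level_unflatten(tgt[sel], dim(node$value)), dim(node$value))
      losses[[length(losses) + 1L]] <- ad_bce_logits(tape, node, t_arr, w_arr)
    }
    offset <- offset + nlv
  }

  # box regression on positive anchors
  enc <- encode_boxes(anchors[pos, ], gt)
  offset <- 0L
  pos_rows <- which(pos)
  for (lv in seq_along(fwd$head)) {
    node <- fwd$head[[lv]]$box
    d <- dim(node$value)
    n_anchor_lv <- d[1] * d[2] * length(ANCHOR_RATIOS)
    lv_rows <- pos_rows[pos_rows > offset & pos_rows <= offset + n_anchor_lv]
    if (length(lv_rows)) {
      loc <- lv_rows - offset
      a_id <- (loc - 1L) %/% (d[1] * d[2]) + 1L
      sp <- (loc - 1L) %% (d[1] * d[2])
      idx <- rep(sp, each = 4L) +
        (rep((a_id - 1L) * 4L, each = 4L) + rep(0:3, length(loc))) * d[1] * d[2] + 1L
      gathered <- ad_gather(tape, node, idx)
      tgt_b <- as.vector(t(enc[match(lv_rows, pos_rows), , drop = FALSE]))
      wt <- rep(1 / (4 * npos), length(idx))
      losses[[length(losses) + 1L]] <-
        ad_smooth_l1(tape, gathered, tgt_b, wt)
    }
    offset <- offset + n_anchor_lv
  }

  # mask loss on the best few positive anchors
  proto <- fwd$proto
  ph <- dim(proto$value)[1]
  gt_small <- downsample_mask(prep$mask, ph)
  scale <- ph / dim(prep$image)[1]
  bx0 <- max(1L, floor(gt[1] * scale) + 1L); bx1 <- min(ph, ceiling(gt[3] * scale))
  by0 <- max(1L, floor(gt[2] * scale) + 1L); by1 <- min(ph, ceiling(gt[4] * scale))
  wbox <- matrix(0, ph, ph)
  wbox[by0:by1, bx0:bx1] <- 1
  sel_anchors <- pos_rows[order(-iou[pos_rows])][
    seq_len(min(n_mask_anchors, npos))]
  wmask <- array(wbox / (sum(wbox) * length(sel_anchors)), c(ph, ph, 1))
  tmask <- array(gt_small, c(ph, ph, 1))
  offset_tbl <- level_anchor_offsets(fwd)
  for (r in sel_anchors) {
    lv <- findInterval(r - 1L, offset_tbl$start0) # level of this anchor row
    node <- fwd$head[[lv]]$coef
    d <- dim(node$value)
    loc <- r - offset_tbl$start0[lv]
    a_id <- (loc - 1L) %/% (d[1] * d[2]) + 1L
    sp <- (loc - 1L) %% (d[1] * d[2])
    kk <- model$k
    idx <- sp + ((a_id - 1L) * kk + seq_len(kk) - 1L) * d[1] * d[2] + 1L
    coef <- ad_gather(tape, node, idx)
    logits <- ad_proto_combine(tape, proto, coef)
    losses[[length(losses) + 1L]] <- ad_bce_logits(tape, logits, tmask, wmask)
  }

  ad_sum_nodes(tape, losses)
}

level_unflatten <- function(v, d) {
  # inverse of flatten_head for a single level / single channel-per-anchor
  array(v, d)
}

level_anchor_offsets <- function(fwd) {
  counts <- vapply(fwd$head, function(o) {
    d <- dim(o$cls$value); d[1] * d[2] * length(ANCHOR_RATIOS)
  }, numeric(1))
  list(start0 = c(0, cumsum(counts))[seq_along(counts)],
       counts = counts)
}

#' Train the plot-segmentation model
#'
#' Stochastic gradient descent with momentum on the composite loss
#' (anchor classification binary cross-entropy + box regression smooth-L1 +
#' mask binary cross-entropy, weighted 1:1:1).  Defaults mirror the working
#' training recipe (SGD momentum 0.9, learning rate 0.001, batch 8) at desk
#' scale.  Fully deterministic for a fixed seed.
#'
#' @param dataset list of `canopy_scene` objects (or `list(image, polygon)`
#'   pairs); non-empty.  A `NULL` polygon marks a negative (plot-free)
#'   example, which trains only the anchor scores; one or two such
#'   negatives teach the detector to stay quiet on plot-less frames.
#' @param hyper named list overriding `iterations` (default 250),
#'   `lr` (0.001), `momentum` (0.9), `batch_size` (8), `seed` (42),
#'   `profile` (`"desk"`), `prototypes`.
#' @param model optionally continue training an existing model.
#' @return the trained `plot_model` with `$loss_history`.
#' @export
train_plot_model <- function(dataset, hyper = list(), model = NULL) {
  if (length(dataset) == 0L)
    abort("empty training dataset", class = "aircanopy_validation_error")
  h <- utils::modifyList(list(iterations = 250L, lr = 0.001, momentum = 0.9,
                              batch_size = 8L, seed = 42L,
                              profile = "desk", prototypes = NULL), hyper)
  model <- model %||% build_plot_model(h$profile, seed = h$seed,
                                       prototypes = h$prototypes)
  preps <- lapply(dataset, prep_plot_example, input_size = model$input_size)
  layers <- plot_model_layers(model)
  n <- length(preps)
  for (it in seq_len(h$iterations)) {
    batch <- preps[((seq_len(min(h$batch_size, n)) +
                       (it - 1L) * h$batch_size - 1L) %% n) + 1L]
    tot <- 0
    for (prep in batch) {
      fwd <- plot_forward(model, prep$image)
      anchors <- plot_model_anchors(model, fwd$sizes)
      loss <- plot_loss(model, prep, fwd, anchors)
      ad_backward(fwd$tape, loss)
      accumulate_grads(layers)
      tot <- tot + loss$value
    }
    apply_sgd(layers, h$lr, h$momentum, scale = 1 / length(batch))
    model$loss_history <- c(model$loss_history, tot / length(batch))
  }
  model
}

# ---- inference -------------------------------------------------------------

#' Candidate plot segmentations in an image
#'
#' Forward pass, score decoding, Fast NMS and mask assembly; returns every
#' candidate above `score_thresh`.
#'
#' @param image H x W x 3 array.
#' @param model a trained `plot_model`.
#' @param score_thresh minimum detection score.
#' @param nms_iou Fast-NMS IoU threshold.
#' @return list of `plot_segmentation` objects (possibly empty).
#' @export
plot_candidates <- function(image, model, score_thresh = 0.3,
                            nms_iou = 0.5) {
  d <- dim(image)
  fwd <- plot_forward(model, image)
  an <- plot_model_anchors(model, fwd$sizes)
  na <- length(ANCHOR_RATIOS)
  cls <- flatten_head(lapply(fwd$head, function(o) o$cls$value), na, 1L)[, 1]
  box <- flatten_head(lapply(fwd$head, function(o) o$box$value), na, 4L)
  coef <- flatten_head(lapply(fwd$head, function(o) o$coef$value), na, model$k)
  dets <- decode_boxes(an, box, model$input_size)
  dets$score <- 1 / (1 + exp(-cls))
  keep <- dets$score >= score_thresh & (dets$xmax - dets$xmin) > 2 &
    (dets$ymax - dets$ymin) > 2
  if (!any(keep)) return(list())
  dets <- dets[keep, ]
  coef <- coef[keep, , drop = FALSE]
  ord <- order(-dets$score)
  dets <- dets[ord, ]; coef <- coef[ord, , drop = FALSE]
  top <- utils::head(seq_len(nrow(dets)), 200L)
  dets <- dets[top, ]; coef <- coef[top, , drop = FALSE]
  dets$mask_coeffs <- lapply(seq_len(nrow(coef)), function(r) coef[r, ])
  kept <- fast_nms(dets, nms_iou, top_k = 5L)
  lapply(seq_len(nrow(kept)), function(r)
    assemble_mask(fwd$proto$value, kept[r, ], d[1:2]))
}

select_central_segmentation <- function(candidates, image_size) {
  if (!length(candidates)) return(NULL)
  ctr <- c(image_size[2] / 2, image_size[1] / 2)
  stats <- purrr::map_dfr(candidates, function(s) {
    px <- which(s$mask, arr.ind = TRUE)
    if (!nrow(px)) return(tibble(dist = Inf, score = s$score))
    tibble(dist = sqrt((mean(px[, 2]) - ctr[1])^2 +
                       (mean(px[, 1]) - ctr[2])^2),
           score = s$score)
  })
  # nearest centroid; ties by score then lowest index
  ord <- order(round(stats$dist, 6), -stats$score, seq_len(nrow(stats)))
  candidates[[ord[1]]]
}

#' Segment the central plot of an aerial image
#'
#' Among candidate detections at or above `score_thresh`, returns the one
#' whose mask centroid lies nearest the image centre (ties broken by score,
#' then index).  When nothing qualifies the result has `found = FALSE`
#' rather than raising, so batch runs degrade gracefully.
#'
#' @inheritParams plot_candidates
#' @return a `plot_segmentation`; check `$found`.
#' @export
segment_central_plot <- function(image, model, score_thresh = 0.3) {
  cands <- plot_candidates(image, model, score_thresh)
  sel <- select_central_segmentation(cands, dim(image)[1:2])
  if (is.null(sel) || !any(sel$mask))
    return(structure(list(mask = NULL, box = NULL, score = NA_real_,
                          found = FALSE),
                     class = "plot_segmentation"))
  sel
}

#' Save / load a model checkpoint
#'
#' One serialized file containing the weights and the embedded
#' configuration.
#'
#' @param model a `plot_model` or `spike_model`.
#' @param path checkpoint path.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "plot_model")) {
    state <- list(type = "plot", profile = model$profile, cfg = model$cfg,
                  k = model$k, loss_history = model$loss_history,
                  layers = layers_state(plot_model_layers(model)))
  } else {
    state <- list(type = "spike", profile = model$profile, cfg = model$cfg,
                  loss_history = model$loss_history,
                  layers = layers_state(spike_model_layers(model)))
  }
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  if (state$type == "plot") {
    model <- build_plot_model(state$profile, config = state$cfg,
                              prototypes = state$k)
    layers <- plot_model_layers(model)
  } else {
    model <- build_spike_detector(state$profile, config = state$cfg)
    layers <- spike_model_layers(model)
  }
  for (i in seq_along(layers)) {
    layers[[i]]$W <- state$layers[[i]]$W
    layers[[i]]$b <- state$layers[[i]]$b
  }
  model$loss_history <- state$loss_history
  model
}
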