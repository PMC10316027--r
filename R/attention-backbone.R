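# Res2Net-CBAM attention backbone and feature pyramid.
#
# CBAM applies channel then spatial attention to a feature map U:
#   Mc = sigmoid( f2(relu(f1(Zavg))) + f2(relu(f1(Zmax))) ),  F' = Mc * U
# with Zavg/Zmax the global average/max pooled 1x1xC maps and f1: C -> C/r,
# f2: C/r -> C a shared two-layer perceptron;
#   Ms = sigmoid( conv7x7([ZAVG; ZMAX]) ),                    F'' = Ms * F'
# with ZAVG/ZMAX the channel-wise mean/max HxWx1 maps.
#
# The Res2Net block splits its input channels into four equal sub-graphs;
# sub-graph i >= 2 is 3x3-convolved on (own split + previous sub-graph
# output), the four outputs are concatenated and fused by a 1x1
# convolution, CBAM gates the fused map, and a residual connection adds the
# block input.

new_cbam_weights <- function(channels, reduction = 16L, seed = 1L) {
  if (channels %% reduction != 0L)
    abort(sprintf("channels (%d) not divisible by the reduction ratio (%d)",
                  channels, reduction),
          class = "aircanopy_config_error")
  withr::with_seed(seed, list(
    f1 = nn_conv_layer(channels, channels %/% reduction, k = 1L, act = "relu"),
    f2 = nn_conv_layer(channels %/% reduction, channels, k = 1L, act = "linear"),
    f3 = nn_conv_layer(2L, 1L, k = 7L, act = "linear")
  ))
}

cbam_channel_forward <- function(tape, w, u) {
  zavg <- ad_global_avg_pool(tape, u)
  zmax <- ad_global_max_pool(tape, u)
  path <- function(z) layer_forward(tape, w$f2, layer_forward(tape, w$f1, z))
  mc <- ad_sigmoid(tape, ad_add(tape, path(zavg), path(zmax)))
  list(mc = mc, f_prime = ad_mul_channel(tape, u, mc),
       zavg = zavg, zmax = zmax)
}

cbam_spatial_forward <- function(tape, w, f_prime) {
  zavg <- ad_channel_mean(tape, f_prime)
  zmax <- ad_channel_max(tape, f_prime)
  ms <- ad_sigmoid(tape, layer_forward(tape, w$f3,
                                       ad_concat_channels(tape, list(zavg, zmax))))
  list(ms = ms, f_dprime = ad_mul_spatial(tape, f_prime, ms))
}

as_feature_array <- function(u) {
  if (length(dim(u)) != 3L)
    abort("feature map must be an H x W x C array",
          class = "aircanopy_validation_error")
  u
}

#' CBAM channel attention
#'
#' Squeezes the feature map with global average and max pooling, runs both
#' pooled vectors through a shared two-layer perceptron (`C -> C/r -> C`),
#' sums and sigmoid-gates, then rescales every channel of the input.
#'
#' @param u H x W x C feature array.
#' @param reduction bottleneck reduction ratio r; C must be divisible by it.
#' @param weights optional weights from a previous call (for reproducible
#'   reuse); otherwise drawn from `seed`.
#' @param seed integer seed for weight initialization.
#' @return list with `mc` (1 x 1 x C attention weights, all in (0,1)),
#'   `f_prime` (rescaled map), `zavg`, `zmax` (pooled descriptors) and
#'   `weights`.
#' @export
channel_attention <- function(u, reduction = 16L, weights = NULL, seed = 1L) {
  u <- as_feature_array(u)
  w <- weights %||% new_cbam_weights(dim(u)[3], reduction, seed)
  tape <- ad_tape()
  res <- cbam_channel_forward(tape, w, ad_node(tape, u))
  list(mc = res$mc$value, f_prime = res$f_prime$value,
       zavg = res$zavg$value, zmax = res$zmax$value, weights = w)
}

#' CBAM spatial attention
#'
#' Pools the (already channel-gated) map across channels by mean and max,
#' concatenates the two H x W x 1 maps, applies a 7 x 7 convolution with a
#' single output channel and a sigmoid, and rescales every spatial position.
#'
#' @param f_prime H x W x C feature array (at least 1 channel).
#' @inheritParams channel_attention
#' @return list with `ms` (H x W x 1 weights in (0,1)), `f_dprime` and
#'   `weights`.
#' @export
spatial_attention <- function(f_prime, weights = NULL, seed = 1L) {
  f_prime <- as_feature_array(f_prime)
  w <- weights %||% new_cbam_weights(max(dim(f_prime)[3], 16L), 16L, seed)
  tape <- ad_tape()
  res <- cbam_spatial_forward(tape, w, ad_node(tape, f_prime))
  list(ms = res$ms$value, f_dprime = res$f_dprime$value, weights = w)
}

# ---- Res2Net-CBAM block ----------------------------------------------------

new_res2net_block <- function(channels, reduction = 16L, seed = 1L) {
  if (channels %% 4L != 0L)
    abort(sprintf("channels (%d) not divisible by 4", channels),
          class = "aircanopy_config_error")
  q <- channels %/% 4L
  withr::with_seed(seed, list(
    convs = lapply(1:3, function(i) nn_conv_layer(q, q, k = 3L, act = "relu")),
    fuse = nn_conv_layer(channels, channels, k = 1L, act = "linear"),
    cbam = new_cbam_weights(channels, reduction, seed = seed + 1L)
  ))
}

res2net_block_forward <- function(tape, blk, x) {
  ch <- dim(x$value)[3]
  q <- ch %/% 4L
  splits <- lapply(1:4, function(i)
    ad_slice_channels(tape, x, (i - 1L) * q + 1L, i * q))
  ys <- vector("list", 4L)
  ys[[1]] <- splits[[1]]
  for (i in 2:4)
    ys[[i]] <- layer_forward(tape, blk$convs[[i - 1L]],
                             ad_add(tape, splits[[i]], ys[[i - 1L]]))
  fused <- layer_forward(tape, blk$fuse, ad_concat_channels(tape, ys))
  att <- cbam_spatial_forward(tape, blk$cbam,
                              cbam_channel_forward(tape, blk$cbam, fused)$f_prime)
  ad_relu(tape, ad_add(tape, att$f_dprime, x))
}

#' Res2Net block with CBAM attention
#'
#' Splits the input channels into four sub-graphs, hierarchically 3x3
#' convolves sub-graphs 2-4 (each on its own split plus the previous
#' output), fuses the concatenation with a 1x1 convolution, applies CBAM
#' (channel then spatial attention) to the fused map, and adds the block
#' input as a residual.  Spatial size and channel count are preserved.
#'
#' @param x H x W x C array, C divisible by 4 (and by `reduction`).
#' @param weights optional block weights (reused across calls).
#' @inheritParams channel_attention
#' @return list with `out` (H x W x C array) and `weights`.
#' @export
res2net_cbam_block <- function(x, reduction = 16L, weights = NULL, seed = 1L) {
  x <- as_feature_array(x)
  blk <- weights %||% new_res2net_block(dim(x)[3], reduction, seed)
  tape <- ad_tape()
  out <- res2net_block_forward(tape, blk, ad_node(tape, x))
  list(out = out$value, weights = blk)
}

# ---- backbone + feature pyramid -------------------------------------------

#' Configuration of the runnable backbone + FPN
#'
#' The desk profile is a reduced-depth, reduced-width configuration meant
#' for CPU training on small synthetic scenes; strides match the full
#' architecture (C3 at 1/8 input, one halving per stage, P6/P7 by strided
#' convolution from P5).
#'
#' @param input_size input side in px; padded up to a multiple of 32.
#' @param stem_width stem output channels.
#' @param stage_channels C2-C5 channels (divisible by 4 and `reduction`
#'   when attention blocks are used).
#' @param stage_depths residual blocks per stage after the strided
#'   transition.
#' @param block `"res2net_cbam"` or `"bottleneck"` (plain 3x3 residual).
#' @param fpn_width pyramid channel width.
#' @param reduction CBAM reduction.
#' @param seed weight-initialization seed.
#' @export
backbone_config <- function(input_size = 160L, stem_width = 8L,
                            stage_channels = c(16L, 32L, 48L, 64L),
                            stage_depths = c(1L, 1L, 1L, 1L),
                            block = c("res2net_cbam", "bottleneck"),
                            fpn_width = 24L, reduction = 8L, seed = 1L) {
  block <- match.arg(block)
  if (input_size < 32L)
    abort("input_size must be at least 32", class = "aircanopy_config_error")
  list(input_size = as.integer(input_size), stem_width = stem_width,
       stage_channels = stage_channels, stage_depths = stage_depths,
       block = block, fpn_width = fpn_width, reduction = reduction,
       seed = seed)
}

new_plain_block <- function(channels, seed = 1L) {
  withr::with_seed(seed, list(
    conv1 = nn_conv_layer(channels, channels, k = 3L, act = "relu"),
    conv2 = nn_conv_layer(channels, channels, k = 3L, act = "linear")))
}

plain_block_forward <- function(tape, blk, x) {
  y <- layer_forward(tape, blk$conv2, layer_forward(tape, blk$conv1, x))
  ad_relu(tape, ad_add(tape, y, x))
}

#' Build the backbone + feature pyramid network
#'
#' Emits the five backbone maps C1-C5 (spatial size halving per stage) and
#' the five pyramid maps P3-P7 (common channel width; P3-P5 by top-down
#' lateral fusion of C3-C5, P6/P7 by stride-2 convolutions from P5).
#'
#' @param config a [backbone_config()].
#' @return a `backbone_fpn` model; call [backbone_forward()] on an image.
#' @export
build_backbone_fpn <- function(config = backbone_config()) {
  cfg <- config
  ch <- cfg$stage_channels
  fw <- cfg$fpn_width
  withr::with_seed(cfg$seed, {
    stem <- nn_conv_layer(3L, cfg$stem_width, k = 3L, stride = 2L,
                          act = "relu")
    prev <- cfg$stem_width
    stages <- list()
    for (s in 1:4) {
      trans <- nn_conv_layer(prev, ch[s], k = 3L, stride = 2L, act = "relu")
      blocks <- lapply(seq_len(cfg$stage_depths[s]), function(b) {
        sd <- cfg$seed + 100L * s + b
        if (cfg$block == "res2net_cbam" && s >= 2L)
          new_res2net_block(ch[s], cfg$reduction, seed = sd)
        else new_plain_block(ch[s], seed = sd)
      })
      stages[[s]] <- list(trans = trans, blocks = blocks)
      prev <- ch[s]
    }
    lat <- lapply(ch[2:4], function(c) nn_conv_layer(c, fw, k = 1L,
                                                     act = "linear"))
    smooth <- lapply(1:3, function(i) nn_conv_layer(fw, fw, k = 3L,
                                                    act = "linear"))
    p6 <- nn_conv_layer(fw, fw, k = 3L, stride = 2L, act = "linear")
    p7 <- nn_conv_layer(fw, fw, k = 3L, stride = 2L, act = "linear")
  })
  structure(list(cfg = cfg, stem = stem, stages = stages, lat = lat,
                 smooth = smooth, p6 = p6, p7 = p7),
            class = "backbone_fpn")
}

pad_to_input <- function(image, input_size) {
  d <- dim(image)
  side <- 32L * as.integer(ceiling(input_size / 32))
  if (d[1] == side && d[2] == side) return(image)
  out <- array(0, c(side, side, d[3]))
  out[seq_len(min(d[1], side)), seq_len(min(d[2], side)), ] <-
    image[seq_len(min(d[1], side)), seq_len(min(d[2], side)), ]
  out
}

block_forward <- function(tape, blk, x) {
  if (!is.null(blk$convs)) res2net_block_forward(tape, blk, x)
  else plain_block_forward(tape, blk, x)
}

#' Forward pass of the backbone + FPN
#'
#' @param model a `backbone_fpn`.
#' @param image H x W x 3 array (padded to the configured input size).
#' @param tape optional autodiff tape (one is created if missing).
#' @return named list of feature nodes `C1..C5`, `P3..P7` (access values
#'   via `$value`).
#' @export
backbone_forward <- function(model, image, tape = NULL) {
  tape <- tape %||% ad_tape()
  x <- ad_node(tape, pad_to_input(image, model$cfg$input_size))
  c1 <- layer_forward(tape, model$stem, x)
  feats <- list(C1 = c1)
  cur <- c1
  for (s in 1:4) {
    cur <- layer_forward(tape, model$stages[[s]]$trans, cur)
    for (blk in model$stages[[s]]$blocks)
      cur <- block_forward(tape, blk, cur)
    feats[[paste0("C", s + 1L)]] <- cur
  }
  l5 <- layer_forward(tape, model$lat[[3]], feats$C5)
  l4 <- layer_forward(tape, model$lat[[2]], feats$C4)
  l3 <- layer_forward(tape, model$lat[[1]], feats$C3)
  t4 <- ad_add(tape, ad_upsample2(tape, l5), l4)
  t3 <- ad_add(tape, ad_upsample2(tape, t4), l3)
  feats$P3 <- layer_forward(tape, model$smooth[[1]], t3)
  feats$P4 <- layer_forward(tape, model$smooth[[2]], t4)
  feats$P5 <- layer_forward(tape, model$smooth[[3]], l5)
  feats$P6 <- layer_forward(tape, model$p6, feats$P5)
  feats$P7 <- layer_forward(tape, model$p7, feats$P6)
  attr(feats, "tape") <- tape
  feats
}
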