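# Minimal reverse-mode automatic differentiation on dense R arrays.
#
# Feature maps are H x W x C arrays (single image; batching is an outer
# loop).  A tape records every operation; ad_backward() walks it in reverse
# accumulating gradients.  Convolutions are im2col gathers followed by one
# BLAS matrix product, with the gather index cached per (shape, kernel,
# stride, pad) so repeated forward passes are cheap.  This is deliberately
# small: just the operations the segmentation and detection networks need.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  class(t) <- "ad_tape"
  t
}

ad_node <- function(tape, value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- n
  n
}

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ad_backward <- function(tape, loss) {
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  for (i in rev(seq_len(tape$n))) {
    n <- tape$nodes[[i]]
    if (is.null(n$grad) || is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    for (j in seq_along(n$parents))
      if (!is.null(gs[[j]])) ad_accum(n$parents[[j]], gs[[j]])
  }
  invisible(NULL)
}

# ---- elementwise ops -------------------------------------------------------

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b),
          function(g) list(g, g))
}

ad_relu <- function(tape, x) {
  m <- x$value > 0
  ad_node(tape, x$value * m, list(x), function(g) list(g * m))
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(tape, x) {
  s <- tanh(x$value)
  ad_node(tape, s, list(x), function(g) list(g * (1 - s^2)))
}

# x: H x W x C, m: 1 x 1 x C  (per-channel gate)
ad_mul_channel <- function(tape, x, m) {
  d <- dim(x$value)
  mv <- rep(as.vector(m$value), each = d[1] * d[2])
  ad_node(tape, x$value * array(mv, d), list(x, m), function(g) {
    gm <- apply(g * x$value, 3, sum)
    list(g * array(mv, d), array(gm, dim(m$value)))
  })
}

# x: H x W x C, m: H x W x 1  (per-position gate)
ad_mul_spatial <- function(tape, x, m) {
  d <- dim(x$value)
  mv <- array(rep(m$value, d[3]), d)
  ad_node(tape, x$value * mv, list(x, m), function(g) {
    gm <- array(rowSums(matrix(g * x$value, ncol = d[3])), dim(m$value))
    list(g * mv, gm)
  })
}

# ---- pooling / reductions --------------------------------------------------

ad_global_avg_pool <- function(tape, x) {
  d <- dim(x$value)
  np <- d[1] * d[2]
  v <- array(colMeans(matrix(x$value, np, d[3])), c(1, 1, d[3]))
  ad_node(tape, v, list(x), function(g)
    list(array(rep(as.vector(g) / np, each = np), d)))
}

ad_global_max_pool <- function(tape, x) {
  d <- dim(x$value)
  np <- d[1] * d[2]
  xm <- matrix(x$value, np, d[3])
  am <- max.col(t(xm), ties.method = "first")
  v <- array(xm[cbind(am, seq_len(d[3]))], c(1, 1, d[3]))
  ad_node(tape, v, list(x), function(g) {
    gx <- matrix(0, np, d[3])
    gx[cbind(am, seq_len(d[3]))] <- as.vector(g)
    list(array(gx, d))
  })
}

ad_channel_mean <- function(tape, x) {
  d <- dim(x$value)
  v <- array(rowMeans(matrix(x$value, d[1] * d[2], d[3])), c(d[1], d[2], 1))
  ad_node(tape, v, list(x), function(g)
    list(array(rep(g, d[3]) / d[3], d)))
}

ad_channel_max <- function(tape, x) {
  d <- dim(x$value)
  xm <- matrix(x$value, d[1] * d[2], d[3])
  am <- max.col(xm, ties.method = "first")
  v <- array(xm[cbind(seq_len(nrow(xm)), am)], c(d[1], d[2], 1))
  ad_node(tape, v, list(x), function(g) {
    gx <- matrix(0, nrow(xm), d[3])
    gx[cbind(seq_len(nrow(xm)), am)] <- as.vector(g)
    list(array(gx, d))
  })
}

# ---- shape ops -------------------------------------------------------------

ad_concat_channels <- function(tape, xs) {
  vals <- lapply(xs, function(n) n$value)
  d1 <- dim(vals[[1]])
  chs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(unlist(vals), c(d1[1], d1[2], sum(chs)))
  ends <- cumsum(chs); starts <- ends - chs + 1
  ad_node(tape, out, xs, function(g)
    lapply(seq_along(xs), function(i)
      g[, , starts[i]:ends[i], drop = FALSE]))
}

ad_slice_channels <- function(tape, x, from, to) {
  d <- dim(x$value)
  ad_node(tape, x$value[, , from:to, drop = FALSE], list(x), function(g) {
    gx <- array(0, d)
    gx[, , from:to] <- g
    list(gx)
  })
}

ad_upsample2 <- function(tape, x) {
  d <- dim(x$value)
  iy <- rep(seq_len(d[1]), each = 2L); ix <- rep(seq_len(d[2]), each = 2L)
  ad_node(tape, x$value[iy, ix, , drop = FALSE], list(x), function(g) {
    o <- seq(1L, 2L * d[1], by = 2L); p <- seq(1L, 2L * d[2], by = 2L)
    list(g[o, p, , drop = FALSE] + g[o + 1L, p, , drop = FALSE] +
         g[o, p + 1L, , drop = FALSE] + g[o + 1L, p + 1L, , drop = FALSE])
  })
}

# weighted sum of prototype maps: proto H x W x k, coef k-vector node
ad_proto_combine <- function(tape, proto, coef) {
  d <- dim(proto$value)
  pm <- matrix(proto$value, d[1] * d[2], d[3])
  v <- array(pm %*% as.vector(coef$value), c(d[1], d[2], 1))
  ad_node(tape, v, list(proto, coef), function(g) {
    gv <- as.vector(g)
    list(array(outer(gv, as.vector(coef$value)), d),
         array(crossprod(pm, gv), dim(coef$value) %||% d[3]))
  })
}

# gather a vector of entries by linear index (e.g. one anchor's coefficients)
ad_gather <- function(tape, x, idx) {
  d <- dim(x$value)
  ad_node(tape, x$value[idx], list(x), function(g) {
    gx <- array(0, d)
    gx[idx] <- gx[idx] + g
    list(gx)
  })
}

# ---- convolution -----------------------------------------------------------

.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(h, w, k, stride, pad) {
  key <- paste(h, w, k, stride, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  oy <- (seq_len(ho) - 1L) * stride        # top-left corner offsets
  ox <- (seq_len(wo) - 1L) * stride
  base <- outer(oy + 1L, ox * hp, `+`)     # linear index of patch corner
  koff <- outer(seq_len(k) - 1L, (seq_len(k) - 1L) * hp, `+`)
  idx <- outer(as.vector(base), as.vector(koff), `+`)  # [ho*wo, k*k]
  out <- list(idx = idx, ho = ho, wo = wo, hp = hp, wp = wp)
  .im2col_cache[[key]] <- out
  out
}

pad_image <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
  out
}

im2col <- function(x, k, stride, pad) {
  d <- dim(x)
  ii <- im2col_index(d[1], d[2], k, stride, pad)
  xp <- pad_image(x, pad)
  xpm <- matrix(xp, ii$hp * ii$wp, d[3])
  k2 <- k * k
  cols <- matrix(0, nrow(ii$idx), k2 * d[3])
  for (c in seq_len(d[3]))
    cols[, ((c - 1L) * k2 + 1L):(c * k2)] <- xpm[, c][ii$idx]
  list(cols = cols, info = ii)
}

# x: H x W x Cin node; W: k x k x Cin x Cout node; b: Cout node
ad_conv2d <- function(tape, x, W, b = NULL, stride = 1L, pad = NULL) {
  dW <- dim(W$value)
  k <- dW[1]; cin <- dW[3]; cout <- dW[4]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  ic <- im2col(x$value, k, stride, pad)
  Wm <- matrix(W$value, k * k * cin, cout)
  ym <- ic$cols %*% Wm
  if (!is.null(b)) ym <- sweep(ym, 2, as.vector(b$value), `+`)
  out_dim <- c(ic$info$ho, ic$info$wo, cout)
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  d_in <- dim(x$value)
  ad_node(tape, array(ym, out_dim), parents, function(g) {
    gm <- matrix(g, ic$info$ho * ic$info$wo, cout)
    gW <- array(crossprod(ic$cols, gm), dW)
    gcols <- gm %*% t(Wm)
    k2 <- k * k
    gxp <- matrix(0, ic$info$hp * ic$info$wp, cin)
    col_of <- function(kk) kk + k2 * (seq_len(cin) - 1L)
    for (kk in seq_len(k2)) {
      rows <- ic$info$idx[, kk]
      gxp[rows, ] <- gxp[rows, ] + gcols[, col_of(kk), drop = FALSE]
    }
    gx <- array(gxp, c(ic$info$hp, ic$info$wp, cin))
    if (pad > 0L)
      gx <- gx[(pad + 1L):(pad + d_in[1]), (pad + 1L):(pad + d_in[2]), ,
               drop = FALSE]
    out <- list(gx, gW)
    if (!is.null(b)) out[[3]] <- colSums(gm)
    out
  })
}

# ---- losses ----------------------------------------------------------------

# numerically stable binary cross-entropy on logits; `weight` both selects
# and normalizes (grad and loss are sums weighted by it)
ad_bce_logits <- function(tape, z, target, weight = NULL) {
  zv <- z$value
  w <- weight %||% array(1 / length(zv), dim(zv) %||% length(zv))
  l <- pmax(zv, 0) - zv * target + log1p(exp(-abs(zv)))
  ad_node(tape, sum(w * l), list(z), function(g) {
    s <- 1 / (1 + exp(-zv))
    list(g[1] * w * (s - target))
  })
}

ad_smooth_l1 <- function(tape, z, target, weight = NULL) {
  zv <- z$value
  w <- weight %||% array(1 / length(zv), dim(zv) %||% length(zv))
  d <- zv - target
  l <- ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)
  ad_node(tape, sum(w * l), list(z), function(g)
    list(g[1] * w * pmin(pmax(d, -1), 1)))
}

ad_sum_nodes <- function(tape, xs) {
  v <- sum(vapply(xs, function(n) as.numeric(n$value)[1], numeric(1)))
  ad_node(tape, v, xs, function(g) rep(list(g), length(xs)))
}

# ---- layers & optimizer ----------------------------------------------------

nn_conv_layer <- function(cin, cout, k = 3L, stride = 1L, pad = NULL,
                          act = c("relu", "linear", "sigmoid", "tanh")) {
  act <- match.arg(act)
  L <- new.env(parent = emptyenv())
  L$W <- array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
               c(k, k, cin, cout))
  L$b <- numeric(cout)
  L$vW <- array(0, dim(L$W)); L$vb <- numeric(cout)
  L$stride <- as.integer(stride)
  L$pad <- if (is.null(pad)) (k - 1L) %/% 2L else as.integer(pad)
  L$act <- act
  L$spec <- list(k = k, cin = cin, cout = cout)
  class(L) <- "nn_conv_layer"
  L
}

layer_forward <- function(tape, L, x) {
  # reuse this tape's parameter nodes so shared layers (e.g. the CBAM
  # two-layer perceptron applied to both pooling paths) accumulate
  # gradients from every application
  if (!identical(L$tape, tape)) {
    L$Wnode <- ad_node(tape, L$W)
    L$bnode <- ad_node(tape, L$b)
    L$tape <- tape
  }
  Wn <- L$Wnode; bn <- L$bnode
  y <- ad_conv2d(tape, x, Wn, bn, stride = L$stride, pad = L$pad)
  switch(L$act,
         relu = ad_relu(tape, y),
         sigmoid = ad_sigmoid(tape, y),
         tanh = ad_tanh(tape, y),
         y)
}

collect_layers <- function(x) {
  if (inherits(x, "nn_conv_layer")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_layers)))
  list()
}


# batch training: per-image backward passes accumulate into L$gW/L$gb,
# then one momentum update is applied for the whole batch
accumulate_grads <- function(layers) {
  for (L in layers) {
    if (is.null(L$gW)) { L$gW <- array(0, dim(L$W)); L$gb <- numeric(length(L$b)) }
    if (!is.null(L$Wnode) && !is.null(L$Wnode$grad)) {
      L$gW <- L$gW + L$Wnode$grad
      L$gb <- L$gb + L$bnode$grad
    }
    L$Wnode <- NULL; L$bnode <- NULL; L$tape <- NULL
  }
  invisible(NULL)
}

apply_sgd <- function(layers, lr, momentum = 0.9, scale = 1) {
  for (L in layers) {
    if (is.null(L$gW)) next
    L$vW <- momentum * L$vW + L$gW * scale
    L$vb <- momentum * L$vb + L$gb * scale
    L$W <- L$W - lr * L$vW
    L$b <- L$b - lr * L$vb
    L$gW <- NULL; L$gb <- NULL
  }
  invisible(NULL)
}



# serialize layer weights to plain lists (for checkpoints)
layers_state <- function(layers)
  lapply(layers, function(L) list(W = L$W, b = L$b, stride = L$stride,
                                  pad = L$pad, act = L$act, spec = L$spec))

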