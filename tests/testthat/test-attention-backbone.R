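test_that("channel attention has sigmoid-range weights and correct shapes", {
  withr::with_seed(1, u <- array(rnorm(8 * 8 * 32), c(8, 8, 32)))
  res <- channel_attention(u, reduction = 16)
  expect_equal(dim(res$mc), c(1, 1, 32))
  expect_equal(dim(res$f_prime), c(8, 8, 32))
  expect_true(all(res$mc > 0 & res$mc < 1))
  expect_equal(res$f_prime, u * array(rep(res$mc, each = 64), dim(u)),
               tolerance = 1e-12)
  expect_error(channel_attention(u, reduction = 5),
               class = "aircanopy_config_error")
})

test_that("average and max pooling coincide on spatially constant input", {
  v <- seq_len(16) / 16
  u <- array(rep(v, each = 36), c(6, 6, 16))
  res <- channel_attention(u, reduction = 4)
  expect_identical(res$zavg, res$zmax)
})

test_that("spatial attention gates every position with a value in (0,1)", {
  withr::with_seed(2, f <- array(rnorm(8 * 8 * 32), c(8, 8, 32)))
  res <- spatial_attention(f)
  expect_equal(dim(res$ms), c(8, 8, 1))
  expect_equal(dim(res$f_dprime), c(8, 8, 32))
  expect_true(all(res$ms > 0 & res$ms < 1))
  nz <- f != 0
  expect_true(all(abs(res$f_dprime)[nz] < abs(f)[nz]))
})

test_that("CBAM is a contraction in the max norm", {
  for (seed in 1:3) {
    withr::with_seed(seed, u <- array(rnorm(5 * 7 * 16, sd = 3), c(5, 7, 16)))
    ca <- channel_attention(u, reduction = 4, seed = seed)
    sa <- spatial_attention(ca$f_prime, seed = seed)
    expect_lte(max(abs(sa$f_dprime)), max(abs(u)))
  }
})

test_that("Res2Net-CBAM block preserves shape and requires 4-divisible channels", {
  withr::with_seed(3, x <- array(rnorm(16 * 16 * 64), c(16, 16, 64)))
  out <- res2net_cbam_block(x, reduction = 16)
  expect_equal(dim(out$out), dim(x))
  bad <- array(0, c(4, 4, 6))
  expect_error(res2net_cbam_block(bad), class = "aircanopy_config_error")
})

test_that("gradients flow to all four sub-graph convolutions", {
  withr::with_seed(4, x <- array(rnorm(4 * 4 * 8), c(4, 4, 8)))
  blk <- aircanopy:::new_res2net_block(8L, reduction = 4L, seed = 5L)
  run_loss <- function(blk, x) {
    tape <- aircanopy:::ad_tape()
    out <- aircanopy:::res2net_block_forward(tape, blk, aircanopy:::ad_node(tape, x))
    withr::with_seed(9, proj <- array(rnorm(length(out$value)), dim(out$value)))
    list(tape = tape, loss = sum(out$value * proj), out = out, proj = proj)
  }
  r <- run_loss(blk, x)
  # analytic gradient of sum(out * proj)
  loss_node <- aircanopy:::ad_node(r$tape, sum(r$out$value * r$proj),
                                   list(r$out), function(g) list(g[1] * r$proj))
  aircanopy:::ad_backward(r$tape, loss_node)
  grads <- lapply(blk$convs, function(L) L$Wnode$grad)
  fuse_grad <- blk$fuse$Wnode$grad
  eps <- 1e-5
  for (ci in 1:3) {
    L <- blk$convs[[ci]]
    g <- grads[[ci]]
    expect_gt(max(abs(g)), 0)
    # finite-difference check on 3 entries
    for (lin in c(1L, 5L, length(L$W))) {
      W0 <- L$W
      Wp <- W0; Wp[lin] <- Wp[lin] + eps
      L$W <- Wp; lp <- run_loss(blk, x)$loss
      Wm <- W0; Wm[lin] <- Wm[lin] - eps
      L$W <- Wm; lm <- run_loss(blk, x)$loss
      L$W <- W0
      expect_equal(g[lin], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
  expect_gt(max(abs(fuse_grad)), 0)
})

test_that("block output is sensitive to permuting the channel splits", {
  withr::with_seed(6, x <- array(rnorm(6 * 6 * 16), c(6, 6, 16)))
  blk <- aircanopy:::new_res2net_block(16L, reduction = 4L, seed = 7L)
  base <- res2net_cbam_block(x, weights = blk)$out
  xp <- x[, , c(9:16, 1:8)]                  # swap split halves
  perm <- res2net_cbam_block(xp, weights = blk)$out
  unperm <- perm[, , c(9:16, 1:8)]
  expect_gt(max(abs(base - unperm)), 1e-3)
})

test_that("backbone + FPN emits all ten maps with the right stride ladder", {
  cfg <- backbone_config(input_size = 544L, stem_width = 4L,
                         stage_channels = c(8L, 8L, 8L, 8L),
                         stage_depths = c(1L, 1L, 1L, 1L),
                         block = "bottleneck", fpn_width = 8L, seed = 1L)
  net <- build_backbone_fpn(cfg)
  withr::with_seed(1, img <- array(runif(544 * 544 * 3), c(544, 544, 3)))
  feats <- backbone_forward(net, img)
  sizes <- vapply(feats[paste0("P", 3:7)], function(n) dim(n$value)[1],
                  numeric(1))
  expect_equal(unname(sizes), c(68, 34, 17, 9, 5))
  expect_equal(vapply(feats[paste0("C", 1:5)], function(n) dim(n$value)[1],
                      numeric(1)) |> unname(),
               c(272, 136, 68, 34, 17))
  widths <- vapply(feats[paste0("P", 3:7)], function(n) dim(n$value)[3],
                   numeric(1))
  expect_true(all(widths == 8))
})

test_that("swapping block families changes the instantiated parameter total", {
  cfgs <- lapply(c("bottleneck", "res2net_cbam"), function(b)
    backbone_config(input_size = 64L, block = b, reduction = 8L, seed = 1L))
  nets <- lapply(cfgs, build_backbone_fpn)
  totals <- vapply(nets, function(n)
    count_params(model_layer_specs(n)), numeric(1))
  expect_false(totals[1] == totals[2])
})
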