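# Canopy-level spectral and textural traits, computed inside a plot mask.
#
# Spectral indices follow the usual RGB-only (no radiometric calibration)
# formulations on chromatic coordinates r = R/(R+G+B) etc.:
#   ExR  = 1.4 r - g
#   ExG  = 2 g - r - b            (used only inside the coverage threshold)
#   NDYI = (G - B) / (G + B)
#   VARI = (G - R) / (G + R - B), clipped to [-1, 1]
# Ratio denominators are guarded by a small epsilon.

EPS_DENOM <- 1e-6

mask_channels <- function(image, mask) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  mask <- as.logical(mask)
  if (!any(mask))
    abort("mask is empty", class = "aircanopy_validation_error")
  list(r = image[, , 1][mask], g = image[, , 2][mask], b = image[, , 3][mask])
}

#' Spectral vegetation indices over a plot mask
#'
#' Per-pixel ExR, NDYI and VARI averaged over the mask.  All three are
#' ratio-based and therefore invariant to uniform brightness scaling.
#'
#' @param image H x W x 3 array, values in `[0, 1]` (or 0-255; only ratios
#'   are used).
#' @param mask logical H x W matrix, non-empty.
#' @return one-row tibble with `exr`, `ndyi`, `vari`.
#' @export
spectral_indices <- function(image, mask) {
  px <- mask_channels(image, mask)
  s <- px$r + px$g + px$b
  r <- px$r / (s + EPS_DENOM); g <- px$g / (s + EPS_DENOM)
  exr <- 1.4 * r - g
  ndyi <- (px$g - px$b) / (px$g + px$b + EPS_DENOM)
  vari <- (px$g - px$r) / (px$g + px$r - px$b + EPS_DENOM)
  vari <- pmin(pmax(vari, -1), 1)
  tibble(exr = mean(exr), ndyi = mean(ndyi), vari = mean(vari))
}

# Otsu threshold on a numeric vector: maximizes between-class variance over
# a 256-bin histogram.  Returns NA for degenerate (effectively unimodal /
# constant) histograms.
otsu_threshold <- function(x, bins = 256L) {
  rng <- range(x)
  if (diff(rng) < 1e-12) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE), bins)
  p <- cnt / sum(cnt)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  if (max(sb) <= 0) return(NA_real_)
  mids[which.max(sb)]
}

#' Vegetation canopy coverage inside a plot mask
#'
#' Fraction of mask pixels classified as vegetation by thresholding the
#' excess-green index ExG = 2g - r - b with Otsu's method computed over the
#' mask's own ExG histogram.  When the histogram is degenerate (near
#' constant, e.g. a pure canopy) the method falls back to the fixed rule
#' ExG > 0.
#'
#' @inheritParams spectral_indices
#' @param method `"otsu"` (with fallback) or `"fixed"` (ExG > 0 only).
#' @return coverage fraction in `[0, 1]`.
#' @export
canopy_coverage <- function(image, mask, method = c("otsu", "fixed")) {
  method <- match.arg(method)
  px <- mask_channels(image, mask)
  s <- px$r + px$g + px$b
  r <- px$r / (s + EPS_DENOM); g <- px$g / (s + EPS_DENOM)
  b <- px$b / (s + EPS_DENOM)
  exg <- 2 * g - r - b
  thr <- if (method == "otsu") otsu_threshold(exg) else NA_real_
  veg <- if (is.na(thr)) exg > 0 else exg > thr
  mean(veg)
}

#' Grey-level co-occurrence matrix over a mask
#'
#' Counts co-occurring quantized grey-level pairs at each offset (both
#' pixels inside the mask), symmetrizes each count matrix, averages over
#' offsets and normalizes to sum 1.  Greyscale is BT.601 luma; quantization
#' is uniform over `[0, 1]`.
#'
#' @param image H x W x 3 RGB array in `[0, 1]`, or an H x W matrix already
#'   in grey levels `0..levels-1`.
#' @param mask logical H x W matrix (default: all pixels).
#' @param levels number of grey levels G.
#' @param offsets data frame with columns `distance` (px) and `angle`
#'   (degrees, one of 0/45/90/135 or any multiple of 45).
#' @return a `glcm_matrix`: list with `p` (G x G), `levels`, `offsets`.
#' @export
glcm <- function(image, mask = NULL, levels = 32L,
                 offsets = data.frame(distance = 1,
                                      angle = c(0, 45, 90, 135))) {
  if (length(dim(image)) == 3L) {
    gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    q <- pmin(floor(gray * levels), levels - 1L)
  } else {
    q <- image
    if (max(q) > levels - 1L || min(q) < 0)
      abort("grey-level image exceeds the stated quantization range",
            class = "aircanopy_validation_error")
  }
  h <- nrow(q); w <- ncol(q)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  acc <- matrix(0, levels, levels)
  total_pairs <- 0L
  for (k in seq_len(nrow(offsets))) {
    ang <- offsets$angle[k] * pi / 180
    dx <- round(offsets$distance[k] * cos(ang))
    dy <- -round(offsets$distance[k] * sin(ang))   # image rows grow downward
    ys <- seq_len(h); xs <- seq_len(w)
    y2 <- ys + dy; x2 <- xs + dx
    vy <- ys[y2 >= 1 & y2 <= h]; vx <- xs[x2 >= 1 & x2 <= w]
    if (!length(vy) || !length(vx)) next
    m1 <- mask[vy, vx, drop = FALSE] & mask[vy + dy, vx + dx, drop = FALSE]
    if (!any(m1)) next
    a <- q[vy, vx, drop = FALSE][m1]
    b <- q[vy + dy, vx + dx, drop = FALSE][m1]
    cm <- matrix(0, levels, levels)
    tab <- table(factor(a, levels = 0:(levels - 1L)),
                 factor(b, levels = 0:(levels - 1L)))
    cm <- cm + unclass(tab)
    acc <- acc + cm + t(cm)                       # symmetrize
    total_pairs <- total_pairs + sum(cm)
  }
  if (total_pairs < 1L)
    abort("no valid pixel pairs under the mask for any offset",
          class = "aircanopy_validation_error")
  p <- unname(acc / sum(acc))
  dimnames(p) <- NULL
  structure(list(p = p, levels = levels, offsets = offsets),
            class = "glcm_matrix")
}

#' GLCM texture statistics
#'
#' `glcm_asm()` is the angular second moment `sum p(i,j)^2` (1 iff the
#' region is constant); `glcm_dissimilarity()` is `sum p(i,j) |i - j|`
#' (0 iff the GLCM is diagonal).
#'
#' @param g a `glcm_matrix` from [glcm()].
#' @return a scalar.
#' @export
glcm_asm <- function(g) {
  stopifnot(inherits(g, "glcm_matrix"))
  sum(g$p^2)
}

#' @rdname glcm_asm
#' @export
glcm_dissimilarity <- function(g) {
  stopifnot(inherits(g, "glcm_matrix"))
  idx <- seq_len(g$levels) - 1L
  d <- abs(outer(idx, idx, `-`))
  sum(g$p * d)
}

#' All seven plot traits from an image + mask + spike count
#'
#' Convenience wrapper combining [spectral_indices()], [canopy_coverage()],
#' [glcm()] statistics and the SNpM2 density into one trait record.
#'
#' @inheritParams spectral_indices
#' @param spike_count detected spikes in the plot.
#' @param plot_area_m2 plot ground area in square metres.
#' @param plot_id record identifier.
#' @param glcm_levels grey levels for the texture statistics.
#' @return a one-row trait tibble (see [trait_record()]).
#' @export
extract_traits <- function(image, mask, spike_count, plot_area_m2 = 2.25,
                           plot_id = "plot", glcm_levels = 32L) {
  sp <- spectral_indices(image, mask)
  g <- glcm(image, mask, levels = glcm_levels)
  trait_record(plot_id = plot_id,
               snpm2 = snpm2(spike_count, plot_area_m2),
               coverage = canopy_coverage(image, mask),
               exr = sp$exr, ndyi = sp$ndyi, vari = sp$vari,
               asm = glcm_asm(g), glcm_dissimilarity = glcm_dissimilarity(g))
}
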