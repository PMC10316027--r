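# Synthetic overhead canopy scenes with exact ground truth.
#
# Scenes emulate the geometry of a drone image hovering over one field
# plot: a central rectangle of textured green canopy on a brown soil
# background, partial neighbour plots at the image edges, and bright
# ellipse-shaped spikes scattered inside the central plot.  Every spike is
# rendered from its analytic parameters, so the ground-truth boxes and the
# central-plot polygon are exact by construction.

hsv_to_rgb <- function(h, s, v) {
  # h in degrees, s/v in [0,1]; vectorized, returns matrix n x 3
  h <- as.vector(h); s <- as.vector(s); v <- as.vector(v)
  h <- (h %% 360) / 60
  i <- floor(h); f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Parameters of a synthetic aerial canopy scene
#'
#' Defaults describe the desk-scale working conditions used throughout the
#' package: a 160 px square frame whose central 1.5 m x 1.5 m plot spans
#' about 55% of the frame, flanked by partial neighbour plots, with spikes
#' rendered as bright oriented ellipses of roughly 5-9 px major axis.
#'
#' @param image_size `c(H, W)` in px.
#' @param plot_rect `c(cx, cy, w, h, angle_deg)` of the central plot.
#' @param spike_count number of spikes to place, `>= 0`.
#' @param spike_axes `c(major_min, major_max, minor_min, minor_max)` px.
#' @param canopy_hue_range,soil_hue_range HSV hue ranges in degrees.
#' @param illumination_gain multiplicative brightness factor.
#' @param max_overlap maximum pairwise centre-distance overlap fraction
#'   allowed when placing spikes.
#' @param seed integer seed; all randomness in [generate_scene()] flows
#'   from it.
#' @return a `scene_params` list.
#' @export
scene_params <- function(image_size = c(160L, 160L),
                         plot_rect = NULL,
                         spike_count = 60L,
                         spike_axes = c(5, 9, 2.2, 3.6),
                         canopy_hue_range = c(95, 130),
                         soil_hue_range = c(25, 40),
                         illumination_gain = 1,
                         max_overlap = 0.45,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  if (is.null(plot_rect))
    plot_rect <- c(image_size[2] / 2, image_size[1] / 2,
                   0.55 * image_size[2], 0.55 * image_size[1], 0)
  stopifnot(length(image_size) == 2L, all(image_size >= 32L),
            length(plot_rect) == 5L, spike_count >= 0,
            illumination_gain > 0)
  half <- rect_corners(plot_rect)
  if (any(half[, 1] < 0) || any(half[, 1] > image_size[2]) ||
      any(half[, 2] < 0) || any(half[, 2] > image_size[1]))
    abort("plot_rect does not fit inside the image",
          class = "aircanopy_validation_error")
  structure(list(image_size = image_size, plot_rect = plot_rect,
                 spike_count = as.integer(spike_count),
                 spike_axes = spike_axes,
                 canopy_hue_range = canopy_hue_range,
                 soil_hue_range = soil_hue_range,
                 illumination_gain = illumination_gain,
                 max_overlap = max_overlap, seed = as.integer(seed)),
            class = "scene_params")
}

rect_corners <- function(rect) {
  cx <- rect[1]; cy <- rect[2]; hw <- rect[3] / 2; hh <- rect[4] / 2
  a <- rect[5] * pi / 180
  base <- rbind(c(-hw, -hh), c(hw, -hh), c(hw, hh), c(-hw, hh))
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  sweep(base %*% t(rot), 2, c(cx, cy), `+`)
}

# value-noise texture in [0,1], smooth at cell scale `scale`
value_noise <- function(h, w, scale) {
  gh <- max(2L, ceiling(h / scale) + 1L)
  gw <- max(2L, ceiling(w / scale) + 1L)
  g <- matrix(stats::runif(gh * gw), gh, gw)
  ys <- seq(1, gh, length.out = h); xs <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ys), gh - 1L); x0 <- pmin(floor(xs), gw - 1L)
  fy <- ys - y0; fx <- xs - x0
  a <- g[cbind(rep(y0, w), rep(x0, each = h))]
  b <- g[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  cc <- g[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fy <- rep(fy, w); fx <- rep(fx, each = h)
  matrix((a * (1 - fy) + b * fy) * (1 - fx) +
         (cc * (1 - fy) + d * fy) * fx, h, w)
}

point_in_rect <- function(x, y, rect) {
  a <- rect[5] * pi / 180
  dx <- x - rect[1]; dy <- y - rect[2]
  u <- dx * cos(a) + dy * sin(a)
  v <- -dx * sin(a) + dy * cos(a)
  abs(u) <= rect[3] / 2 & abs(v) <= rect[4] / 2
}

#' Generate a synthetic aerial canopy scene
#'
#' Deterministic for a fixed seed; the returned ground truth (central-plot
#' polygon, spike boxes, spike count) is exact by construction.  Spike
#' centres are rejection-sampled inside the plot under a pairwise overlap
#' bound; an unplaceable `spike_count` raises a placement error.
#'
#' @param params a [scene_params()] object.
#' @return a `canopy_scene`: list with `image` (H x W x 3 array in
#'   `[0, 1]`, 8-bit quantized), `plot_polygon` (polygon tibble),
#'   `spike_boxes` (box tibble), `true_count`, `spikes` (analytic spike
#'   parameters) and `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  withr::with_seed(params$seed, generate_scene_impl(params))
}

generate_scene_impl <- function(params) {
  h <- params$image_size[1]; w <- params$image_size[2]
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)   # pixel centres
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)

  # soil background
  soil_hue <- stats::runif(1, params$soil_hue_range[1], params$soil_hue_range[2])
  tex <- value_noise(h, w, 6)
  soil <- hsv_to_rgb(soil_hue + 8 * (tex - 0.5), 0.35 + 0.1 * tex,
                     0.42 + 0.18 * tex)
  img <- array(soil, dim = c(h, w, 3))

  # canopy texture shared by central and neighbour plots
  canopy_hue <- stats::runif(1, params$canopy_hue_range[1],
                             params$canopy_hue_range[2])
  ctex <- value_noise(h, w, 3)
  canopy <- hsv_to_rgb(canopy_hue + 12 * (ctex - 0.5), 0.55 + 0.2 * ctex,
                       0.30 + 0.25 * ctex)

  # partial neighbour plots hugging the frame edges
  rect <- params$plot_rect
  gap <- max(4, 0.06 * min(h, w))
  top_edge <- min(rect_corners(rect)[, 2]); bot_edge <- max(rect_corners(rect)[, 2])
  nb <- rbind(c(rect[1], top_edge - gap - h, rect[3], 2 * h, rect[5]),
              c(rect[1], bot_edge + gap + h, rect[3], 2 * h, rect[5]))
  in_plot <- point_in_rect(xs, ys, rect)
  in_nb <- point_in_rect(xs, ys, nb[1, ]) | point_in_rect(xs, ys, nb[2, ])
  sel <- as.vector(in_plot | in_nb)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sel] <- canopy[, ch][sel]
    img[, , ch] <- plane
  }

  # spikes: oriented bright ellipses with exact analytic ground truth
  n <- params$spike_count
  ax <- params$spike_axes
  spikes <- NULL
  if (n > 0L) {
    inset <- ax[2] + 1
    shrunk <- c(rect[1], rect[2], max(rect[3] - 2 * inset, 1),
                max(rect[4] - 2 * inset, 1), rect[5])
    placed <- matrix(numeric(0), 0, 2)
    out <- vector("list", n)
    min_sep <- (1 - params$max_overlap) * (ax[1] + ax[2]) / 2
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:400) {
        u <- stats::runif(1, -shrunk[3] / 2, shrunk[3] / 2)
        v <- stats::runif(1, -shrunk[4] / 2, shrunk[4] / 2)
        a <- rect[5] * pi / 180
        cx <- rect[1] + u * cos(a) - v * sin(a)
        cy <- rect[2] + u * sin(a) + v * cos(a)
        if (nrow(placed) == 0 ||
            min(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)) >= min_sep) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        abort(sprintf("could not place spike %d of %d under the overlap bound",
                      i, n),
              class = "aircanopy_placement_error")
      placed <- rbind(placed, c(cx, cy))
      out[[i]] <- c(cx = cx, cy = cy,
                    major = stats::runif(1, ax[1], ax[2]),
                    minor = stats::runif(1, ax[3], ax[4]),
                    theta = stats::runif(1, 0, pi))
    }
    spikes <- do.call(rbind, out)

    hue_sp <- stats::runif(n, 55, 80)
    val_sp <- stats::runif(n, 0.82, 0.98)
    col_sp <- hsv_to_rgb(hue_sp, stats::runif(n, 0.45, 0.7), val_sp)
    for (i in seq_len(n)) {
      s <- spikes[i, ]
      half_w <- half_extent(s["major"], s["minor"], s["theta"], axis = "x")
      half_h <- half_extent(s["major"], s["minor"], s["theta"], axis = "y")
      x0 <- max(1L, floor(s["cx"] - half_w)); x1 <- min(w, ceiling(s["cx"] + half_w))
      y0 <- max(1L, floor(s["cy"] - half_h)); y1 <- min(h, ceiling(s["cy"] + half_h))
      sub_x <- xs[y0:y1, x0:x1]; sub_y <- ys[y0:y1, x0:x1]
      dx <- sub_x - s["cx"]; dy <- sub_y - s["cy"]
      u <- dx * cos(s["theta"]) + dy * sin(s["theta"])
      v <- -dx * sin(s["theta"]) + dy * cos(s["theta"])
      inside <- (u / s["major"])^2 + (v / s["minor"])^2 <= 1
      for (ch in 1:3) {
        plane <- img[y0:y1, x0:x1, ch]
        plane[inside] <- col_sp[i, ch]
        img[y0:y1, x0:x1, ch] <- plane
      }
    }
  }

  img <- pmin(pmax(img * params$illumination_gain, 0), 1)
  img <- round(img * 255) / 255                      # 8-bit quantization

  boxes <- if (is.null(spikes) || nrow(spikes) == 0) {
    box_annotation(character(0), character(0), numeric(0), numeric(0),
                   numeric(0), numeric(0))
  } else {
    hw_ <- half_extent(spikes[, "major"], spikes[, "minor"], spikes[, "theta"], "x")
    hh_ <- half_extent(spikes[, "major"], spikes[, "minor"], spikes[, "theta"], "y")
    box_annotation("scene", "spike",
                   pmax(spikes[, "cx"] - hw_, 0), pmax(spikes[, "cy"] - hh_, 0),
                   pmin(spikes[, "cx"] + hw_, w), pmin(spikes[, "cy"] + hh_, h))
  }
  poly <- polygon_annotation("scene", "plot", rect_corners(params$plot_rect))

  structure(list(image = img, plot_polygon = poly, spike_boxes = boxes,
                 true_count = nrow(boxes),
                 spikes = spikes, params = params),
            class = "canopy_scene")
}

# half-extent of a rotated ellipse's axis-aligned bounding box
half_extent <- function(major, minor, theta, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") sqrt((major * cos(theta))^2 + (minor * sin(theta))^2)
  else             sqrt((major * sin(theta))^2 + (minor * cos(theta))^2)
}

#' Rasterize a polygon to a binary mask
#'
#' Even-odd rule at pixel centres; used for ground-truth masks and mask IoU.
#'
#' @param vertices data frame of polygon `x`, `y` (0-based px).
#' @param image_size `c(H, W)`.
#' @return logical H x W matrix.
#' @export
polygon_mask <- function(vertices, image_size) {
  h <- image_size[1]; w <- image_size[2]
  px <- rep(seq_len(w) - 0.5, each = h)
  py <- rep(seq_len(h) - 0.5, times = w)
  n <- nrow(vertices)
  inside <- rep(FALSE, h * w)
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices$x[i]; yi <- vertices$y[i]
    xj <- vertices$x[j]; yj <- vertices$y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  matrix(inside, h, w)
}

# ---- augmentation ----------------------------------------------------------

#' Augment a synthetic scene
#'
#' The four augmentation operators used to enlarge the plot training set:
#' luminance scaling, rotation about the image centre, salt-and-pepper
#' impulse noise, and four-scene mosaic composition.  Annotations are
#' remapped with the image; rotated boxes become the axis-aligned hulls of
#' their rotated corners, and mosaic composition scales four scenes into the
#' quadrants of one canvas, remapping and clipping all annotations.
#'
#' @param scene a `canopy_scene` (for `"mosaic"`: a list of exactly 4).
#' @param op one of `"luminance"`, `"rotation"`, `"salt_pepper"`,
#'   `"mosaic"`.
#' @param op_params named list: `gain` for luminance; `angle` (degrees,
#'   counter-clockwise) for rotation; `fraction` for salt_pepper.
#' @param seed integer seed for the stochastic operators.
#' @return an augmented `canopy_scene`.
#' @export
augment_scene <- function(scene, op, op_params = list(), seed = 1L) {
  switch(op,
    luminance  = augment_luminance(scene, op_params$gain %||% 1.25),
    rotation   = augment_rotation(scene, op_params$angle %||% 15),
    salt_pepper = withr::with_seed(seed,
      augment_salt_pepper(scene, op_params$fraction %||% 0.02)),
    mosaic     = augment_mosaic(scene),
    abort(sprintf("unknown augmentation op '%s'", op),
          class = "aircanopy_argument_error")
  )
}

requantize <- function(img) round(pmin(pmax(img, 0), 1) * 255) / 255

augment_luminance <- function(scene, gain) {
  scene$image <- requantize(scene$image * gain)
  scene
}

augment_salt_pepper <- function(scene, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(scene)
  img <- scene$image
  npx <- prod(dim(img)[1:2])
  hit <- which(stats::runif(npx) < fraction)
  if (length(hit)) {
    val <- stats::rbinom(length(hit), 1L, 0.5)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[hit] <- val
      img[, , ch] <- plane
    }
  }
  scene$image <- img
  scene
}

augment_rotation <- function(scene, angle) {
  if (angle %% 360 == 0) return(scene)
  img <- scene$image
  h <- dim(img)[1]; w <- dim(img)[2]
  a <- angle * pi / 180
  cx <- w / 2; cy <- h / 2
  # inverse map: for each output pixel, sample the source (nearest neighbour)
  px <- rep(seq_len(w) - 0.5, each = h) - cx
  py <- rep(seq_len(h) - 0.5, times = w) - cy
  sx <- cx + px * cos(-a) - py * sin(-a)
  sy <- cy + px * sin(-a) + py * cos(-a)
  ix <- pmin(pmax(ceiling(sx), 1L), w)
  iy <- pmin(pmax(ceiling(sy), 1L), h)
  valid <- sx >= 0 & sx <= w & sy >= 0 & sy <= h
  out <- array(0, dim(img))
  fill <- apply(img, 3, stats::median)
  idx <- (ix - 1L) * h + iy
  for (ch in 1:3) {
    plane <- img[, , ch][idx]
    plane[!valid] <- fill[ch]
    out[, , ch] <- matrix(plane, h, w)
  }
  scene$image <- out

  fwd <- function(x, y) {
    dx <- x - cx; dy <- y - cy
    list(x = cx + dx * cos(a) - dy * sin(a),
         y = cy + dx * sin(a) + dy * cos(a))
  }
  v <- scene$plot_polygon$vertices[[1]]
  rv <- fwd(v$x, v$y)
  scene$plot_polygon$vertices[[1]] <-
    tibble(x = pmin(pmax(rv$x, 0), w), y = pmin(pmax(rv$y, 0), h))
  if (nrow(scene$spike_boxes)) {
    b <- scene$spike_boxes
    cxs <- cbind(b$xmin, b$xmax, b$xmin, b$xmax)
    cys <- cbind(b$ymin, b$ymin, b$ymax, b$ymax)
    rx <- matrix(0, nrow(b), 4); ry <- rx
    for (k in 1:4) {
      rr <- fwd(cxs[, k], cys[, k])
      rx[, k] <- rr$x; ry[, k] <- rr$y
    }
    b$xmin <- pmax(apply(rx, 1, min), 0); b$xmax <- pmin(apply(rx, 1, max), w)
    b$ymin <- pmax(apply(ry, 1, min), 0); b$ymax <- pmin(apply(ry, 1, max), h)
    keep <- b$xmax > b$xmin & b$ymax > b$ymin
    scene$spike_boxes <- b[keep, ]
    scene$true_count <- sum(keep)
  }
  scene
}

augment_mosaic <- function(scenes) {
  if (!is.list(scenes) || length(scenes) != 4L ||
      !all(vapply(scenes, inherits, logical(1), "canopy_scene")))
    abort("mosaic needs exactly 4 canopy scenes",
          class = "aircanopy_argument_error")
  h <- dim(scenes[[1]]$image)[1]; w <- dim(scenes[[1]]$image)[2]
  hh <- h %/% 2L; hw <- w %/% 2L
  canvas <- array(0, c(h, w, 3))
  offs <- list(c(0, 0), c(0, hw), c(hh, 0), c(hh, hw))
  boxes <- list(); polys <- list()
  for (q in 1:4) {
    sc <- scenes[[q]]
    small <- downscale2(sc$image, hh, hw)
    oy <- offs[[q]][1]; ox <- offs[[q]][2]
    canvas[(oy + 1):(oy + hh), (ox + 1):(ox + hw), ] <- small
    fy <- hh / dim(sc$image)[1]; fx <- hw / dim(sc$image)[2]
    if (nrow(sc$spike_boxes)) {
      b <- sc$spike_boxes
      boxes[[q]] <- tibble(image_id = "mosaic", label = b$label,
                           xmin = b$xmin * fx + ox, ymin = b$ymin * fy + oy,
                           xmax = b$xmax * fx + ox, ymax = b$ymax * fy + oy)
    }
    v <- sc$plot_polygon$vertices[[1]]
    polys[[q]] <- tibble(x = v$x * fx + ox, y = v$y * fy + oy)
  }
  all_boxes <- dplyr::bind_rows(boxes)
  out <- scenes[[1]]
  out$image <- requantize(canvas)
  out$spike_boxes <- all_boxes
  out$true_count <- nrow(all_boxes)
  out$plot_polygon <- polygon_annotation("mosaic", "plot", polys[[1]])
  out$mosaic_polygons <- polys
  out
}

downscale2 <- function(img, nh, nw) {
  h <- dim(img)[1]; w <- dim(img)[2]
  yi <- pmin(pmax(ceiling(seq_len(nh) * h / nh - 0.5), 1L), h)
  xi <- pmin(pmax(ceiling(seq_len(nw) * w / nw - 0.5), 1L), w)
  img[yi, xi, , drop = FALSE]
}

#' Write a scene to disk as a PNG + annotation bundle
#'
#' @param scene a `canopy_scene`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the paths written (png, coco json, voc xml).
#' @export
write_scene_bundle <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hw <- dim(scene$image)[1:2]
  png_path <- file.path(dir, paste0(name, ".png"))
  png::writePNG(scene$image, png_path)
  coco_path <- file.path(dir, paste0(name, "_plots.json"))
  poly <- scene$plot_polygon
  poly$image_id <- paste0(name, ".png")
  sizes <- stats::setNames(list(hw), paste0(name, ".png"))
  write_coco_polygons(poly, coco_path, image_sizes = sizes)
  voc_path <- file.path(dir, paste0(name, "_spikes.xml"))
  if (nrow(scene$spike_boxes)) {
    bx <- scene$spike_boxes
    bx$image_id <- paste0(name, ".png")
    write_voc_boxes(bx, voc_path, image_size = hw)
  }
  invisible(c(png = png_path, coco = coco_path, voc = voc_path))
}
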