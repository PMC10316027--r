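# Shared fixtures.  Heavy artefacts (trained desk models) are built once
# per session and cached in this environment so the overfit-recovery,
# pipeline and acceptance tests reuse the same training runs.

.fixture_cache <- new.env(parent = emptyenv())

fixture_scenes <- function() {
  if (is.null(.fixture_cache$scenes))
    .fixture_cache$scenes <- lapply(1:4, function(i) generate_scene(
      scene_params(seed = i, spike_count = 40,
                   plot_rect = c(80 + 8 * (i %% 2), 80 - 6 * (i %/% 3),
                                 88 + 6 * (i %% 2), 92 - 4 * (i %% 2),
                                 c(0, 8, -6, 4)[i]))))
  .fixture_cache$scenes
}

fixture_crops <- function() {
  if (is.null(.fixture_cache$crops))
    .fixture_cache$crops <- lapply(fixture_scenes(), scene_plot_crop)
  .fixture_cache$crops
}

fixture_soil_image <- function(seed = 60) {
  withr::with_seed(seed, {
    soil <- array(0, c(160, 160, 3))
    soil[, , 1] <- 0.45 + 0.04 * matrix(runif(25600), 160)
    soil[, , 2] <- 0.37 + 0.04 * matrix(runif(25600), 160)
    soil[, , 3] <- 0.27 + 0.04 * matrix(runif(25600), 160)
    soil
  })
}

trained_plot_model <- function() {
  if (is.null(.fixture_cache$plot_model))
    .fixture_cache$plot_model <- train_plot_model(
      c(fixture_scenes(),
        list(list(image = fixture_soil_image(61), polygon = NULL))),
      hyper = list(iterations = 180L, lr = 0.003, batch_size = 1L,
                   seed = 42L))
  .fixture_cache$plot_model
}

trained_spike_model <- function() {
  if (is.null(.fixture_cache$spike_model))
    .fixture_cache$spike_model <- train_spike_detector(
      fixture_crops(),
      hyper = list(iterations = 650L, lr = 0.005, seed = 7L))
  .fixture_cache$spike_model
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)

scene_truth_mask <- function(scene)
  polygon_mask(scene$plot_polygon$vertices[[1]], dim(scene$image)[1:2])

# deterministic pseudo-random boxes for matcher properties
random_boxes <- function(n, size = 100, seed = 1) {
  withr::with_seed(seed, {
    x <- runif(n, 0, size - 20); y <- runif(n, 0, size - 20)
    w <- runif(n, 5, 20); h <- runif(n, 5, 20)
    tibble::tibble(xmin = x, ymin = y, xmax = x + w, ymax = y + h)
  })
}
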