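# Three-class yield classification from the seven plot traits with
# gradient-boosted trees (xgboost), grid-search + k-fold CV tuning, and
# gain-based feature importances.

yield_classes <- c("high", "medium", "low")

#' Simulate a plot-trait yield dataset
#'
#' Draws Gaussian class clusters over the seven traits.  Class proportions
#' default to the observed 101 high / 90 medium / 19 low imbalance of a
#' 210-variety trial; by default the signal is carried by SNpM2, NDYI and
#' ASM (class means separated by about 3 within-class standard deviations)
#' while ExR, VARI, coverage and dissimilarity are uninformative noise.
#'
#' @param n total records (class counts are scaled proportionally when `n`
#'   differs from the sum of `class_counts`).
#' @param class_counts named integer vector over `high`, `medium`, `low`.
#' @param class_means 3 x 7 matrix of trait means (rows = classes); defaults
#'   encode realistic trait scales (spike densities 380-520 per m2, NDYI
#'   peaks near 0.68/0.45, ASM descending with yield).
#' @param class_sds 3 x 7 matrix of within-class SDs.
#' @param informative trait names carrying class signal; the others share
#'   one pooled mean across classes.
#' @param seed integer seed.
#' @return a `yield_dataset`: list with `features` tibble (n x 7),
#'   `labels` factor, `ids`.
#' @export
simulate_yield_dataset <- function(n = 210L,
                                   class_counts = c(high = 101L, medium = 90L,
                                                    low = 19L),
                                   class_means = NULL, class_sds = NULL,
                                   informative = c("snpm2", "ndyi", "asm"),
                                   seed = 1L) {
  traits <- trait_columns
  if (is.null(class_means)) {
    class_means <- rbind(
      high   = c(snpm2 = 520, coverage = 0.88, exr = 0.06, ndyi = 0.68,
                 vari = 0.32, asm = 0.24, glcm_dissimilarity = 1.8),
      medium = c(snpm2 = 450, coverage = 0.88, exr = 0.06, ndyi = 0.56,
                 vari = 0.32, asm = 0.20, glcm_dissimilarity = 1.8),
      low    = c(snpm2 = 380, coverage = 0.88, exr = 0.06, ndyi = 0.45,
                 vari = 0.32, asm = 0.16, glcm_dissimilarity = 1.8))
    colnames(class_means) <- traits
  }
  if (is.null(class_sds)) {
    class_sds <- matrix(rep(c(snpm2 = 22, coverage = 0.04, exr = 0.02,
                              ndyi = 0.035, vari = 0.05, asm = 0.013,
                              glcm_dissimilarity = 0.3), each = 3), 3,
                        dimnames = list(yield_classes, traits))
  }
  keep_noise <- setdiff(traits, informative)
  class_means[, keep_noise] <- rep(colMeans(class_means[, keep_noise,
                                                        drop = FALSE]),
                                   each = 3)
  counts <- round(class_counts / sum(class_counts) * n)
  counts[1] <- n - sum(counts[-1])
  withr::with_seed(seed, {
    rows <- purrr::map2(yield_classes, counts, function(cl, k) {
      if (k <= 0) return(NULL)
      vals <- purrr::map2(class_means[cl, traits], class_sds[cl, traits],
                          function(m, s) stats::rnorm(k, m, s))
      df <- as_tibble(vals)
      df$coverage <- pmin(pmax(df$coverage, 0), 1)
      df$asm <- pmin(pmax(df$asm, 1e-3), 1)
      df$snpm2 <- pmax(df$snpm2, 0)
      df$glcm_dissimilarity <- pmax(df$glcm_dissimilarity, 0)
      df$.label <- cl
      df
    })
    df <- dplyr::bind_rows(rows)
    df <- df[sample.int(nrow(df)), ]
  })
  structure(list(features = df[, traits],
                 labels = factor(df$.label, levels = yield_classes),
                 ids = sprintf("variety_%03d", seq_len(nrow(df)))),
            class = "yield_dataset")
}

#' Assemble a yield dataset from a trait table and labels
#'
#' @param traits tibble containing the seven trait columns.
#' @param labels vector of `high`/`medium`/`low` labels.
#' @param ids optional identifiers.
#' @return a `yield_dataset`.
#' @export
yield_dataset <- function(traits, labels, ids = NULL) {
  missing <- setdiff(trait_columns, names(traits))
  if (length(missing))
    abort(paste("missing trait columns:", paste(missing, collapse = ", ")),
          class = "aircanopy_validation_error")
  feats <- traits[, trait_columns]
  if (anyNA(feats))
    abort("missing values in trait features", class = "aircanopy_validation_error")
  labels <- factor(as.character(labels), levels = yield_classes)
  if (anyNA(labels))
    abort("labels outside {high, medium, low}",
          class = "aircanopy_validation_error")
  structure(list(features = feats, labels = labels,
                 ids = ids %||% sprintf("record_%03d", seq_len(nrow(feats)))),
            class = "yield_dataset")
}

subset_yield <- function(ds, idx) {
  structure(list(features = ds$features[idx, ], labels = ds$labels[idx],
                 ids = ds$ids[idx]), class = "yield_dataset")
}

#' Stratified train/test split
#'
#' Training size is exactly `round(n * train_frac)`; records are allocated
#' per class proportionally (largest-remainder rounding) so the split is
#' stratified whenever every class is large enough, disjoint and exhaustive,
#' and deterministic per seed.  A class absent from either side raises a
#' warning flag attribute.
#'
#' @param ds a `yield_dataset`.
#' @param train_frac fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` datasets and `train_idx`.
#' @export
split_dataset <- function(ds, train_frac = 0.7, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  n <- nrow(ds$features)
  n_train <- round(n * train_frac)
  cls_idx <- split(seq_len(n), ds$labels)
  sizes <- vapply(cls_idx, length, integer(1))
  quota <- sizes * n_train / n
  take <- floor(quota)
  rem <- n_train - sum(take)
  if (rem > 0) {
    ord <- order(-(quota - take))
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  train_idx <- withr::with_seed(seed,
    unlist(purrr::map2(cls_idx, take, function(ix, k)
      if (k > 0) sample(ix, min(k, length(ix))) else integer(0))))
  train_idx <- sort(unname(train_idx))
  test_idx <- setdiff(seq_len(n), train_idx)
  out <- list(train = subset_yield(ds, train_idx),
              test = subset_yield(ds, test_idx), train_idx = train_idx)
  missing_class <- any(table(out$train$labels) == 0) ||
    any(table(out$test$labels) == 0)
  attr(out, "stratification_warning") <- missing_class
  if (missing_class)
    warn("a yield class is absent from one side of the split")
  out
}

#' Default hyperparameter grid
#'
#' Axes follow the tuned quantities of gradient boosting: number of trees,
#' tree depth, learning rate, row subsampling and feature subsampling.
#'
#' @export
yield_default_grid <- function() {
  list(nrounds = c(100, 300, 500), max_depth = c(3, 5, 7),
       eta = c(0.05, 0.1, 0.3), subsample = c(0.7, 1),
       colsample_bytree = c(0.7, 1))
}

fit_xgb <- function(features, labels, par, seed = 1L) {
  y <- as.integer(labels) - 1L
  x <- as.matrix(features)
  withr::with_seed(seed, {
    xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(yield_classes),
                    max_depth = par$max_depth, eta = par$eta,
                    subsample = par$subsample,
                    colsample_bytree = par$colsample_bytree,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = par$nrounds, verbose = 0)
  })
}

xgb_probs <- function(booster, features) {
  p <- stats::predict(booster, as.matrix(features))
  p <- matrix(as.numeric(p), nrow = nrow(features),
              ncol = length(yield_classes))
  dimnames(p) <- list(NULL, yield_classes)
  p
}

#' Grid search with k-fold cross-validation
#'
#' Evaluates the full Cartesian product of the grid by stratified k-fold CV
#' accuracy, then refits the best configuration (ties broken by grid order)
#' on all of the training data.
#'
#' @param train a `yield_dataset`.
#' @param grid named list of axis values (see [yield_default_grid()]).
#' @param k folds, `>= 2` and at most the smallest class count.
#' @param seed integer seed controlling folds and fits.
#' @return a `yield_model`: list with `booster`, `best_params`, `cv_score`,
#'   `cv_results` tibble, `importances` (named 7-vector summing to 1).
#' @export
grid_search_cv <- function(train, grid = yield_default_grid(), k = 5L,
                           seed = 1L) {
  stopifnot(k >= 2L)
  if (any(lengths(grid) == 0))
    abort("every grid axis must be non-empty", class = "aircanopy_argument_error")
  smallest <- min(table(droplevels(train$labels)))
  if (k > smallest)
    abort(sprintf("k = %d exceeds the smallest class count (%d)", k, smallest),
          class = "aircanopy_argument_error")
  n <- nrow(train$features)
  folds <- withr::with_seed(seed, {
    f <- integer(n)
    for (ix in split(seq_len(n), train$labels))
      f[ix] <- sample(rep_len(seq_len(k), length(ix)))
    f
  })
  configs <- do.call(tidyr::expand_grid, grid)     # grid order preserved
  acc <- purrr::map_dbl(seq_len(nrow(configs)), function(i) {
    par <- as.list(configs[i, ])
    mean(purrr::map_dbl(seq_len(k), function(fold) {
      tr <- folds != fold
      booster <- fit_xgb(train$features[tr, ], train$labels[tr], par,
                         seed = seed + fold)
      pr <- xgb_probs(booster, train$features[!tr, ])
      mean(yield_classes[max.col(pr, ties.method = "first")] ==
             as.character(train$labels[!tr]))
    }))
  })
  best <- which.max(acc)                            # first max = grid order
  best_par <- as.list(configs[best, ])
  booster <- fit_xgb(train$features, train$labels, best_par, seed = seed)
  structure(list(booster = booster, best_params = best_par,
                 cv_score = acc[best],
                 cv_results = dplyr::mutate(configs, cv_accuracy = acc),
                 importances = yield_importances(booster),
                 trait_names = trait_columns, n_train = n, seed = seed),
            class = "yield_model")
}

yield_importances <- function(booster) {
  imp <- xgboost::xgb.importance(model = booster)
  v <- stats::setNames(rep(0, length(trait_columns)), trait_columns)
  v[imp$Feature] <- imp$Gain
  if (sum(v) > 0) v <- v / sum(v)
  v
}

#' Classify yield groups from trait features
#'
#' @param model a `yield_model` from [grid_search_cv()].
#' @param features tibble/matrix with the seven trait columns.
#' @return tibble with `.pred_class` and one probability column per class
#'   (rows sum to 1).
#' @export
classify_yield <- function(model, features) {
  stopifnot(inherits(model, "yield_model"))
  if (is.data.frame(features)) {
    missing <- setdiff(model$trait_names, names(features))
    if (length(missing))
      abort(paste("missing trait columns:", paste(missing, collapse = ", ")),
            class = "aircanopy_validation_error")
    features <- features[, model$trait_names]
  }
  if (ncol(features) != length(model$trait_names))
    abort("feature matrix must have exactly 7 trait columns",
          class = "aircanopy_validation_error")
  pr <- xgb_probs(model$booster, features)
  out <- as_tibble(pr)
  out$.pred_class <- factor(yield_classes[max.col(pr, ties.method = "first")],
                            levels = yield_classes)
  out[, c(".pred_class", yield_classes)]
}

#' Normalized gain-based feature importances
#'
#' @param model a `yield_model`.
#' @return tibble with `trait` and `importance` (sums to 1).
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "yield_model"))
  tibble(trait = names(model$importances),
         importance = unname(model$importances))
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a fitted yield model
#'
#' `tidy()` returns per-trait importances; `glance()` returns a one-row
#' model summary (best hyperparameters, CV accuracy).
#'
#' @param x a `yield_model`.
#' @param ... unused.
#' @method tidy yield_model
#' @export
tidy.yield_model <- function(x, ...) feature_importance(x)

#' @rdname tidy.yield_model
#' @method glance yield_model
#' @export
glance.yield_model <- function(x, ...) {
  dplyr::bind_cols(tibble(cv_accuracy = x$cv_score, n_train = x$n_train),
                   as_tibble(x$best_params))
}
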