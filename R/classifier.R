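# Threshold-based training-pixel extraction, row-subsampled random forest
# with OOB-driven hyperparameter tuning, and pixelwise image classification.

CLASS_LEVELS <- c("TWP", "tissue_paraffin")

#' Percentile threshold of an elemental map
#'
#' The labeling rule `threshold = factor * P(percentile)` with the
#' percentile computed over all pixel values of the image by linear
#' interpolation between closest ranks (R quantile type 7). The mask marks
#' pixels strictly exceeding the threshold.
#'
#' @param map Numeric matrix (or vector) of pixel values.
#' @param percentile Percentile in (0, 100]; default 95.
#' @param factor Multiplier; default 0.75.
#' @return List with `threshold` (scalar) and `mask` (logical, same shape
#'   as `map`).
#' @export
percentile_threshold <- function(map, percentile = 95, factor = 0.75) {
  v <- as.vector(map)
  if (length(v) == 0 || !all(is.finite(v))) {
    stop_twp("map must be non-empty and finite", "twpscan_empty_map")
  }
  thr <- factor * unname(quantile(v, percentile / 100, type = 7))
  mask <- map > thr
  list(threshold = thr, mask = mask)
}

#' Extract the labeled training-pixel set
#'
#' Class 1 (TWP): a uniform sample without replacement of `n_per_class`
#' pixels of the TWP-in-paraffin image whose Zn signal exceeds
#' `0.75 * P95(Zn)` of that image. Class 2 (tissue and paraffin): a uniform
#' sample of all pixels of the blank-gut image. Features are the six marker
#' maps; standardization is fitted once on the pooled set and frozen.
#'
#' @param twp_image Normalized `elemental_image` of a TWP-in-paraffin scene.
#' @param blank_image Normalized `elemental_image` of a blank-gut scene.
#' @param n_per_class Pixels per class (default 4000).
#' @param seed Integer seed for the pixel draws.
#' @param percentile,factor Threshold rule parameters.
#' @return A `labeled_pixel_set` tibble: `class`, `source`, `line`, `pixel`,
#'   raw marker columns `raw_<isotope>` and standardized marker columns.
#'   Attributes: `std_params` (frozen standardization),
#'   `zn_threshold`.
#' @export
extract_training_pixels <- function(twp_image, blank_image,
                                    n_per_class = 4000L, seed = 1L,
                                    percentile = 95, factor = 0.75) {
  zn <- percentile_threshold(twp_image$data[["Zn64"]], percentile, factor)
  twp_feat <- image_features(twp_image)
  blank_feat <- image_features(blank_image)
  eligible <- which(as.vector(zn$mask))
  if (length(eligible) < n_per_class) {
    stop_twp(paste0("only ", length(eligible),
                    " pixels above the Zn threshold; need ", n_per_class,
                    " (scene too sparse)"), "twpscan_sparse")
  }
  if (nrow(blank_feat) < n_per_class) {
    stop_twp("blank image has fewer pixels than n_per_class", "twpscan_sparse")
  }
  sel <- with_seed(seed, list(
    twp = sample(eligible, n_per_class),
    blank = sample(nrow(blank_feat), n_per_class)))
  cls1 <- twp_feat[sel$twp, ]
  cls2 <- blank_feat[sel$blank, ]
  raw <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(class = factor("TWP", levels = CLASS_LEVELS),
                            source = "twp_in_paraffin"), cls1),
    dplyr::bind_cols(tibble(class = factor("tissue_paraffin",
                                           levels = CLASS_LEVELS),
                            source = "blank_gut"), cls2))
  params <- fit_standardization(raw, features = marker_isotopes())
  std <- apply_standardization(raw, params)
  for (k in marker_isotopes()) std[[paste0("raw_", k)]] <- raw[[k]]
  structure(std, class = c("labeled_pixel_set", class(tibble())),
            std_params = params, zn_threshold = zn$threshold)
}

#' Random-forest configuration
#'
#' The forest's only sources of randomness are the per-tree row subsamples:
#' each tree is grown on `round(r_value * n)` training rows drawn uniformly
#' (without replacement by default, the natural reading of an "R-value"
#' fraction of the training set; set `replace = TRUE` for bootstrap draws),
#' with all six features available at every split (Gini criterion,
#' unbounded depth). The study's optimized values, 65 trees and
#' r = 0.58, are the defaults.
#'
#' @param n_trees Number of trees.
#' @param r_value Fraction of the training set per tree, in (0, 1].
#' @param seed Integer seed.
#' @param n_repeats Seed repeats used when averaging OOB errors (default 5).
#' @param replace Draw per-tree rows with replacement.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 65L, r_value = 0.58, seed = 1L,
                      n_repeats = 5L, replace = FALSE) {
  stopifnot(n_trees >= 1, r_value > 0, r_value <= 1)
  structure(list(n_trees = as.integer(n_trees), r_value = r_value,
                 seed = as.integer(seed), n_repeats = as.integer(n_repeats),
                 replace = replace),
            class = "rf_config")
}

pixel_set_xy <- function(pixel_set) {
  list(x = as.data.frame(pixel_set[, marker_isotopes()]),
       y = pixel_set$class)
}

#' Fit the pixelwise random-forest classifier
#'
#' @param pixel_set A [extract_training_pixels()] result (standardized
#'   features).
#' @param config An [rf_config()].
#' @return A `twp_classifier`: the fitted forest, the config, the frozen
#'   standardization parameters and Zn threshold, and per-class plus
#'   balanced out-of-bag (OOB) error estimates.
#' @export
fit_forest <- function(pixel_set, config = rf_config()) {
  xy <- pixel_set_xy(pixel_set)
  n <- nrow(xy$x)
  size <- round(config$r_value * n)
  if (size < 2L) {
    stop_twp("r_value so small that trees receive < 2 rows", "twpscan_rvalue")
  }
  rf <- with_seed(config$seed,
    randomForest::randomForest(
      x = xy$x, y = xy$y, ntree = config$n_trees,
      mtry = ncol(xy$x), replace = config$replace, sampsize = size,
      keep.forest = TRUE))
  per_class <- rf$confusion[CLASS_LEVELS, "class.error"]
  structure(list(forest = rf, config = config,
                 std_params = attr(pixel_set, "std_params"),
                 zn_threshold = attr(pixel_set, "zn_threshold"),
                 oob_per_class = per_class,
                 oob_balanced = mean(per_class),
                 n_features = ncol(xy$x), n_training = n),
            class = "twp_classifier")
}

#' @export
print.twp_classifier <- function(x, ...) {
  cat("<twp_classifier>", x$config$n_trees, "trees, r =", x$config$r_value,
      ";", x$n_training, "training pixels,", x$n_features, "features\n")
  cat("  balanced OOB error:", signif(x$oob_balanced, 4), "\n")
  invisible(x)
}

#' @export
tidy.twp_classifier <- function(x, ...) {
  tibble(class = names(x$oob_per_class),
         oob_error = unname(x$oob_per_class))
}

#' @export
glance.twp_classifier <- function(x, ...) {
  tibble(n_trees = x$config$n_trees, r_value = x$config$r_value,
         n_features = x$n_features, n_training = x$n_training,
         oob_balanced = x$oob_balanced)
}

# Balanced OOB error (mean of the two class error rates) after the first
# `t` trees, for every t in n_trees_grid, from one fitted forest's
# cumulative err.rate.
oob_curve <- function(pixel_set, r_value, max_trees, seed, replace = FALSE) {
  xy <- pixel_set_xy(pixel_set)
  size <- round(r_value * nrow(xy$x))
  rf <- with_seed(seed,
    randomForest::randomForest(
      x = xy$x, y = xy$y, ntree = max_trees,
      mtry = ncol(xy$x), replace = replace, sampsize = size,
      keep.forest = FALSE))
  (rf$err.rate[, CLASS_LEVELS[1]] + rf$err.rate[, CLASS_LEVELS[2]]) / 2
}

#' Optimize forest hyperparameters by averaged OOB error
#'
#' For every grid point (n_trees, r_value) the balanced OOB error is
#' averaged over `n_repeats` random seeds; the argmin is returned (ties
#' broken toward smaller n_trees, then smaller r_value) together with the
#' full error surface. The OOB error at t trees is read from the cumulative
#' error trace of a single forest of `max(n_trees)` trees per (r_value,
#' repeat), which is both exact and far cheaper than refitting per grid
#' point.
#'
#' @param pixel_set A [extract_training_pixels()] result.
#' @param n_trees_grid,r_value_grid Grid (defaults 5,10,...,200 and
#'   0.10, 0.14, ..., 0.90).
#' @param n_repeats Seed repeats (default 5).
#' @param seed Base seed from which repeat seeds are derived.
#' @param replace Per-tree sampling with replacement.
#' @return An `rf_opt` object: `best_n_trees`, `best_r_value`, `surface`
#'   (tibble n_trees x r_value with averaged `oob_error`).
#' @export
optimize_hyperparameters <- function(pixel_set,
                                     n_trees_grid = seq(5L, 200L, by = 5L),
                                     r_value_grid = seq(0.10, 0.90, by = 0.04),
                                     n_repeats = 5L, seed = 1L,
                                     replace = FALSE) {
  stopifnot(length(n_trees_grid) > 0, length(r_value_grid) > 0)
  max_trees <- max(n_trees_grid)
  surface <- purrr::map_dfr(seq_along(r_value_grid), function(ri) {
    r <- r_value_grid[ri]
    curves <- vapply(seq_len(n_repeats), function(rep) {
      oob_curve(pixel_set, r, max_trees,
                seed = child_seed(seed, ri * 1000L + rep),
                replace = replace)
    }, numeric(max_trees))
    avg <- rowMeans(curves)
    tibble(n_trees = as.integer(n_trees_grid), r_value = r,
           oob_error = avg[n_trees_grid])
  })
  ord <- order(surface$oob_error, surface$n_trees, surface$r_value)
  best <- surface[ord[1], ]
  structure(list(best_n_trees = best$n_trees, best_r_value = best$r_value,
                 surface = surface),
            class = "rf_opt")
}

#' @export
print.rf_opt <- function(x, ...) {
  cat("<rf_opt> best: n_trees =", x$best_n_trees, ", r_value =",
      x$best_r_value, "; min averaged OOB error =",
      signif(min(x$surface$oob_error), 4), "\n")
  invisible(x)
}

#' Classify every pixel of an elemental image
#'
#' Applies the frozen standardization, then the majority vote of the
#' forest's trees per pixel. Tied votes are assigned to class 2 (tissue and
#' paraffin): the workflow prioritizes avoiding false positives.
#'
#' @param classifier A [fit_forest()] result.
#' @param image Normalized `elemental_image` with all six marker maps.
#' @return Logical matrix, TRUE where a pixel is classified as TWP.
#' @export
classify_image <- function(classifier, image) {
  feat <- image_features(image)
  d <- dim(image$data[[1]])
  std <- apply_standardization(feat, classifier$std_params)
  votes <- predict(classifier$forest,
                   newdata = as.data.frame(std[, marker_isotopes()]),
                   type = "vote", norm.votes = TRUE)
  pred <- votes[, "TWP"] > 0.5          # strict: ties go to class 2
  matrix(pred, d[1], d[2])
}

#' Single-element Zn threshold classifier
#'
#' The univariate baseline: a pixel is called TWP when its Zn signal
#' exceeds the Zn training threshold (`0.75 * P95` of the training
#' TWP-in-paraffin image). Used to demonstrate that no single marker
#' element separates TWPs from gut tissue.
#'
#' @param classifier A [fit_forest()] result (supplies the stored
#'   threshold).
#' @param image Normalized `elemental_image`.
#' @return Logical matrix.
#' @export
classify_zn_threshold <- function(classifier, image) {
  image$data[["Zn64"]] > classifier$zn_threshold
}

#' Confusion counts of two masks
#'
#' @param predicted,truth Logical masks of identical shape.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)) ||
      length(predicted) != length(truth)) {
    stop_twp("mask shapes differ", "twpscan_shape")
  }
  p <- as.vector(predicted); t <- as.vector(truth)
  tibble(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
         tn = sum(!p & !t))
}
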