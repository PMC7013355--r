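#' Target registration error
#'
#' Mean Euclidean distance between corresponding target points,
#' `TRE = (1/n) sum_i ||b_i - a_i||`; `method = "rms"` gives the
#' root-mean-square variant used by part of the literature.
#'
#' @param targets_ref n x 3 matrix (or data frame) of reference positions, mm.
#' @param targets_reg n x 3 matrix of registered positions, mm.
#' @param method `"mean"` (default) or `"rms"`.
#' @return TRE in mm.
#' @export
target_registration_error <- function(targets_ref, targets_reg,
                                      method = c("mean", "rms")) {
  method <- match.arg(method)
  a <- as_point_matrix(targets_ref)
  b <- as_point_matrix(targets_reg)
  if (nrow(a) != nrow(b) || nrow(a) < 1L) {
    abort("target sets must have equal, nonzero counts",
          class = "plcpd_dimension_error")
  }
  d <- sqrt(rowSums((a - b)^2))
  if (method == "mean") mean(d) else sqrt(mean(d^2))
}

#' Root-mean-square difference of parameter triplets
#'
#' `RMS = sqrt((1/3) sum_k (b_k - a_k)^2)`, applied to translation triplets
#' (mm) or Euler-angle triplets (degrees).
#'
#' @param ref_triplet,est_triplet Length-3 numeric vectors.
#' @return RMS difference in the input units.
#' @examples
#' rms_difference(c(0, 0, 0), c(1, 2, 2)) # sqrt(3)
#' @export
rms_difference <- function(ref_triplet, est_triplet) {
  if (length(ref_triplet) != 3L || length(est_triplet) != 3L) {
    abort("triplets must have 3 components", class = "plcpd_dimension_error")
  }
  sqrt(mean((as.numeric(est_triplet) - as.numeric(ref_triplet))^2))
}

#' Dice overlap coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks have Dice 1 by
#' convention.
#'
#' @param a,b Binary masks: logical arrays, +1/-1 label volumes, or
#'   [us_volume()] objects on the same grid.
#' @return Dice fraction in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  ma <- mask_array(a)
  mb <- mask_array(b)
  if (!identical(dim(ma), dim(mb))) {
    abort("masks are on different grids", class = "plcpd_dimension_error")
  }
  na <- sum(ma)
  nb <- sum(mb)
  if (na + nb == 0L) return(1)
  2 * sum(ma & mb) / (na + nb)
}

#' Hausdorff surface distance
#'
#' Maximum (or, via `percentile`, a quantile) of the two directed
#' surface-to-nearest-surface distances between the boundary voxels of two
#' masks, in mm. Surfaces are the masks minus their 6-neighbor erosions.
#'
#' @param a,b Binary masks as in [dice_coefficient()]; both nonempty.
#' @param spacing Voxel spacing in mm; taken from the volumes when they carry
#'   it, otherwise 1.
#' @param percentile Quantile of the directed distances (default 1 = max;
#'   0.95 gives the robust variant).
#' @return Distance in mm.
#' @export
hausdorff_surface_distance <- function(a, b, spacing = NULL, percentile = 1) {
  sp <- spacing %||% (if (inherits(a, "us_volume")) a$spacing else c(1, 1, 1))
  sp <- rep_len(as.numeric(sp), 3L)
  ma <- mask_array(a)
  mb <- mask_array(b)
  if (!identical(dim(ma), dim(mb))) {
    abort("masks are on different grids", class = "plcpd_dimension_error")
  }
  if (!any(ma) || !any(mb)) {
    abort("surface distance undefined for an empty mask",
          class = "plcpd_metric_undefined_error")
  }
  surf <- function(m) {
    bd <- m & !erode6(m)
    sweep(which(bd, arr.ind = TRUE) - 1, 2, sp, `*`)
  }
  sa <- surf(ma)
  sb <- surf(mb)
  dir_ab <- nearest_dist_cpp(sa, sb)
  dir_ba <- nearest_dist_cpp(sb, sa)
  if (percentile >= 1) {
    max(max(dir_ab), max(dir_ba))
  } else {
    max(quantile(dir_ab, percentile, names = FALSE),
        quantile(dir_ba, percentile, names = FALSE))
  }
}

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, ties
#' counting one half; equal to the trapezoidal area under the ROC curve.
#' Computed with pROC (direction and levels pinned, so reversed scores give
#' 0, not an auto-flipped 1).
#'
#' @param scores Numeric scores (e.g. classifier posteriors).
#' @param labels Binary labels: logical, or +1/-1.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- label_vector(labels)
  if (length(unique(y)) < 2L) {
    abort("AUC undefined: both classes must be present",
          class = "plcpd_metric_undefined_error")
  }
  r <- pROC::roc(response = factor(y, levels = c(-1, 1)),
                 predictor = as.numeric(scores),
                 levels = c("-1", "1"), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Axis-aligned bounding box of a mask, in mm
#'
#' @param mask A `label_volume`, logical array or [us_volume()].
#' @param spacing,origin Grid metadata when `mask` is a bare array.
#' @return 2 x 3 matrix: first row minimum corner, second row maximum, mm.
#' @export
mask_bbox <- function(mask, spacing = NULL, origin = NULL) {
  sp <- spacing %||% (if (inherits(mask, "us_volume")) mask$spacing else c(1, 1, 1))
  org <- origin %||% (if (inherits(mask, "us_volume")) mask$origin else c(0, 0, 0))
  m <- mask_array(mask)
  if (!any(m)) {
    abort("empty mask has no bounding box", class = "plcpd_parameter_error")
  }
  idx <- which(m, arr.ind = TRUE) - 1
  lo <- unname(apply(idx, 2, min)) * sp + org
  hi <- unname(apply(idx, 2, max)) * sp + org
  rbind(lo, hi, deparse.level = 0)
}

#' Evaluate an estimated transform against the ground truth
#'
#' Samples `n_targets` points uniformly inside the head's bounding box, maps
#' them through the true and the estimated transform, and reports the target
#' registration error plus the RMS differences of the translation triplets
#' (mm) and of the intrinsic Z-Y-X Euler-angle triplets (degrees).
#'
#' @param truth,estimated [similarity_transform()] objects.
#' @param bbox 2 x 3 matrix (min/max corners, mm), e.g. from [mask_bbox()].
#' @param n_targets Number of target points, default 1000.
#' @param seed Seed for target sampling.
#' @param tre_method `"mean"` (default) or `"rms"`, see
#'   [target_registration_error()].
#' @return One-row tibble: `tre`, `rms_translation`, `rms_rotation`,
#'   `rotation_error`, `scale_error`, `n_targets`.
#' @export
evaluate_registration <- function(truth, estimated, bbox, n_targets = 1000L,
                                  seed = 1L, tre_method = "mean") {
  stopifnot(inherits(truth, "similarity_transform"),
            inherits(estimated, "similarity_transform"))
  bbox <- as.matrix(bbox)
  if (!identical(dim(bbox), c(2L, 3L)) || any(bbox[2, ] <= bbox[1, ])) {
    abort("bbox must be a 2 x 3 matrix with max > min on every axis",
          class = "plcpd_parameter_error")
  }
  set.seed(seed)
  n <- as.integer(n_targets)
  targets <- cbind(runif(n, bbox[1, 1], bbox[2, 1]),
                   runif(n, bbox[1, 2], bbox[2, 2]),
                   runif(n, bbox[1, 3], bbox[2, 3]))
  b <- transform_points(targets, truth)
  a <- transform_points(targets, estimated)
  tibble::tibble(
    tre = target_registration_error(b, a, method = tre_method),
    rms_translation = rms_difference(truth$translation, estimated$translation),
    rms_rotation = rms_difference(euler_zyx(truth$rotation),
                                  euler_zyx(estimated$rotation)),
    rotation_error = rotation_angle(t(truth$rotation) %*% estimated$rotation),
    scale_error = abs(estimated$scale - truth$scale),
    n_targets = n)
}

#' Segment a volume with the full preprocessing pipeline
#'
#' Confidence-weights the volume, extracts the feature stack and applies the
#' forest: the standard path from a raw acquisition to its posterior volume.
#'
#' @param vol A [us_volume()].
#' @param forest A `cranium_forest` trained on stacks produced with the same
#'   `window`/`beam_axis` settings.
#' @param window Analysis window, default 9.
#' @param beam_axis Beam axis for the confidence map, default 3.
#' @param attenuation_coeff,shadow_gain Confidence-map parameters.
#' @return A `posterior_volume`.
#' @export
segment_volume <- function(vol, forest, window = 9L, beam_axis = 3L,
                           attenuation_coeff = 0.02, shadow_gain = 0.5) {
  cmap <- compute_confidence_map(vol, beam_axis = beam_axis,
                                 attenuation_coeff = attenuation_coeff,
                                 shadow_gain = shadow_gain)
  wv <- weight_by_confidence(vol, cmap)
  fs <- extract_features(wv, window = window)
  predict_posterior(forest, fs)
}

#' Cross-validated segmentation performance on labeled volumes
#'
#' K-fold cross-validation of the forest segmenter: each fold holds out one
#' group of volumes, trains on the rest (pooled, class-balanced subsampling)
#' and reports held-out Dice, AUC and Hausdorff surface distance per volume.
#'
#' @param volumes List of [us_volume()] acquisitions.
#' @param labels List of matching label volumes (+1 cranium / -1 rest).
#' @param n_folds Number of folds; with as many volumes as folds this is
#'   leave-one-volume-out. Default 5.
#' @param window Analysis window, default 9.
#' @param sample_cap Training voxels per fold (class-balanced), default 50000.
#' @param trees,max_depth Forest size, defaults 50 / 12.
#' @param threshold Binarization threshold for Dice/HSD, default 0.5.
#' @param seed Seed controlling fold assignment, subsampling and tree growth.
#' @return Tibble with one row per held-out volume: `fold`, `volume`, `dice`,
#'   `auc`, `hsd`.
#' @export
crossvalidate_segmentation <- function(volumes, labels, n_folds = 5L,
                                       window = 9L, sample_cap = 50000L,
                                       trees = 50L, max_depth = 12L,
                                       threshold = 0.5, seed = 1L) {
  stopifnot(length(volumes) == length(labels), length(volumes) >= n_folds)
  nv <- length(volumes)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(n_folds), nv))
  stacks <- lapply(volumes, function(v) {
    cmap <- compute_confidence_map(v)
    extract_features(weight_by_confidence(v, cmap), window = window)
  })
  purrr::map_dfr(seq_len(n_folds), function(f) {
    train_idx <- which(fold_of != f)
    test_idx <- which(fold_of == f)
    Xtr <- do.call(rbind, lapply(train_idx, function(i) stack_matrix(stacks[[i]])))
    ytr <- unlist(lapply(train_idx, function(i) label_vector(labels[[i]])))
    forest <- train_forest(Xtr, ytr, trees = trees, max_depth = max_depth,
                           sample_cap = sample_cap, seed = seed + f)
    purrr::map_dfr(test_idx, function(i) {
      post <- predict_posterior(forest, stacks[[i]])
      seg <- binarize_posterior(post, threshold = threshold)
      tibble::tibble(
        fold = f, volume = i,
        dice = dice_coefficient(seg, labels[[i]]),
        auc = roc_auc(as.vector(post$data), label_vector(labels[[i]])),
        hsd = hausdorff_surface_distance(seg, labels[[i]],
                                         spacing = post$spacing))
    })
  })
}

#' End-to-end registration of two raw acquisitions
#'
#' The full pipeline on a pair of volumes: confidence weighting, forest
#' segmentation, posterior-weighted shell clouds, PL-CPD registration of the
#' moving cloud onto the fixed one.
#'
#' @param fixed_vol,moving_vol [us_volume()] acquisitions.
#' @param forest A trained `cranium_forest`.
#' @param target_points Cloud size, default 2000.
#' @param seed Seed for cloud subsampling.
#' @param ... Passed on to [plcpd_register()].
#' @inheritParams segment_volume
#' @return A `plcpd_fit`; the clouds are attached as `fixed_cloud` and
#'   `moving_cloud` attributes.
#' @export
register_volumes <- function(fixed_vol, moving_vol, forest,
                             target_points = 2000L, window = 9L,
                             beam_axis = 3L, seed = 1L, ...) {
  seg <- function(v) {
    post <- segment_volume(v, forest, window = window, beam_axis = beam_axis)
    mask <- binarize_posterior(post)
    build_weighted_cloud(mask, post, target_points = target_points, seed = seed)
  }
  fixed_cloud <- seg(fixed_vol)
  moving_cloud <- seg(moving_vol)
  fit <- plcpd_register(fixed_cloud, moving_cloud, ...)
  attr(fit, "fixed_cloud") <- fixed_cloud
  attr(fit, "moving_cloud") <- moving_cloud
  fit
}
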