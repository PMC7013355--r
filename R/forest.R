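#' Entropy of a discrete class distribution
#'
#' Shannon entropy in bits, `H = -sum p log2 p` with `0 log 0 = 0`.
#'
#' @param p Numeric vector of class probabilities (non-negative, summing to 1
#'   within 1e-9).
#' @return Entropy in bits.
#' @examples
#' class_entropy(c(0.5, 0.5)) # 1 bit
#' class_entropy(c(1, 0))     # 0
#' @export
class_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("probabilities must be >= 0 and sum to 1",
          class = "plcpd_distribution_error")
  }
  pz <- p[p > 0]
  -sum(pz * log2(pz))
}

#' Information gain of a binary split
#'
#' `I = H(parent) - sum_i |child_i|/|parent| H(child_i)` over the left/right
#' children, entropies in bits. Always in `[0, H(parent)]`.
#'
#' @param labels Vector of class labels for the parent subset (any two-valued
#'   coding, e.g. +1/-1).
#' @param goes_left Logical vector, `TRUE` where the element is routed to the
#'   left child; `NA` is an error (every element must go to exactly one child).
#' @return Information gain in bits.
#' @examples
#' information_gain(c(1, 1, 1, 1, -1, -1, -1, -1), rep(c(TRUE, FALSE), each = 4))
#' @export
information_gain <- function(labels, goes_left) {
  if (length(labels) != length(goes_left) || !is.logical(goes_left)) {
    abort("goes_left must be a logical vector matching labels",
          class = "plcpd_split_error")
  }
  if (anyNA(goes_left) || anyNA(labels)) {
    abort("every element must be routed to exactly one child",
          class = "plcpd_split_error")
  }
  hist_of <- function(l) {
    if (length(l) == 0L) return(NULL)
    tabulate(factor(l, levels = unique(labels)),
             nbins = length(unique(labels))) / length(l)
  }
  hp <- class_entropy(hist_of(labels))
  n <- length(labels)
  gain <- hp
  for (side in list(goes_left, !goes_left)) {
    if (any(side)) {
      gain <- gain - sum(side) / n * class_entropy(hist_of(labels[side]))
    }
  }
  max(gain, 0)
}

#' Train a random forest voxel classifier for the fetal cranium
#'
#' Grows `trees` binary decision trees. At each node a fresh random candidate
#' set (a subset of features crossed with quantile thresholds of the node's
#' values) is drawn, and the split maximizing the information gain in bits is
#' kept; leaves store the empirical class histogram. The ensemble posterior
#' `P(c = +1 | V)` is the average of the reached leaves' positive-class
#' frequencies.
#'
#' @param features A `feature_stack` from [extract_features()], or a numeric
#'   matrix (samples x features).
#' @param labels Label volume (array on the same grid) or vector with values
#'   +1 (cranium) and -1 (everything else); a `label_volume` works too.
#' @param trees Number of trees, default 50.
#' @param max_depth Maximum tree depth, default 12.
#' @param n_candidates Features tried per node; default `ceiling(sqrt(d))`.
#' @param n_thresholds Quantile thresholds tried per candidate feature,
#'   default 10.
#' @param min_leaf Minimum samples per leaf, default 5.
#' @param sample_cap Class-balanced cap on training voxels (default 50000);
#'   `Inf` disables subsampling.
#' @param mask Optional logical array restricting which voxels are eligible.
#' @param seed Integer seed; the model is reproducible given the seed.
#' @return A `cranium_forest` model.
#' @export
train_forest <- function(features, labels, trees = 50L, max_depth = 12L,
                         n_candidates = NULL, n_thresholds = 10L,
                         min_leaf = 5L, sample_cap = 50000L, mask = NULL,
                         seed = 1L) {
  if (inherits(features, "feature_stack")) {
    X <- stack_matrix(features)
    feat_names <- features$features
  } else {
    X <- as.matrix(features)
    feat_names <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  }
  y <- label_vector(labels)
  if (length(y) != nrow(X)) {
    abort("labels do not match the feature grid", class = "plcpd_dimension_error")
  }
  keep <- if (is.null(mask)) rep(TRUE, length(y)) else as.vector(mask)
  idx <- which(keep)
  if (is.finite(sample_cap)) {
    set.seed(seed)
    pos <- idx[y[idx] > 0]
    neg <- idx[y[idx] < 0]
    npos <- min(length(pos), ceiling(sample_cap / 2))
    nneg <- min(length(neg), sample_cap - npos)
    idx <- c(if (length(pos)) sample(pos, npos) else integer(),
             if (length(neg)) sample(neg, nneg) else integer())
  }
  ysub <- y[idx]
  if (length(unique(ysub)) < 2L) {
    abort("training data contain a single class",
          class = "plcpd_degenerate_training_error")
  }
  d <- ncol(X)
  if (is.null(n_candidates)) n_candidates <- ceiling(sqrt(d))
  raw <- train_forest_cpp(X[idx, , drop = FALSE],
                          as.integer(ysub > 0),
                          as.integer(trees), as.integer(max_depth),
                          as.integer(n_candidates), as.integer(n_thresholds),
                          as.integer(min_leaf), as.integer(seed))
  structure(list(trees = raw, features = feat_names,
                 config = list(trees = as.integer(trees),
                               max_depth = as.integer(max_depth),
                               n_candidates = as.integer(n_candidates),
                               n_thresholds = as.integer(n_thresholds),
                               min_leaf = as.integer(min_leaf)),
                 seed = as.integer(seed)),
            class = "cranium_forest")
}

#' @export
print.cranium_forest <- function(x, ...) {
  cat(sprintf("<cranium_forest> %d trees (max depth %d, %d candidate features x %d thresholds per node), features: %s\n",
              length(x$trees), x$config$max_depth, x$config$n_candidates,
              x$config$n_thresholds, paste(x$features, collapse = ", ")))
  invisible(x)
}

label_vector <- function(labels) {
  if (inherits(labels, "us_volume")) labels <- labels$data
  v <- as.vector(labels)
  if (is.logical(v)) v <- ifelse(v, 1, -1)
  u <- unique(v)
  if (!all(u %in% c(-1, 1))) {
    abort("labels must be coded +1 / -1 (or logical)",
          class = "plcpd_parameter_error")
  }
  v
}

#' Voxelwise posterior probability of cranium
#'
#' Averages the reached leaf class histograms over all trees:
#' `P(c=+1|V) = (1/T) sum_t P_t(c=+1|V)`.
#'
#' @param model A `cranium_forest`.
#' @param features A `feature_stack` (grid output) or numeric matrix (vector
#'   output); feature order must match training.
#' @return A `posterior_volume` ([us_volume()] subclass with values in
#'   \[0, 1\]) for stacks, or a numeric vector for matrices.
#' @export
predict_posterior <- function(model, features) {
  stopifnot(inherits(model, "cranium_forest"))
  gridded <- inherits(features, "feature_stack")
  X <- if (gridded) stack_matrix(features) else as.matrix(features)
  if (ncol(X) != length(model$features)) {
    abort(sprintf("model expects %d features, got %d",
                  length(model$features), ncol(X)),
          class = "plcpd_model_error")
  }
  p <- predict_forest_cpp(model$trees, X)
  if (!gridded) return(p)
  out <- us_volume(array(p, dim(features$data)[1:3]),
                   spacing = features$spacing, origin = features$origin)
  class(out) <- c("posterior_volume", class(out))
  out
}

#' Binarize a posterior volume into a cranium mask
#'
#' Labels +1 where the posterior is at least `threshold` (ties go to cranium)
#' and -1 elsewhere; optionally keeps only the largest 26-connected component
#' (the cranium is a single shell).
#'
#' @param post A `posterior_volume` (or [us_volume()] of probabilities).
#' @param threshold Probability threshold in (0, 1), default 0.5.
#' @param largest_component Keep only the largest connected component
#'   (default `TRUE`).
#' @return A `label_volume` ([us_volume()] subclass with values +1/-1).
#' @export
binarize_posterior <- function(post, threshold = 0.5, largest_component = TRUE) {
  stopifnot(inherits(post, "us_volume"))
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must be inside (0, 1)", class = "plcpd_parameter_error")
  }
  m <- post$data >= threshold
  if (largest_component && any(m)) {
    lab <- label_components_cpp(as.vector(m), as.integer(dim(m)))
    counts <- tabulate(lab)
    m <- array(lab == which.max(counts), dim(m))
  }
  out <- us_volume(array(ifelse(m, 1, -1), dim(m)),
                   spacing = post$spacing, origin = post$origin)
  class(out) <- c("label_volume", class(out))
  out
}

#' Serialize / restore a forest model as JSON
#'
#' Tree arrays (feature index, threshold, children, leaf histograms) are
#' written verbatim so the reloaded model predicts identically.
#'
#' @param model A `cranium_forest`.
#' @param path Output JSON path.
#' @return `path` (write) or the restored `cranium_forest` (read).
#' @export
write_forest <- function(model, path) {
  stopifnot(inherits(model, "cranium_forest"))
  payload <- list(features = model$features, config = model$config,
                  seed = model$seed,
                  trees = lapply(model$trees, function(t) {
                    lapply(t, as.vector)
                  }))
  # I(17) significant digits: split thresholds are exact data values, and a
  # one-ulp loss would flip the < comparison for the defining sample
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(seq_len(if (is.data.frame(payload$trees)) nrow(payload$trees)
                          else length(payload$trees)),
                  function(i) {
                    t <- if (is.data.frame(payload$trees)) {
                      lapply(payload$trees, function(col) col[[i]])
                    } else payload$trees[[i]]
                    list(feature = as.integer(t$feature),
                         threshold = as.numeric(t$threshold),
                         left = as.integer(t$left),
                         right = as.integer(t$right),
                         p_pos = as.numeric(t$p_pos),
                         n_node = as.integer(t$n_node),
                         gain = as.numeric(t$gain))
                  })
  structure(list(trees = trees, features = payload$features,
                 config = lapply(payload$config, as.integer),
                 seed = as.integer(payload$seed)),
            class = "cranium_forest")
}
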