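#' Per-voxel texture and edge feature stack
#'
#' Computes the eight-feature bank used for cranium classification: raw
#' intensity, local variance, local rank, local entropy, local median, a
#' Wiener-filtered intensity, a slice-wise Canny edge map and a 6-neighbor
#' Laplacian response. Window statistics use a cubic analysis window with
#' edge replication at the borders.
#'
#' Feature definitions:
#' * `rank` — normalized rank of the center voxel among the other window
#'   voxels (ties counted half), in \[0, 1\].
#' * `entropy` — histogram entropy in bits of window intensities quantized to
#'   `nbins` levels over the global range.
#' * `wiener` — local adaptive filter `mu + max(var - nu, 0)/max(var, nu) *
#'   (x - mu)` with noise variance `nu` estimated as the mean of the local
#'   variances.
#' * `canny` — binary edges from a 2D Canny detector applied slice-wise along
#'   `canny_axis`, hysteresis thresholds fixed at (0.1, 0.2) of each slice's
#'   maximum gradient.
#' * `laplacian` — 6-neighbor discrete Laplacian.
#'
#' @param vol A [us_volume()].
#' @param window Odd cubic window edge length (>= 3), default 9.
#' @param canny_axis Axis along which slices are taken for the 2D Canny
#'   detector (default 3, i.e. slices perpendicular to the beam axis when the
#'   beam runs along axis 3... slices are taken across that axis).
#' @param nbins Gray levels for the entropy histogram (default 32).
#' @return A `feature_stack`: 4D array (x, y, z, feature) plus feature names
#'   and grid metadata.
#' @export
extract_features <- function(vol, window = 9L, canny_axis = 3L, nbins = 32L) {
  stopifnot(inherits(vol, "us_volume"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    abort("window must be odd and >= 3", class = "plcpd_parameter_error")
  }
  d <- dim(vol$data)
  if (any(d < window)) {
    abort("window larger than the volume", class = "plcpd_parameter_error")
  }
  v <- as.vector(vol$data)
  dims <- as.integer(d)

  mv <- local_mean_var_cpp(v, dims, window)
  rm_ <- local_rank_median_cpp(v, dims, window)
  ent <- local_entropy_cpp(v, dims, window, as.integer(nbins))
  lap <- laplacian6_cpp(v, dims)
  can <- canny_slices_cpp(v, dims, as.integer(canny_axis) - 1L, 0.1, 0.2)

  nu <- mean(mv$var)
  adj <- pmax(mv$var - nu, 0) / pmax(mv$var, max(nu, .Machine$double.eps))
  wiener <- mv$mean + adj * (v - mv$mean)

  feats <- c("intensity", "variance", "rank", "entropy", "median",
             "wiener", "canny", "laplacian")
  stack <- array(c(v, mv$var, rm_$rank, ent, rm_$median, wiener, can, lap),
                 dim = c(d, length(feats)))
  structure(list(data = stack, features = feats,
                 spacing = vol$spacing, origin = vol$origin),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<feature_stack> %d x %d x %d voxels, %d features: %s\n",
              d[1], d[2], d[3], d[4], paste(x$features, collapse = ", ")))
  invisible(x)
}

# flatten a feature stack to a (n_voxels x d) matrix
stack_matrix <- function(fs) {
  d <- dim(fs$data)
  m <- matrix(fs$data, nrow = prod(d[1:3]), ncol = d[4])
  colnames(m) <- fs$features
  m
}
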