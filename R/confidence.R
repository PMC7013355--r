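#' Per-voxel ultrasound confidence maps
#'
#' Estimates, for every voxel, how reliable the ultrasound signal is at that
#' location: confidence is 1 at the transducer-side face and decays with depth
#' along the beam axis, decaying faster through voxels with strong intensity
#' gradients (the reflectors that cast acoustic shadows). The model is a
#' per-beam-line recurrence
#' \deqn{c(0)=1,\quad c(k) = c(k-1)\,
#'   e^{-\Delta (\mu + \gamma\, \hat g_k)},}
#' where \eqn{\Delta} is the voxel spacing along the beam (mm), \eqn{\mu} the
#' baseline attenuation per mm, \eqn{\gamma} the shadow gain, and
#' \eqn{\hat g_k} the beam-axis gradient magnitude normalized to \[0, 1\] over
#' the whole volume. The gradient normalization makes the map invariant to
#' global affine intensity rescaling.
#'
#' @param vol A [us_volume()].
#' @param beam_axis Axis (1, 2 or 3) along which sound propagates; the first
#'   slice on that axis is the transducer side. Default 3.
#' @param attenuation_coeff Baseline attenuation rate per mm (>= 0).
#' @param shadow_gain Extra attenuation rate per mm applied at full normalized
#'   gradient.
#' @return A `confidence_map` (a [us_volume()] subclass with values in
#'   \[0, 1\] and a `beam_axis` field).
#' @export
compute_confidence_map <- function(vol, beam_axis = 3L,
                                   attenuation_coeff = 0.02,
                                   shadow_gain = 0.5) {
  stopifnot(inherits(vol, "us_volume"))
  beam_axis <- as.integer(beam_axis)
  if (length(beam_axis) != 1L || is.na(beam_axis) ||
      beam_axis < 1L || beam_axis > 3L) {
    abort("beam_axis must be 1, 2 or 3", class = "plcpd_parameter_error")
  }
  if (attenuation_coeff < 0 || shadow_gain < 0) {
    abort("attenuation_coeff and shadow_gain must be >= 0",
          class = "plcpd_parameter_error")
  }
  g <- axis_gradient(vol$data, beam_axis, vol$spacing[beam_axis])
  gmax <- max(abs(g))
  ghat <- if (gmax > 0) abs(g) / gmax else array(0, dim(vol$data))

  step <- exp(-vol$spacing[beam_axis] * (attenuation_coeff + shadow_gain * ghat))
  # put the beam axis first, cumulative product down each beam line,
  # with the transducer-side slice pinned at confidence 1
  perm <- c(beam_axis, setdiff(1:3, beam_axis))
  m <- aperm(step, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  m[1, ] <- 1
  cm <- apply(m, 2, cumprod)
  cm <- aperm(array(cm, dm), order(perm))

  out <- us_volume(cm, spacing = vol$spacing, origin = vol$origin)
  out$beam_axis <- beam_axis
  class(out) <- c("confidence_map", class(out))
  out
}

# central-difference gradient along one axis (one-sided at the ends)
axis_gradient <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  if (n < 2L) return(array(0, d))
  idx_plus <- pmin(seq_len(n) + 1L, n)
  idx_minus <- pmax(seq_len(n) - 1L, 1L)
  slicer <- function(ix) {
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- ix
    do.call(`[`, c(list(a), args, list(drop = FALSE)))
  }
  denom <- (idx_plus - idx_minus) * h
  (slicer(idx_plus) - slicer(idx_minus)) / rep_along_axis(denom, d, axis)
}

# broadcast a per-slice value along the other two axes
rep_along_axis <- function(v, d, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- array(v, c(d[axis], d[setdiff(1:3, axis)]))
  aperm(a, order(perm))
}

#' Weight a volume by its confidence map
#'
#' Multiplies voxel intensities by confidence, homogenizing intensities and
#' suppressing unreliable (shadowed, deep) regions. Output intensity is never
#' larger than input wherever confidence is at most 1.
#'
#' @param vol A [us_volume()].
#' @param cmap A `confidence_map` on the same grid.
#' @return A [us_volume()] with intensities `vol * cmap`.
#' @export
weight_by_confidence <- function(vol, cmap) {
  stopifnot(inherits(vol, "us_volume"), inherits(cmap, "us_volume"))
  if (!identical(dim(vol$data), dim(cmap$data))) {
    abort("volume and confidence map shapes differ",
          class = "plcpd_dimension_error")
  }
  us_volume(vol$data * cmap$data, spacing = vol$spacing, origin = vol$origin)
}
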