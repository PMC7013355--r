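#' Specify a synthetic ultrasound fetal-head phantom pair
#'
#' The phantom is an ellipsoidal cranium shell over soft-tissue texture and
#' background, with multiplicative speckle, angular occlusion sectors that
#' wipe out parts of the shell (emulating acoustic shadows from nonuniform
#' cranial calcification), and a second "acquisition" of the same anatomy
#' related to the first by a known ground-truth similarity transform, with
#' its own complementary occlusion sectors and an independent speckle
#' realization — the way repeat axial/coronal acquisitions of one head differ.
#'
#' Occlusion sectors are azimuthal wedges (about the grid z-axis through the
#' ellipsoid center): a 90-degree-wide sector at attenuation factor 0 removes
#' about a quarter of the shell. Each sector is
#' `list(direction = , width_deg = , factor = )` where `direction` is a
#' length-3 vector whose azimuth locates the wedge center.
#'
#' @param grid_dim Grid size, default `c(160, 160, 160)` (64 mm extent at the
#'   default spacing, enough to hold the default head).
#' @param spacing Isotropic voxel size in mm, default 0.4 (clinical fetal 3D
#'   ultrasound is acquired at 0.2-0.5 mm).
#' @param semi_axes Outer ellipsoid semi-axes in mm, default `c(28, 24, 20)`
#'   (a second-trimester head).
#' @param shell_thickness Cranium shell thickness in mm, default 2.5.
#' @param center Ellipsoid center in mm; default the grid center.
#' @param intensity_background,intensity_tissue,intensity_shell Mean
#'   intensities (arbitrary units), defaults 40 / 120 / 220.
#' @param speckle_sigma Rayleigh mode of the multiplicative speckle field
#'   (0 disables speckle), default 1.
#' @param speckle_smooth Gaussian smoothing of the speckle field in voxels
#'   (correlated speckle), default 0.8.
#' @param occlusion_a,occlusion_b Lists of occlusion sectors for the two
#'   acquisitions; defaults are complementary 90-degree sectors at factor 0.1.
#' @param rotation_deg,rotation_axis,translation,scale Ground-truth similarity
#'   transform mapping acquisition B's frame into A's; defaults 15 degrees
#'   about an oblique axis, (6, 4, -3) mm, scale 1.
#' @param seed Integer seed fixing all randomness.
#' @return A validated `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(160L, 160L, 160L),
                         spacing = 0.4,
                         semi_axes = c(28, 24, 20),
                         shell_thickness = 2.5,
                         center = NULL,
                         intensity_background = 40,
                         intensity_tissue = 120,
                         intensity_shell = 220,
                         speckle_sigma = 1,
                         speckle_smooth = 0.8,
                         occlusion_a = list(list(direction = c(1, 0, 0),
                                                 width_deg = 90, factor = 0.1)),
                         occlusion_b = list(list(direction = c(-1, 0, 0),
                                                 width_deg = 90, factor = 0.1)),
                         rotation_deg = 15,
                         rotation_axis = c(0.3, 0.4, 1),
                         translation = c(6, 4, -3),
                         scale = 1,
                         seed = 1L) {
  grid_dim <- as.integer(grid_dim)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(grid_dim < 8L)) {
    abort("grid must be at least 8 voxels per axis", class = "plcpd_spec_error")
  }
  if (!(shell_thickness > 0) || any(semi_axes <= shell_thickness)) {
    abort("need semi_axes > shell_thickness > 0", class = "plcpd_spec_error")
  }
  for (occ in c(occlusion_a, occlusion_b)) {
    if (!(occ$width_deg > 0 && occ$width_deg <= 360) ||
        occ$factor < 0 || occ$factor >= 1) {
      abort("occlusion sectors need width in (0, 360] and factor in [0, 1)",
            class = "plcpd_spec_error")
    }
  }
  extent <- grid_dim * spacing
  if (is.null(center)) center <- extent / 2
  if (any(center - semi_axes < 0) || any(center + semi_axes > extent)) {
    abort("ellipsoid exceeds the grid", class = "plcpd_spec_error")
  }
  transform <- similarity_transform(
    rotation = rotation_matrix(rotation_axis, rotation_deg),
    scale = scale, translation = translation)
  structure(list(grid_dim = grid_dim, spacing = spacing,
                 semi_axes = semi_axes, shell_thickness = shell_thickness,
                 center = center,
                 intensity_background = intensity_background,
                 intensity_tissue = intensity_tissue,
                 intensity_shell = intensity_shell,
                 speckle_sigma = speckle_sigma,
                 speckle_smooth = speckle_smooth,
                 occlusion_a = occlusion_a, occlusion_b = occlusion_b,
                 transform = transform, seed = as.integer(seed)),
            class = "phantom_spec")
}

# ellipsoidal "radius" (1 on the outer surface) at world points, n x 3
ellipsoid_rho <- function(pts, center, semi_axes) {
  u <- sweep(pts, 2, center)
  sqrt((u[, 1] / semi_axes[1])^2 + (u[, 2] / semi_axes[2])^2 +
         (u[, 3] / semi_axes[3])^2)
}

# anatomy = noiseless intensity + shell membership, evaluated analytically
phantom_anatomy <- function(spec, pts) {
  rho_out <- ellipsoid_rho(pts, spec$center, spec$semi_axes)
  rho_in <- ellipsoid_rho(pts, spec$center, spec$semi_axes - spec$shell_thickness)
  shell <- rho_out <= 1 & rho_in > 1
  interior <- rho_in <= 1
  intensity <- ifelse(shell, spec$intensity_shell,
                      ifelse(interior, spec$intensity_tissue,
                             spec$intensity_background))
  list(intensity = intensity, shell = shell)
}

# TRUE where a point falls inside any occlusion wedge (azimuth about z
# through `center`)
in_occlusion <- function(pts, center, sectors) {
  if (length(sectors) == 0L) return(rep(FALSE, nrow(pts)))
  az <- atan2(pts[, 2] - center[2], pts[, 1] - center[1]) * 180 / pi
  hit <- rep(FALSE, nrow(pts))
  for (occ in sectors) {
    occ_az <- atan2(occ$direction[2], occ$direction[1]) * 180 / pi
    d <- ((az - occ_az + 180) %% 360) - 180
    hit <- hit | abs(d) <= occ$width_deg / 2
  }
  hit
}

occlusion_factors <- function(pts, center, sectors) {
  f <- rep(1, nrow(pts))
  for (occ in sectors) {
    occ_az <- atan2(occ$direction[2], occ$direction[1]) * 180 / pi
    az <- atan2(pts[, 2] - center[2], pts[, 1] - center[1]) * 180 / pi
    d <- ((az - occ_az + 180) %% 360) - 180
    f[abs(d) <= occ$width_deg / 2] <- occ$factor
  }
  f
}

# correlated multiplicative speckle: smoothed Rayleigh field, mode sigma
speckle_field <- function(dim3, sigma, smooth_vox) {
  if (sigma <= 0) return(array(1, dim3))
  f <- array(sigma * sqrt(-2 * log(runif(prod(dim3)))), dim3)
  if (smooth_vox > 0) f <- gauss_smooth3(f, smooth_vox)
  f
}

# separable 3D Gaussian smoothing (replicated borders)
gauss_smooth3 <- function(a, sigma_vox) {
  r <- max(1L, ceiling(2 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  d <- dim(a)
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = dm[1])
    pad_top <- m[rep(1L, r), , drop = FALSE]
    pad_bot <- m[rep(nrow(m), r), , drop = FALSE]
    mp <- rbind(pad_top, m, pad_bot)
    sm <- stats::filter(mp, k, sides = 2)
    sm <- sm[(r + 1):(r + dm[1]), , drop = FALSE]
    a <- aperm(array(as.numeric(sm), dm), order(perm))
  }
  a
}

#' Generate a phantom acquisition pair with ground truth
#'
#' Acquisition A is the spec's anatomy on its grid; acquisition B is the same
#' anatomy observed through the ground-truth transform (the noiseless anatomy
#' is evaluated analytically at the transformed coordinates, so B's grid
#' carries no interpolation error), with its own occlusion sectors and an
#' independent speckle realization. Label volumes mark unoccluded shell
#' voxels (+1); occluded shell voxels lose their signal and their label.
#'
#' @param spec A [phantom_spec()].
#' @return List with `vol_a`, `vol_b` ([us_volume()]), `label_a`, `label_b`
#'   (`label_volume`), and `transform` (maps B's frame into A's).
#' @export
make_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dim
  idx <- as.matrix(expand.grid(x = seq_len(d[1]) - 1L,
                               y = seq_len(d[2]) - 1L,
                               z = seq_len(d[3]) - 1L))
  pts <- sweep(idx, 2, spec$spacing, `*`)

  build <- function(sample_pts, label_pts_center, sectors, tf_center) {
    an <- phantom_anatomy(spec, sample_pts)
    occ_f <- occlusion_factors(label_pts_center, tf_center, sectors)
    inten <- an$intensity
    inten[an$shell] <- inten[an$shell] * occ_f[an$shell]
    lab <- an$shell & occ_f == 1
    list(intensity = inten, label = lab)
  }

  set.seed(spec$seed)
  a <- build(pts, pts, spec$occlusion_a, spec$center)
  spA <- speckle_field(d, spec$speckle_sigma, spec$speckle_smooth)
  vol_a <- us_volume(array(a$intensity, d) * spA, spacing = spec$spacing)

  # B: anatomy seen through the ground-truth transform; occlusion wedges sit
  # in B's own frame around the transformed ellipsoid center
  tf <- spec$transform
  pts_b_in_a <- transform_points(pts, tf)
  center_b <- as.vector(invert_transform(tf)$translation +
                          invert_transform(tf)$scale *
                          invert_transform(tf)$rotation %*% spec$center)
  b <- build(pts_b_in_a, pts, spec$occlusion_b, center_b)
  spB <- speckle_field(d, spec$speckle_sigma, spec$speckle_smooth)
  vol_b <- us_volume(array(b$intensity, d) * spB, spacing = spec$spacing)

  as_label <- function(lab) {
    out <- us_volume(array(ifelse(lab, 1, -1), d), spacing = spec$spacing)
    class(out) <- c("label_volume", class(out))
    out
  }
  list(vol_a = vol_a, vol_b = vol_b,
       label_a = as_label(a$label), label_b = as_label(b$label),
       transform = tf)
}

#' Generate a corresponding weighted cloud pair with ground truth
#'
#' Samples points on the phantom's inner and outer shell surfaces (A's frame),
#' maps them through the inverse ground-truth transform into B's frame (so the
#' returned transform registers B onto A exactly), then optionally jitters B's
#' points, replaces a fixed fraction of them with uniform box outliers
#' carrying a low weight, and beta-perturbs the weights. Cloud A carries unit
#' weights (the fixed set's weights are ignored by the registration model).
#'
#' @param spec A [phantom_spec()].
#' @param n_points Points per cloud, default 1000.
#' @param outlier_fraction Fraction of B's points replaced by outliers
#'   (`round(fraction * n_points)` of them, deterministic count), default 0.
#' @param inlier_weight,outlier_weight Nominal weights of B's inliers and
#'   outliers, defaults 0.95 / 0.01.
#' @param weight_noise Beta concentration for weight perturbation (0 = exact
#'   nominal weights), default 0.
#' @param noise_sd Isotropic Gaussian jitter of B's inlier points in mm,
#'   default 0.
#' @param seed Seed; defaults to the spec's.
#' @return List with `cloud_a`, `cloud_b` ([weighted_cloud()]; `cloud_b` has
#'   a logical `outlier` column) and `transform`.
#' @export
make_cloud_pair <- function(spec, n_points = 1000L, outlier_fraction = 0,
                            inlier_weight = 0.95, outlier_weight = 0.01,
                            weight_noise = 0, noise_sd = 0,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  n <- as.integer(n_points)
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  inner <- seq_len(n) <= n / 2
  ax <- matrix(rep(spec$semi_axes, each = n), n, 3)
  ax[inner, ] <- ax[inner, ] - spec$shell_thickness
  pts_a <- sweep(dirs * ax, 2, spec$center, `+`)

  inv <- invert_transform(spec$transform)
  pts_b <- transform_points(pts_a, inv)
  if (noise_sd > 0) pts_b <- pts_b + matrix(rnorm(3 * n, sd = noise_sd), n, 3)

  n_out <- round(outlier_fraction * n)
  is_out <- rep(FALSE, n)
  if (n_out > 0) {
    is_out[sample.int(n, n_out)] <- TRUE
    rng <- apply(pts_b, 2, range)
    span <- rng[2, ] - rng[1, ]
    lo <- rng[1, ] - 0.1 * span
    hi <- rng[2, ] + 0.1 * span
    pts_b[is_out, ] <- cbind(runif(n_out, lo[1], hi[1]),
                             runif(n_out, lo[2], hi[2]),
                             runif(n_out, lo[3], hi[3]))
  }
  wts <- ifelse(is_out, outlier_weight, inlier_weight)
  if (weight_noise > 0) {
    wts <- rbeta(n, weight_noise * wts, weight_noise * (1 - wts))
  }
  cloud_b <- weighted_cloud(pts_b, pmin(pmax(wts, 0), 1))
  cloud_b$outlier <- is_out
  list(cloud_a = weighted_cloud(pts_a, 1),
       cloud_b = cloud_b,
       transform = spec$transform)
}
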