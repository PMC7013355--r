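#' Similarity transforms (rotation, isotropic scale, translation)
#'
#' A similarity transform maps a point `p` (mm) to `s * R %*% p + t`, with `R`
#' a proper rotation (orthonormal, determinant +1), `s > 0` and `t` in mm.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param scale Positive scalar.
#' @param translation Length-3 numeric, mm.
#' @return An object of class `similarity_transform`.
#' @examples
#' tf <- similarity_transform(rotation_matrix(c(0, 0, 1), 20),
#'                            scale = 1, translation = c(5, -3, 2))
#' @export
similarity_transform <- function(rotation = diag(3), scale = 1,
                                 translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  if (!identical(dim(rotation), c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    abort("rotation must be a 3x3 orthonormal matrix with determinant +1",
          class = "plcpd_parameter_error")
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    abort("scale must be a positive scalar", class = "plcpd_parameter_error")
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation))) {
    abort("translation must be 3 finite values (mm)",
          class = "plcpd_parameter_error")
  }
  structure(list(rotation = rotation, scale = scale, translation = translation),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  e <- euler_zyx(x$rotation)
  cat(sprintf("<similarity_transform> scale %.6g, translation (%s) mm, rotation ZYX (%s) deg\n",
              x$scale, paste(signif(x$translation, 6), collapse = ", "),
              paste(signif(e, 6), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix about an axis
#'
#' @param axis Length-3 axis (normalized internally).
#' @param angle_deg Rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Intrinsic Z-Y-X Euler angles of a rotation
#'
#' Decomposes `R = Rz(alpha) Ry(delta) Rx(lambda)`; returns the three angles
#' in degrees. Any fixed convention is valid for error reporting as long as
#' truth and estimate use the same one.
#'
#' @param R 3x3 rotation matrix.
#' @return Named numeric vector `c(alpha, delta, lambda)` in degrees.
#' @export
euler_zyx <- function(R) {
  delta <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(delta)) > 1e-10) {
    lambda <- atan2(R[3, 2], R[3, 3])
    alpha <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock
    lambda <- atan2(-R[2, 3], R[2, 2])
    alpha <- 0
  }
  c(alpha = alpha, delta = delta, lambda = lambda) * 180 / pi
}

#' Angle of a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return Rotation angle in degrees, in \[0, 180\].
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Apply a similarity transform to points
#'
#' Maps every point through `s R p + t`; weights and any extra columns are
#' untouched. Satisfies the composition law
#' `apply_transform(apply_transform(c, T1), T2) = apply_transform(c, compose_transforms(T2, T1))`.
#'
#' @param cloud A weighted cloud tibble (columns `x`, `y`, `z`, ...) or an
#'   n x 3 matrix.
#' @param transform A [similarity_transform()].
#' @return Same type as the input with transformed coordinates.
#' @export
apply_transform <- function(cloud, transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  if (is.matrix(cloud)) {
    return(transform_points(cloud, transform))
  }
  pts <- as_point_matrix(cloud)
  out <- transform_points(pts, transform)
  cloud$x <- out[, 1]
  cloud$y <- out[, 2]
  cloud$z <- out[, 3]
  cloud
}

transform_points <- function(P, tf) {
  sweep(tf$scale * (P %*% t(tf$rotation)), 2, tf$translation, `+`)
}

#' Compose and invert similarity transforms
#'
#' `compose_transforms(t2, t1)` is `t2` applied after `t1`.
#'
#' @param t2,t1,transform [similarity_transform()] objects.
#' @return A [similarity_transform()].
#' @export
compose_transforms <- function(t2, t1) {
  similarity_transform(rotation = t2$rotation %*% t1$rotation,
                       scale = t2$scale * t1$scale,
                       translation = t2$scale * as.vector(t2$rotation %*% t1$translation) +
                         t2$translation)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  similarity_transform(rotation = Rt, scale = 1 / transform$scale,
                       translation = -as.vector(Rt %*% transform$translation) /
                         transform$scale)
}

#' Read / write a transform as JSON
#'
#' Schema: `rotation` (3x3, row-major), `scale`, `translation`, and the
#' convention string `"x' = s*R*x + t, mm, world frame"`.
#'
#' @param transform A [similarity_transform()].
#' @param path JSON file path.
#' @return `path` (write) or the transform (read).
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "similarity_transform"))
  jsonlite::write_json(
    list(rotation = as.vector(t(transform$rotation)),
         scale = transform$scale,
         translation = transform$translation,
         convention = "x' = s*R*x + t, mm, world frame"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(rotation = matrix(as.numeric(j$rotation), 3, 3,
                                         byrow = TRUE),
                       scale = as.numeric(j$scale),
                       translation = as.numeric(j$translation))
}
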