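#' Weighted point clouds
#'
#' A weighted cloud is a tibble with coordinate columns `x`, `y`, `z` (mm,
#' world frame) and a `weight` column in \[0, 1\] holding the classifier
#' posterior at each point. The constructor validates and tags the tibble so
#' plotting and printing know what it is; all package functions also accept a
#' plain data frame with the same columns.
#'
#' @param points n x 3 matrix or data frame of coordinates (mm).
#' @param weights Numeric vector in \[0, 1\], recycled scalar allowed;
#'   default 1.
#' @param source Optional provenance string.
#' @return A `weighted_cloud` tibble.
#' @export
weighted_cloud <- function(points, weights = 1, source = NULL) {
  P <- as_point_matrix(points)
  w <- rep_len(as.numeric(weights), nrow(P))
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    abort("weights must lie in [0, 1]", class = "plcpd_parameter_error")
  }
  out <- tibble::tibble(x = P[, 1], y = P[, 2], z = P[, 3], weight = w)
  class(out) <- c("weighted_cloud", class(out))
  if (!is.null(source)) attr(out, "source") <- source
  out
}

#' Build a weighted shell cloud from a segmentation
#'
#' Vertices are the world-frame centers of the mask's boundary voxels (the
#' mask minus its 6-neighbor erosion — the inner and outer enveloping surfaces
#' of the cranium shell), each weighted by the classifier posterior sampled
#' (trilinearly) at the vertex. The cloud is then reduced to about
#' `target_points` vertices by farthest-point subsampling from a seeded
#' random start, which preserves coverage of both surfaces.
#'
#' @param mask A `label_volume` (+1/-1), logical array or [us_volume()];
#'   positive/`TRUE` voxels are cranium.
#' @param post A `posterior_volume` on the same grid.
#' @param target_points Target cloud size (>= 4), default 2000; the full
#'   boundary is kept when smaller than this.
#' @param seed Integer seed for the subsampling start.
#' @return A [weighted_cloud()].
#' @export
build_weighted_cloud <- function(mask, post, target_points = 2000L, seed = 1L) {
  m <- mask_array(mask)
  stopifnot(inherits(post, "us_volume"))
  if (!identical(dim(m), dim(post$data))) {
    abort("mask and posterior grids differ", class = "plcpd_dimension_error")
  }
  if (target_points < 4L) {
    abort("target_points must be at least 4", class = "plcpd_parameter_error")
  }
  if (!any(m)) {
    abort("empty segmentation: no cranium voxels",
          class = "plcpd_empty_segmentation_error")
  }
  boundary <- m & !erode6(m)
  idx <- which(boundary, arr.ind = TRUE) - 1L  # 0-based
  pts <- voxel_world(post, idx)
  if (nrow(pts) > target_points) {
    set.seed(seed)
    start <- sample.int(nrow(pts), 1L) - 1L
    keep <- farthest_point_sample_cpp(pts, as.integer(target_points), start) + 1L
    keep <- sort(keep)
    pts <- pts[keep, , drop = FALSE]
  }
  w <- sample_trilinear(post, pts)
  weighted_cloud(pts, pmin(pmax(w, 0), 1))
}

mask_array <- function(mask) {
  if (inherits(mask, "us_volume")) mask <- mask$data
  if (is.logical(mask)) {
    m <- mask
  } else {
    m <- mask > 0
  }
  if (length(dim(m)) != 3L) {
    abort("mask must be a 3D array", class = "plcpd_dimension_error")
  }
  m
}

# 6-neighbor binary erosion
erode6 <- function(m) {
  d <- dim(m)
  shift <- function(a, axis, by) {
    idx <- seq_len(d[axis]) - by
    idx[idx < 1L] <- 1L
    idx[idx > d[axis]] <- d[axis]
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- idx
    out <- do.call(`[`, c(list(a), args, list(drop = FALSE)))
    # outside the volume counts as background
    edge <- if (by > 0) 1L else d[axis]
    args[[axis]] <- edge
    eval_args <- c(list(out), args)
    out <- do.call(`[<-`, c(eval_args, list(value = FALSE)))
    out
  }
  e <- m
  for (axis in 1:3) {
    e <- e & shift(m, axis, 1L) & shift(m, axis, -1L)
  }
  e
}

# trilinear interpolation of a volume at world-frame points
sample_trilinear <- function(vol, pts) {
  d <- dim(vol$data)
  g <- sweep(sweep(pts, 2, vol$origin), 2, vol$spacing, `/`)  # 0-based voxel coords
  g0 <- floor(g)
  f <- g - g0
  val <- numeric(nrow(pts))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ix <- pmin(pmax(g0[, 1] + cx, 0), d[1] - 1)
    iy <- pmin(pmax(g0[, 2] + cy, 0), d[2] - 1)
    iz <- pmin(pmax(g0[, 3] + cz, 0), d[3] - 1)
    wgt <- (if (cx == 1) f[, 1] else 1 - f[, 1]) *
           (if (cy == 1) f[, 2] else 1 - f[, 2]) *
           (if (cz == 1) f[, 3] else 1 - f[, 3])
    val <- val + wgt * vol$data[cbind(ix + 1, iy + 1, iz + 1)]
  }
  val
}

#' Read and write weighted point clouds
#'
#' Supported formats: PLY with per-vertex properties `x`, `y`, `z`, `weight`
#' (ascii written; ascii and binary_little_endian read), and 4-column
#' whitespace text `x y z w`. A missing weight column or property defaults
#' every weight to 1 with a notice.
#'
#' @param path File path; `.ply` selects PLY, anything else the text format.
#' @param cloud A [weighted_cloud()] (or data frame with `x`, `y`, `z`,
#'   `weight`).
#' @return `read_cloud()` a [weighted_cloud()]; `write_cloud()` the path,
#'   invisibly.
#' @export
read_cloud <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "plcpd_format_error")
  }
  if (grepl("\\.ply$", tolower(path))) read_ply(path) else read_xyzw(path)
}

#' @rdname read_cloud
#' @export
write_cloud <- function(cloud, path) {
  P <- as_point_matrix(cloud)
  w <- cloud_weights(cloud) %||% rep(1, nrow(P))
  if (grepl("\\.ply$", tolower(path))) {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(P)),
             "property double x", "property double y", "property double z",
             "property double weight", "end_header")
    body <- apply(cbind(P, w), 1, function(r) {
      paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = " ")
    })
    writeLines(c(hdr, body), path)
  } else {
    utils::write.table(cbind(P, w), path, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

read_xyzw <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v) || !(length(v) %in% c(3L, 4L))) {
      abort(sprintf("%s: malformed vertex line %d", path, i),
            class = "plcpd_parse_error")
    }
    v
  })
  ncols <- unique(vapply(rows, length, 1L))
  if (length(ncols) != 1L) {
    abort(sprintf("%s: inconsistent column counts", path),
          class = "plcpd_parse_error")
  }
  m <- do.call(rbind, rows)
  if (ncols == 3L) {
    inform("no weight column; defaulting all weights to 1")
    weighted_cloud(m, 1)
  } else {
    weighted_cloud(m[, 1:3, drop = FALSE], m[, 4])
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fmt <- NULL
  nvert <- NA_integer_
  props <- character(0)
  sizes <- integer(0)
  in_vertex <- FALSE
  type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  repeat {
    line <- trimws(readLines(con, n = 1L, warn = FALSE))
    if (length(line) == 0L) {
      abort(sprintf("%s: truncated PLY header", path), class = "plcpd_parse_error")
    }
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
    }
    if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") {
        abort(sprintf("%s: list properties on vertices are not supported", path),
              class = "plcpd_parse_error")
      }
      props <- c(props, tok[3])
      sizes <- c(sizes, type_size[[tok[2]]])
    }
    if (tok[1] == "end_header") break
  }
  if (is.na(nvert) || !all(c("x", "y", "z") %in% props)) {
    abort(sprintf("%s: PLY file lacks vertex x/y/z properties", path),
          class = "plcpd_parse_error")
  }
  if (fmt == "ascii") {
    vals <- matrix(NA_real_, nvert, length(props))
    for (i in seq_len(nvert)) {
      line <- readLines(con, n = 1L, warn = FALSE)
      v <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
      if (length(v) != length(props) || anyNA(v)) {
        abort(sprintf("%s: malformed vertex line %d", path, i),
              class = "plcpd_parse_error")
      }
      vals[i, ] <- v
    }
  } else if (fmt == "binary_little_endian") {
    vals <- matrix(NA_real_, nvert, length(props))
    # per-property typed reads, vertex by vertex
    types <- ifelse(sizes == 8, "double", ifelse(sizes == 4, "float", "int"))
    for (i in seq_len(nvert)) {
      for (j in seq_along(props)) {
        vals[i, j] <- if (sizes[j] >= 4L && types[j] != "int") {
          readBin(con, "double", 1L, size = sizes[j], endian = "little")
        } else {
          readBin(con, "integer", 1L, size = sizes[j], endian = "little")
        }
      }
    }
  } else {
    abort(sprintf("%s: unsupported PLY format %s", path, fmt),
          class = "plcpd_parse_error")
  }
  P <- vals[, match(c("x", "y", "z"), props), drop = FALSE]
  if ("weight" %in% props) {
    weighted_cloud(P, vals[, match("weight", props)])
  } else {
    inform("no weight property; defaulting all weights to 1")
    weighted_cloud(P, 1)
  }
}

#' Plot a weighted cloud as 2D projections
#'
#' Scatter of the three axis-aligned projections, colored by weight.
#'
#' @param object A [weighted_cloud()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.weighted_cloud <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(h = object$x, v = object$y, weight = object$weight,
                   projection = "x-y"),
    tibble::tibble(h = object$x, v = object$z, weight = object$weight,
                   projection = "x-z"),
    tibble::tibble(h = object$y, v = object$z, weight = object$weight,
                   projection = "y-z"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v,
                                   colour = .data$weight)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::facet_wrap(~projection, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "mm", y = "mm") +
    ggplot2::theme_minimal()
}
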