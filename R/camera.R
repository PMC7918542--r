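#' Pinhole camera intrinsics
#'
#' Constructs the intrinsic parameter set of a pinhole depth camera: focal
#' lengths `fx`, `fy` and principal point `ppx`, `ppy`, all in pixels, plus
#' the sensor resolution. The extrinsic pose is fixed to the identity
#' rotation and zero translation (the camera frame is the world frame).
#'
#' Axis convention: `x` lateral (rightward), `y` vertical (upward), `z`
#' depth, with scene points in front of the camera carrying `z < 0`.
#' Pixel (0, 0) is the top-left corner, `u` grows rightward and `v`
#' downward.
#'
#' The defaults are a documented synthetic stand-in for an uncalibrated
#' 640 x 480 depth sensor (fx = fy = 600, principal point at the image
#' centre); real deployments should load measured intrinsics via
#' [read_intrinsics()].
#'
#' @param fx,fy Focal lengths in pixels; must be positive.
#' @param ppx,ppy Principal point in pixels; must lie inside the sensor.
#' @param width,height Sensor resolution in pixels.
#' @return An object of class `camera_intrinsics` (a named list).
#' @examples
#' cam <- camera_intrinsics()
#' project_points(data.frame(x = 0.5, y = 0.2, z = -2), cam)
#' @export
camera_intrinsics <- function(fx = 600, fy = 600, ppx = 320, ppy = 240,
                              width = 640L, height = 480L) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0)
  if (ppx < 0 || ppx >= width) stop("ppx must lie in [0, width)")
  if (ppy < 0 || ppy >= height) stop("ppy must lie in [0, height)")
  structure(
    list(fx = fx, fy = fy, ppx = ppx, ppy = ppy,
         width = as.integer(width), height = as.integer(height)),
    class = "camera_intrinsics"
  )
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf(
    "<camera_intrinsics> %dx%d px, fx=%.6g fy=%.6g, pp=(%.6g, %.6g)\n",
    x$width, x$height, x$fx, x$fy, x$ppx, x$ppy
  ))
  invisible(x)
}

#' Read / write camera intrinsics sidecar files
#'
#' Intrinsics travel beside depth images as a small YAML or JSON config with
#' keys `fx`, `fy`, `ppx`, `ppy`, `width`, `height`.
#'
#' @param path File path; format chosen by extension (`.json` else YAML).
#' @param cam A [camera_intrinsics()] object.
#' @return `read_intrinsics()` returns a `camera_intrinsics`;
#'   `write_intrinsics()` returns `path` invisibly.
#' @export
read_intrinsics <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("fx", "fy", "ppx", "ppy", "width", "height")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("intrinsics config missing keys: ", paste(miss, collapse = ", "))
  camera_intrinsics(cfg$fx, cfg$fy, cfg$ppx, cfg$ppy, cfg$width, cfg$height)
}

#' @rdname read_intrinsics
#' @export
write_intrinsics <- function(cam, path) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(cam), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(cam), path)
  }
  invisible(path)
}

#' Project 3D points onto the image plane
#'
#' Applies the pinhole projection `u = fx * x / z + ppx`,
#' `v = fy * y / z + ppy` to every point. Coordinates are continuous
#' (not rounded). Scene points must carry `z != 0`; points at the camera
#' origin plane are degenerate.
#'
#' @param points A data frame with numeric columns `x`, `y`, `z` (meters,
#'   camera frame, scene points at `z < 0`).
#' @param cam A [camera_intrinsics()].
#' @return A tibble with columns `u`, `v` (pixels), one row per point.
#' @export
project_points <- function(points, cam) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  pts <- as_point_cloud(points)
  if (nrow(pts) && any(pts$z == 0)) {
    stop("cannot project points with z = 0 (degenerate)")
  }
  tibble::tibble(
    u = cam$fx * pts$x / pts$z + cam$ppx,
    v = cam$fy * pts$y / pts$z + cam$ppy
  )
}

#' Back-project pixels with depth into 3D
#'
#' Inverse of [project_points()]: a pixel `(u, v)` observed at positive
#' depth `d` (meters) maps to the 3D point with `z = -d`,
#' `x = (u - ppx) * z / fx`, `y = (v - ppy) * z / fy`.
#'
#' @param pixels A data frame with numeric columns `u`, `v` (pixels) and
#'   `depth` (meters, strictly positive).
#' @param cam A [camera_intrinsics()].
#' @return A tibble of 3D points `x`, `y`, `z` (meters, `z < 0`).
#' @export
backproject_pixels <- function(pixels, cam) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  px <- tibble::as_tibble(pixels)
  need <- c("u", "v", "depth")
  if (!all(need %in% names(px))) {
    stop("pixels must have columns u, v, depth")
  }
  if (nrow(px) && any(px$depth <= 0)) {
    stop("invalid depth: back-projection requires depth > 0")
  }
  z <- -px$depth
  tibble::tibble(
    x = (px$u - cam$ppx) * z / cam$fx,
    y = (px$v - cam$ppy) * z / cam$fy,
    z = z
  )
}

#' Coerce to a point-cloud tibble
#'
#' A point cloud is a tibble with numeric columns `x`, `y`, `z` in meters
#' (camera frame); extra columns (e.g. a provenance `label`) are preserved.
#'
#' @param points A data frame with columns `x`, `y`, `z`.
#' @return A tibble.
#' @export
as_point_cloud <- function(points) {
  pts <- tibble::as_tibble(points)
  if (!all(c("x", "y", "z") %in% names(pts))) {
    stop("a point cloud needs columns x, y, z")
  }
  if (nrow(pts) && !all(is.finite(pts$x) & is.finite(pts$y) & is.finite(pts$z))) {
    stop("point cloud contains non-finite coordinates")
  }
  pts
}

# round-half-away-from-zero (base round() is round-half-even)
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Render a point cloud into a depth image
#'
#' Projects every point with the camera model, rounds to the nearest pixel
#' (half away from zero), and writes the positive depth `-z` into that
#' pixel. When several points land on the same pixel the nearest point to
#' the camera wins (smallest `-z`, physical occlusion). Pixels hit by no
#' point are 0, the background/invalid code. Points projecting outside the
#' sensor are dropped.
#'
#' @param points A point cloud (all `z < 0`).
#' @param cam A [camera_intrinsics()].
#' @return A `depth_image`: a `height x width` numeric matrix of depths in
#'   meters (0 = background), with the intrinsics attached as attribute
#'   `cam`.
#' @export
render_depth_image <- function(points, cam) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  pts <- as_point_cloud(points)
  img <- matrix(0, nrow = cam$height, ncol = cam$width)
  if (nrow(pts)) {
    if (any(pts$z >= 0)) stop("render_depth_image requires all points at z < 0")
    uv <- project_points(pts, cam)
    ui <- round_half_away(uv$u)
    vi <- round_half_away(uv$v)
    keep <- ui >= 0 & ui < cam$width & vi >= 0 & vi < cam$height
    if (any(keep)) {
      d <- -pts$z[keep]
      idx <- vi[keep] + 1 + ui[keep] * cam$height  # column-major linear index
      ord <- order(d, decreasing = TRUE)           # nearest written last wins
      img[idx[ord]] <- d[ord]
    }
  }
  new_depth_image(img, cam)
}

new_depth_image <- function(mat, cam = NULL) {
  structure(mat, cam = cam, class = c("depth_image", "matrix", "array"))
}

#' @export
print.depth_image <- function(x, ...) {
  nz <- sum(x > 0)
  cat(sprintf(
    "<depth_image> %dx%d px, %d foreground px, depth range [%.3f, %.3f] m\n",
    ncol(x), nrow(x), nz,
    if (nz) min(x[x > 0]) else NA_real_, if (nz) max(x) else NA_real_
  ))
  invisible(x)
}

#' @describeIn render_depth_image Plot a depth image as a raster.
#' @param object,... autoplot arguments.
#' @export
autoplot.depth_image <- function(object, ...) {
  df <- tidyr::expand_grid(
    v = seq_len(nrow(object)) - 1L,
    u = seq_len(ncol(object)) - 1L
  )
  df$depth <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v, fill = .data$depth)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "u [px]", y = "v [px]", fill = "depth [m]")
}
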