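#' Moving-least-squares smoothing of a point cloud
#'
#' Replaces every point by its projection onto a local least-squares plane
#' (order-1 fit, uniform weights) through its neighbors within
#' `radius`. Points with fewer than 3 neighbors (including themselves)
#' pass through unchanged, so the point count is preserved.
#'
#' @param points A point cloud tibble; extra columns are preserved.
#' @param radius Neighborhood search radius in meters (default 0.03).
#' @return A point cloud tibble of the same size.
#' @export
smooth_mls <- function(points, radius = 0.03) {
  pts <- as_point_cloud(points)
  n <- nrow(pts)
  if (n == 0) stop("cannot smooth an empty cloud")
  P <- cbind(pts$x, pts$y, pts$z)
  # fixed-radius neighbor pairs via a uniform grid of cell size = radius
  cell <- floor(P / radius)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  ukey <- unique(key)
  grp <- split(seq_len(n), factor(key, levels = ukey))
  sizes <- lengths(grp)
  i_all <- vector("list", 27L); j_all <- vector("list", 27L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- k + 1L
    g <- match(paste(cell[, 1] + dx, cell[, 2] + dy, cell[, 3] + dz), ukey)
    hit <- which(!is.na(g))
    i_all[[k]] <- rep(hit, sizes[g[hit]])
    j_all[[k]] <- unlist(grp[g[hit]], use.names = FALSE)
  }
  i <- unlist(i_all); j <- unlist(j_all)
  d2 <- (P[i, 1] - P[j, 1])^2 + (P[i, 2] - P[j, 2])^2 + (P[i, 3] - P[j, 3])^2
  keep <- d2 <= radius^2
  i <- i[keep]; j <- j[keep]
  # per-point neighborhood moments
  M <- rowsum(
    cbind(1, P[j, 1], P[j, 2], P[j, 3],
          P[j, 1]^2, P[j, 1] * P[j, 2], P[j, 1] * P[j, 3],
          P[j, 2]^2, P[j, 2] * P[j, 3], P[j, 3]^2),
    i
  )
  pid <- as.integer(rownames(M))
  np <- M[, 1]
  mx <- M[, 2] / np; my <- M[, 3] / np; mz <- M[, 4] / np
  a <- M[, 5] / np - mx^2; b <- M[, 6] / np - mx * my; c <- M[, 7] / np - mx * mz
  d <- M[, 8] / np - my^2; e <- M[, 9] / np - my * mz; f <- M[, 10] / np - mz^2
  # smallest eigenvector of the covariance = dominant eigenvector of its
  # adjugate; power iteration, exact for rank-2 (planar) neighborhoods
  A11 <- d * f - e^2; A12 <- c * e - b * f; A13 <- b * e - c * d
  A22 <- a * f - c^2; A23 <- b * c - a * e; A33 <- a * d - b^2
  nrm1 <- sqrt(A11^2 + A12^2 + A13^2)
  nrm2 <- sqrt(A12^2 + A22^2 + A23^2)
  nrm3 <- sqrt(A13^2 + A23^2 + A33^2)
  pickc <- max.col(cbind(nrm1, nrm2, nrm3), ties.method = "first")
  vx <- ifelse(pickc == 1, A11, ifelse(pickc == 2, A12, A13))
  vy <- ifelse(pickc == 1, A12, ifelse(pickc == 2, A22, A23))
  vz <- ifelse(pickc == 1, A13, ifelse(pickc == 2, A23, A33))
  for (it in 1:3) {
    wx <- A11 * vx + A12 * vy + A13 * vz
    wy <- A12 * vx + A22 * vy + A23 * vz
    wz <- A13 * vx + A23 * vy + A33 * vz
    len <- sqrt(wx^2 + wy^2 + wz^2)
    ok <- len > 0
    vx <- ifelse(ok, wx / len, vx)
    vy <- ifelse(ok, wy / len, vy)
    vz <- ifelse(ok, wz / len, vz)
  }
  vlen <- sqrt(vx^2 + vy^2 + vz^2)
  good <- np >= 3 & vlen > 0.5  # skip degenerate (isotropic) neighborhoods
  vx <- vx / pmax(vlen, 1e-300); vy <- vy / pmax(vlen, 1e-300); vz <- vz / pmax(vlen, 1e-300)
  proj <- (P[pid, 1] - mx) * vx + (P[pid, 2] - my) * vy + (P[pid, 3] - mz) * vz
  upd <- pid[good]
  P[upd, 1] <- P[upd, 1] - proj[good] * vx[good]
  P[upd, 2] <- P[upd, 2] - proj[good] * vy[good]
  P[upd, 3] <- P[upd, 3] - proj[good] * vz[good]
  pts$x <- P[, 1]; pts$y <- P[, 2]; pts$z <- P[, 3]
  pts
}

fit_plane_lsq <- function(P) {
  ctr <- colMeans(P)
  C <- crossprod(sweep(P, 2, ctr))
  nrm <- eigen(C, symmetric = TRUE)$vectors[, 3]
  c(nrm, -sum(nrm * ctr))
}

#' Remove the dominant plane (floor) via RANSAC
#'
#' Fits the dominant plane of the cloud with random sample consensus
#' (minimal 3-point samples, inliers within `dist_thresh`, the candidate
#' with the most inliers wins, ties keep the first found), refines it by a
#' total least-squares fit on the inlier set, and removes all points within
#' `dist_thresh` of the refined plane.
#'
#' @param points A point cloud with at least 3 points.
#' @param dist_thresh Inlier distance threshold in meters (default 0.02).
#' @param iterations Number of RANSAC hypotheses (default 1000).
#' @param seed Optional integer seed making the inlier set reproducible.
#' @param axis Optional unit axis the plane normal must align with (e.g.
#'   `c(0, 1, 0)` to accept only horizontal, floor-like planes); `NULL`
#'   accepts the dominant plane of any orientation.
#' @param eps_angle Maximum angle (degrees) between plane normal and `axis`.
#' @param min_inlier_frac Minimum inlier fraction for the plane to be
#'   removed at all; below it the cloud is returned unchanged (guards a
#'   floor-free scene against losing part of the person).
#' @return The remaining points, with attributes `plane` (unit-normal
#'   coefficients `(a, b, c, d)` of `ax + by + cz + d = 0`), `inliers`
#'   (indices of the removed points in the input) and `n_removed`.
#' @export
remove_floor_plane <- function(points, dist_thresh = 0.02, iterations = 1000,
                               seed = NULL, axis = NULL, eps_angle = 30,
                               min_inlier_frac = 0) {
  pts <- as_point_cloud(points)
  n <- nrow(pts)
  if (n < 3) stop("plane segmentation needs at least 3 points")
  P <- cbind(pts$x, pts$y, pts$z)
  cos_eps <- cos(eps_angle * pi / 180)
  run <- function() {
    best_count <- -1L
    best_plane <- NULL
    for (it in seq_len(iterations)) {
      s <- sample.int(n, 3L)
      v1 <- P[s[2], ] - P[s[1], ]
      v2 <- P[s[3], ] - P[s[1], ]
      nrm <- c(
        v1[2] * v2[3] - v1[3] * v2[2],
        v1[3] * v2[1] - v1[1] * v2[3],
        v1[1] * v2[2] - v1[2] * v2[1]
      )
      len <- sqrt(sum(nrm^2))
      if (len < 1e-12) next
      nrm <- nrm / len
      if (!is.null(axis) && abs(sum(nrm * axis)) < cos_eps) next
      d <- -sum(nrm * P[s[1], ])
      cnt <- sum(abs(P %*% nrm + d) <= dist_thresh)
      if (cnt > best_count) {
        best_count <- cnt
        best_plane <- c(nrm, d)
      }
    }
    best_plane
  }
  plane <- if (is.null(seed)) run() else with_local_seed(seed, run())
  if (is.null(plane)) {  # no admissible hypothesis (axis constraint)
    attr(pts, "plane") <- NULL
    attr(pts, "inliers") <- integer(0)
    attr(pts, "n_removed") <- 0L
    return(pts)
  }
  # refine on the consensus set (total least squares), as PCL does
  inl <- which(abs(P %*% plane[1:3] + plane[4]) <= dist_thresh)
  if (length(inl) >= 3) {
    plane <- fit_plane_lsq(P[inl, , drop = FALSE])
    inl <- which(abs(P %*% plane[1:3] + plane[4]) <= dist_thresh)
  }
  if (length(inl) < min_inlier_frac * n) {
    attr(pts, "plane") <- plane
    attr(pts, "inliers") <- integer(0)
    attr(pts, "n_removed") <- 0L
    return(pts)
  }
  out <- pts[setdiff(seq_len(n), inl), , drop = FALSE]
  attr(out, "plane") <- plane
  attr(out, "inliers") <- inl
  attr(out, "n_removed") <- length(inl)
  out
}

# evaluate code with a temporary RNG state, restoring the caller's
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Lateral (x-axis) crop of a point cloud
#'
#' Retains points with `x_min <= x <= x_max`. The defaults keep a 2 m wide
#' corridor around the walkway axis.
#'
#' @param points A point cloud.
#' @param x_min,x_max Bounds in meters, `x_min < x_max`.
#' @return The retained points.
#' @export
crop_lateral <- function(points, x_min = -1, x_max = 1) {
  if (!(x_min < x_max)) stop("x_min must be smaller than x_max")
  pts <- as_point_cloud(points)
  pts[pts$x >= x_min & pts$x <= x_max, , drop = FALSE]
}

#' Centre-of-mass depth crop
#'
#' Computes the depth centre of mass (mean `z` over all remaining points,
#' taken to represent the person) and removes points farther than `thresh`
#' from it along the depth axis. The interval is closed: points exactly at
#' the threshold distance are retained.
#'
#' @param points A nonempty point cloud.
#' @param thresh Depth threshold in meters (default 0.5, i.e. 50 cm).
#' @return The retained points, with the centre of mass as attribute
#'   `z_com`.
#' @export
crop_depth_com <- function(points, thresh = 0.5) {
  pts <- as_point_cloud(points)
  if (nrow(pts) == 0) stop("cannot take the depth centre of mass of an empty cloud")
  z_com <- mean(pts$z)
  out <- pts[abs(pts$z - z_com) <= thresh, , drop = FALSE]
  attr(out, "z_com") <- z_com
  out
}

#' Normalize a depth image to gray values
#'
#' Maps the nonzero (foreground) depths linearly to the integer range
#' `[1, 255]` (min depth to 1, max depth to 255) and keeps background
#' pixels at exactly 0, so foreground is never confused with background.
#' A constant nonzero depth maps to 255.
#'
#' @param depth A `depth_image` or numeric matrix (meters, 0 = background)
#'   with at least one nonzero pixel.
#' @return An integer matrix of gray values in `[0, 255]`, with the mapped
#'   depth range attached as attribute `norm`
#'   (`list(min_depth, max_depth)`).
#' @export
normalize_depth_to_gray <- function(depth) {
  m <- unclass(depth)
  stopifnot(is.matrix(m))
  fg <- m > 0
  if (!any(fg)) stop("cannot normalize an all-background depth image")
  lo <- min(m[fg]); hi <- max(m[fg])
  g <- matrix(0L, nrow(m), ncol(m))
  g[fg] <- if (hi > lo) as.integer(round(1 + 254 * (m[fg] - lo) / (hi - lo))) else 255L
  attr(g, "norm") <- list(min_depth = lo, max_depth = hi)
  g
}

#' Crop transform between original and model-input coordinates
#'
#' Records the clipping window and scaling factor of [crop_and_scale()]:
#' a model-input coordinate `m` maps back to the original image as
#' `m / scale + offset` (see [map_to_original()]).
#'
#' @param scale Uniform scale factor (> 0), model pixels per original pixel.
#' @param offset_u,offset_v Top-left corner of the clipping window in the
#'   original image (pixels; may be negative when padding was needed).
#' @param crop_w,crop_h Clipping-window size in original pixels (3:4).
#' @return A `crop_transform` object.
#' @export
crop_transform <- function(scale, offset_u, offset_v, crop_w, crop_h) {
  stopifnot(scale > 0, crop_w > 0, crop_h > 0)
  structure(
    list(scale = scale, offset_u = offset_u, offset_v = offset_v,
         crop_w = crop_w, crop_h = crop_h),
    class = "crop_transform"
  )
}

#' @export
print.crop_transform <- function(x, ...) {
  cat(sprintf("<crop_transform> scale=%.4g, offset=(%g, %g), window %gx%g px\n",
              x$scale, x$offset_u, x$offset_v, x$crop_w, x$crop_h))
  invisible(x)
}

new_model_input <- function(image, transform, norm = NULL) {
  structure(list(image = image, transform = transform, norm = norm),
            class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  cat(sprintf("<model_input> %dx%d gray image, %d foreground px\n",
              ncol(x$image), nrow(x$image), sum(x$image > 0)))
  print(x$transform)
  invisible(x)
}

#' Crop to the person and scale to the model-input size
#'
#' Finds the bounding box of all nonzero pixels, expands it symmetrically
#' to the model aspect ratio of 3:4 (padding with background 0 where the
#' window exceeds the image), and resamples the window to
#' `width x height` with nearest-neighbor interpolation. The clipping
#' window and scale factor are returned as an invertible
#' [crop_transform()] for coordinate reconstruction.
#'
#' @param gray An integer gray image (matrix, 0 = background) with at least
#'   one nonzero pixel.
#' @param width,height Model-input size in pixels (default 288 x 384).
#' @return A `model_input`: list with elements `image`
#'   (`height x width` integer matrix), `transform` and `norm` (taken from
#'   the `norm` attribute of `gray`, if any).
#' @export
crop_and_scale <- function(gray, width = 288L, height = 384L) {
  stopifnot(is.matrix(gray))
  nz <- which(gray > 0, arr.ind = TRUE)
  if (!nrow(nz)) stop("cannot crop an all-background image")
  v0 <- min(nz[, 1]) - 1L; v1 <- max(nz[, 1]) - 1L  # 0-based rows (v)
  u0 <- min(nz[, 2]) - 1L; u1 <- max(nz[, 2]) - 1L
  bw <- u1 - u0 + 1L; bh <- v1 - v0 + 1L
  # smallest window with exact width:height aspect covering the box
  aw <- width / gcd_int(width, height); ah <- height / gcd_int(width, height)
  base <- max(ceiling(bw / aw), ceiling(bh / ah))
  crop_w <- aw * base; crop_h <- ah * base
  offset_u <- u0 - floor((crop_w - bw) / 2)
  offset_v <- v0 - floor((crop_h - bh) / 2)
  scale <- width / crop_w
  # nearest-neighbor source index per model pixel (centre sampling)
  src_u <- offset_u + floor((seq_len(width) - 0.5) / scale)
  src_v <- offset_v + floor((seq_len(height) - 0.5) * crop_h / height)
  ok_u <- src_u >= 0 & src_u < ncol(gray)
  ok_v <- src_v >= 0 & src_v < nrow(gray)
  img <- matrix(0L, height, width)
  img[ok_v, ok_u] <- gray[src_v[ok_v] + 1L, src_u[ok_u] + 1L]
  new_model_input(
    img,
    crop_transform(scale, offset_u, offset_v, crop_w, crop_h),
    attr(gray, "norm")
  )
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Map model-input coordinates back to the original image
#'
#' Inverts the crop-and-scale step: `original = model / scale + offset`.
#' Works on any data frame with pixel columns `u`, `v` (e.g. decoded
#' detections).
#'
#' @param detections A data frame with numeric columns `u`, `v` in
#'   model-input pixels.
#' @param transform The [crop_transform()] from the same preprocessing run.
#' @return The input tibble with `u`, `v` replaced by original-image
#'   coordinates.
#' @export
map_to_original <- function(detections, transform) {
  stopifnot(inherits(transform, "crop_transform"))
  det <- tibble::as_tibble(detections)
  det$u <- det$u / transform$scale + transform$offset_u
  det$v <- det$v / transform$scale + transform$offset_v
  det
}

#' Model-input tensor normalization
#'
#' Replicates the gray image to 3 channels, scales to `[0, 1]` and
#' standardizes per channel with the ImageNet means (0.485, 0.456, 0.406)
#' and standard deviations (0.229, 0.224, 0.225) expected by
#' ResNet-backbone pose models.
#'
#' @param input A `model_input`.
#' @return A numeric array of shape `3 x height x width`.
#' @export
to_model_tensor <- function(input) {
  stopifnot(inherits(input, "model_input"))
  mu <- c(0.485, 0.456, 0.406)
  sd <- c(0.229, 0.224, 0.225)
  g <- input$image / 255
  arr <- array(0, c(3L, nrow(g), ncol(g)))
  for (c in 1:3) arr[c, , ] <- (g - mu[c]) / sd[c]
  arr
}

#' Preprocessing configuration
#'
#' Collects the tunable parameters of [preprocess_scene()]. Defaults follow
#' the pipeline's reference settings: MLS radius 0.03 m, RANSAC plane
#' threshold 0.02 m, 50 cm centre-of-mass depth crop, lateral corridor
#' +/- 1 m, model input 288 x 384.
#'
#' In the pipeline the floor plane is constrained to be floor-like: its
#' normal must lie within `floor_eps_angle` of the vertical axis and it
#' must support at least `floor_min_frac` of the points, so a scene without
#' a visible floor does not lose part of the person instead.
#'
#' @param mls_radius MLS search radius in meters; `NA` disables smoothing.
#' @param plane_dist RANSAC inlier threshold in meters; `NA` disables floor
#'   removal.
#' @param floor_eps_angle Maximum deviation (degrees) of the floor normal
#'   from vertical.
#' @param floor_min_frac Minimum inlier fraction for floor removal.
#' @param x_bounds Length-2 lateral crop bounds in meters; `NULL` disables.
#' @param z_crop Centre-of-mass depth threshold in meters; `NA` disables.
#' @param input_w,input_h Model-input size in pixels.
#' @param ransac_iters RANSAC hypothesis count.
#' @param seed Optional seed for the RANSAC sampler.
#' @return A named list of class `preprocess_config`.
#' @export
preprocess_config <- function(mls_radius = 0.03, plane_dist = 0.02,
                              x_bounds = c(-1, 1), z_crop = 0.5,
                              input_w = 288L, input_h = 384L,
                              ransac_iters = 1000L, seed = NULL,
                              floor_eps_angle = 30, floor_min_frac = 0.15) {
  structure(
    list(mls_radius = mls_radius, plane_dist = plane_dist,
         x_bounds = x_bounds, z_crop = z_crop,
         input_w = as.integer(input_w), input_h = as.integer(input_h),
         ransac_iters = as.integer(ransac_iters), seed = seed,
         floor_eps_angle = floor_eps_angle, floor_min_frac = floor_min_frac),
    class = "preprocess_config"
  )
}

#' Full scene preprocessing pipeline
#'
#' Chains MLS smoothing, RANSAC floor removal, the lateral crop, the
#' centre-of-mass depth crop, depth-image rendering, gray normalization and
#' the crop-and-scale step into one call, logging point/pixel counts per
#' stage. Any stage failure is re-raised with the stage name.
#'
#' @param points A scene point cloud (tibble `x`, `y`, `z`).
#' @param cam A [camera_intrinsics()].
#' @param config A [preprocess_config()].
#' @return A `model_input`, with a per-stage count log attached as
#'   attribute `log` (tibble `stage`, `n`).
#' @export
preprocess_scene <- function(points, cam, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  pts <- as_point_cloud(points)
  log <- list(tibble::tibble(stage = "input", n = nrow(pts)))
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop("preprocessing stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    n <- if (is.data.frame(res)) nrow(res)
    else if (inherits(res, "model_input")) sum(res$image > 0)
    else sum(unclass(res) > 0)
    log[[length(log) + 1L]] <<- tibble::tibble(stage = name, n = as.integer(n))
    res
  }
  if (!is.na(config$mls_radius)) {
    pts <- stage("smooth_mls", function() smooth_mls(pts, config$mls_radius))
  }
  if (!is.na(config$plane_dist)) {
    pts <- stage("remove_floor_plane", function() {
      remove_floor_plane(pts, config$plane_dist, config$ransac_iters,
                         config$seed, axis = c(0, 1, 0),
                         eps_angle = config$floor_eps_angle,
                         min_inlier_frac = config$floor_min_frac)
    })
  }
  if (!is.null(config$x_bounds)) {
    pts <- stage("crop_lateral", function() {
      crop_lateral(pts, config$x_bounds[1], config$x_bounds[2])
    })
  }
  if (!is.na(config$z_crop)) {
    pts <- stage("crop_depth_com", function() crop_depth_com(pts, config$z_crop))
  }
  depth <- stage("render_depth_image", function() render_depth_image(pts, cam))
  gray <- stage("normalize_depth_to_gray", function() normalize_depth_to_gray(depth))
  out <- stage("crop_and_scale", function() {
    crop_and_scale(gray, config$input_w, config$input_h)
  })
  attr(out, "log") <- dplyr::bind_rows(log)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
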