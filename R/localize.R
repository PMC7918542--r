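#' Attach 3D positions to detections from the depth image
#'
#' For every detection in original-image coordinates, reads the sensor
#' depth at the rounded pixel and back-projects to 3D, reported in
#' centimeters. A sensor reading of zero marks an invalid depth: the joint
#' is flagged invalid and excluded from downstream error summaries, as is
#' any detection falling outside the image.
#'
#' The depth lookup uses the single rounded pixel (no neighborhood
#' pooling), matching the premise that one zero reading invalidates the
#' joint.
#'
#' @param detections A tibble with columns `u`, `v` in original-image
#'   pixels (e.g. from [map_to_original()]).
#' @param depth The scene `depth_image` (meters, 0 = invalid).
#' @param cam The [camera_intrinsics()] of the depth image.
#' @return The detections with columns `x_cm`, `y_cm`, `z_cm` (camera
#'   frame, `z_cm < 0`) and a logical `valid` flag (`NA` positions when
#'   invalid).
#' @export
localize_keypoints <- function(detections, depth, cam) {
  det <- tibble::as_tibble(detections)
  stopifnot(all(c("u", "v") %in% names(det)))
  m <- unclass(depth)
  ui <- round_half_away(det$u)
  vi <- round_half_away(det$v)
  inside <- ui >= 0 & ui < ncol(m) & vi >= 0 & vi < nrow(m)
  d <- rep(0, nrow(det))
  d[inside] <- m[cbind(vi[inside] + 1L, ui[inside] + 1L)]
  valid <- inside & d > 0
  det$x_cm <- det$y_cm <- det$z_cm <- NA_real_
  if (any(valid)) {
    p <- backproject_pixels(
      tibble::tibble(u = det$u[valid], v = det$v[valid], depth = d[valid]), cam
    )
    det$x_cm[valid] <- p$x * 100
    det$y_cm[valid] <- p$y * 100
    det$z_cm[valid] <- p$z * 100
  }
  det$valid <- valid
  det
}

#' Per-axis spatial errors of localized detections
#'
#' Pairs localized detections with reference 3D positions (by `keypoint`
#' and, when present, `image_id`) and computes the absolute per-axis error
#' in centimeters: lateral (x), height (y) and depth (z). Only valid-depth
#' detections are paired; the fraction excluded for invalid depth is
#' attached as attribute `invalid_fraction`.
#'
#' @param detections3d Output of [localize_keypoints()] (columns `keypoint`,
#'   `x_cm`, `y_cm`, `z_cm`, `valid`, optionally `image_id`).
#' @param references3d Reference positions with the same columns
#'   (centimeters).
#' @return A tibble with one row per paired keypoint and columns
#'   `keypoint`, `ex`, `ey`, `ez` (absolute errors, cm).
#' @export
spatial_errors <- function(detections3d, references3d) {
  det <- tibble::as_tibble(detections3d)
  ref <- tibble::as_tibble(references3d)
  keys <- intersect(c("image_id", "keypoint"), intersect(names(det), names(ref)))
  if (!"keypoint" %in% keys) stop("both inputs need a keypoint column")
  n_all <- nrow(det)
  if ("valid" %in% names(det)) det <- det[det$valid, , drop = FALSE]
  invalid_fraction <- if (n_all) 1 - nrow(det) / n_all else 0
  if ("valid" %in% names(ref)) ref <- ref[ref$valid, , drop = FALSE]
  pair <- dplyr::inner_join(
    det, ref,
    by = keys, suffix = c("", ".ref"), relationship = "one-to-one"
  )
  out <- tibble::tibble(
    keypoint = pair$keypoint,
    ex = abs(pair$x_cm - pair$x_cm.ref),
    ey = abs(pair$y_cm - pair$y_cm.ref),
    ez = abs(pair$z_cm - pair$z_cm.ref)
  )
  if ("image_id" %in% keys) out <- dplyr::bind_cols(tibble::tibble(image_id = pair$image_id), out)
  attr(out, "invalid_fraction") <- invalid_fraction
  out
}

#' Summarize spatial errors per keypoint and axis
#'
#' Computes, per keypoint and axis, the median absolute error plus Tukey
#' boxplot statistics (quartiles, 1.5 x IQR whiskers, outlier count).
#'
#' @param errors A [spatial_errors()] tibble (columns `keypoint`, `ex`,
#'   `ey`, `ez`); must be nonempty.
#' @return A tibble with columns `keypoint`, `axis` (`"x"`, `"y"`, `"z"`),
#'   `n`, `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `n_outliers`, in centimeters.
#' @export
spatial_error_summary <- function(errors) {
  err <- tibble::as_tibble(errors)
  if (!nrow(err)) stop("no paired keypoints: spatial error summary undefined")
  long <- tidyr::pivot_longer(
    err[, c("keypoint", "ex", "ey", "ez")],
    cols = c("ex", "ey", "ez"), names_to = "axis", values_to = "error"
  )
  long$axis <- substring(long$axis, 2)
  dplyr::summarise(
    dplyr::group_by(long, .data$keypoint, .data$axis),
    n = dplyr::n(),
    median = stats::median(.data$error),
    q1 = stats::quantile(.data$error, 0.25, names = FALSE),
    q3 = stats::quantile(.data$error, 0.75, names = FALSE),
    whisker_low = {
      b <- grDevices::boxplot.stats(.data$error)$stats
      b[1]
    },
    whisker_high = grDevices::boxplot.stats(.data$error)$stats[5],
    n_outliers = length(grDevices::boxplot.stats(.data$error)$out),
    .groups = "drop"
  )
}

#' @describeIn spatial_error_summary Boxplots of per-keypoint axis errors.
#' @param object,... autoplot arguments (`object` is a [spatial_errors()]
#'   tibble).
#' @export
plot_spatial_errors <- function(object, ...) {
  err <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(
    err[, c("keypoint", "ex", "ey", "ez")],
    cols = c("ex", "ey", "ez"), names_to = "axis", values_to = "error"
  )
  long$axis <- c(ex = "lateral (x)", ey = "height (y)", ez = "depth (z)")[long$axis]
  long$keypoint <- factor(long$keypoint, levels = keypoint_names())
  ggplot2::ggplot(long, ggplot2::aes(.data$keypoint, .data$error)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "absolute error [cm]") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
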