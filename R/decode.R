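#' Decode heatmaps into keypoint detections
#'
#' Per keypoint map, the location of the maximum value is taken as the
#' detection and the maximum itself as the confidence score. Ties are
#' broken row-major (smallest `v`, then smallest `u`), so a constant map
#' decodes to (0, 0). Coordinates are scaled from the heatmap frame to the
#' model-input frame by the resolution ratio `scale` (4 for the 72 x 96 /
#' 288 x 384 convention).
#'
#' With `refine = TRUE` a log-parabolic sub-pixel interpolation through the
#' peak and its 4-neighborhood is applied before scaling; this is exact for
#' Gaussian-shaped peaks. The default is the plain integer argmax.
#'
#' @param stack A `heatmap_stack`.
#' @param scale Model-input pixels per heatmap pixel (default 4).
#' @param refine Apply sub-pixel peak refinement? Default `FALSE`.
#' @return A tibble with columns `keypoint`, `u`, `v` (model-input frame),
#'   `hu`, `hv` (heatmap frame) and `score`.
#' @export
decode_heatmaps <- function(stack, scale = 4, refine = FALSE) {
  stopifnot(inherits(stack, "heatmap_stack"))
  h <- dim(stack)[1]; w <- dim(stack)[2]
  res <- purrr::map_dfr(1:17, function(i) {
    m <- stack[, , i]
    mx <- max(m)
    hits <- which(m == mx, arr.ind = TRUE)
    hit <- hits[order(hits[, 1], hits[, 2])[1], ]  # smallest v, then u
    hv <- unname(hit[1]) - 1
    hu <- unname(hit[2]) - 1
    if (refine) {
      hu <- hu + subpixel_offset(m[hv + 1, ], hu, w)
      hv <- hv + subpixel_offset(m[, hu_round(hu, w) + 1], unname(hit[1]) - 1, h)
    }
    tibble::tibble(keypoint = keypoint_names()[i], hu = hu, hv = hv, score = mx)
  })
  res$u <- res$hu * scale
  res$v <- res$hv * scale
  res[, c("keypoint", "u", "v", "hu", "hv", "score")]
}

hu_round <- function(x, w) min(max(round(x), 0), w - 1)

# vertex of the parabola through log-values at (peak-1, peak, peak+1);
# exact for an un-truncated Gaussian profile
subpixel_offset <- function(profile, peak0, n) {
  i <- peak0 + 1L
  if (i <= 1L || i >= n) return(0)
  l <- profile[i - 1L]; c <- profile[i]; r <- profile[i + 1L]
  if (l <= 0 || c <= 0 || r <= 0) return(0)
  ll <- log(l); lc <- log(c); lr <- log(r)
  den <- ll + lr - 2 * lc
  if (den >= 0) return(0)
  off <- 0.5 * (ll - lr) / den
  min(max(off, -0.5), 0.5)
}

#' Build an ROC curve over detection scores
#'
#' Computes the receiver operating characteristic of "predict visible when
#' `score > t`" over all unique score thresholds, with the end points
#' (fpr, tpr) = (0, 0) (threshold at the maximum score) and (1, 1)
#' (threshold below all scores) included.
#'
#' @param scores A data frame with columns `score` (numeric) and `visible`
#'   (logical or 0/1 reference class); both classes must be present.
#' @return A `roc_curve`: a tibble with columns `threshold`, `fpr`, `tpr`
#'   ordered by decreasing threshold, with the trapezoidal AUC as
#'   attribute `auc`.
#' @export
build_roc <- function(scores) {
  sc <- tibble::as_tibble(scores)
  stopifnot(all(c("score", "visible") %in% names(sc)))
  vis <- as.logical(sc$visible > 0)
  n_pos <- sum(vis); n_neg <- sum(!vis)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one visible and one occluded example")
  }
  th <- c(sort(unique(sc$score), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) sum(sc$score[vis] > t) / n_pos, numeric(1))
  fpr <- vapply(th, function(t) sum(sc$score[!vis] > t) / n_neg, numeric(1))
  curve <- tibble::tibble(threshold = th, fpr = fpr, tpr = tpr)
  # trapezoid over points ordered by increasing fpr = decreasing threshold
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(curve, auc = auc, n_pos = n_pos, n_neg = n_neg,
            class = c("roc_curve", class(curve)))
}

#' Select the operating threshold of an ROC curve
#'
#' Chooses the threshold minimizing the Euclidean distance
#' `sqrt((1 - tpr)^2 + fpr^2)` of the operating point to the ideal corner
#' (fpr, tpr) = (0, 1). Ties are resolved toward the larger threshold (the
#' more conservative visibility verdict).
#'
#' @param roc A [build_roc()] curve.
#' @return The selected threshold, with its `fpr`, `tpr` and `dist`
#'   attached as attributes.
#' @export
select_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  dist <- sqrt((1 - roc$tpr)^2 + roc$fpr^2)
  best <- which(dist == min(dist))
  pick <- best[which.max(roc$threshold[best])]
  structure(roc$threshold[pick],
            fpr = roc$fpr[pick], tpr = roc$tpr[pick], dist = dist[pick])
}

#' @export
tidy.roc_curve <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, fpr = x$fpr, tpr = x$tpr,
                 dist = sqrt((1 - x$tpr)^2 + x$fpr^2))
}

#' @export
glance.roc_curve <- function(x, ...) {
  t_star <- select_threshold(x)
  tibble::tibble(
    auc = attr(x, "auc"),
    threshold = as.numeric(t_star),
    fpr = attr(t_star, "fpr"),
    tpr = attr(t_star, "tpr"),
    dist = attr(t_star, "dist"),
    n_visible = attr(x, "n_pos"),
    n_occluded = attr(x, "n_neg")
  )
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted", colour = "grey50") +
    ggplot2::annotate("point", x = g$fpr, y = g$tpr, colour = "red") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUC %.3f, threshold %.3g (fpr %.3f, tpr %.3f)",
                      g$auc, g$threshold, g$fpr, g$tpr)
    )
}

#' Apply the visibility threshold to decoded detections
#'
#' A keypoint is accepted as visible when its confidence score strictly
#' surpasses the threshold; keypoints at or below it are rejected as
#' occluded.
#'
#' @param detections A decoded detections tibble (column `score`).
#' @param threshold The operating threshold (e.g. from
#'   [select_threshold()]).
#' @return The detections with a logical `visible` verdict column.
#' @export
filter_visibility <- function(detections, threshold) {
  det <- tibble::as_tibble(detections)
  det$visible <- det$score > as.numeric(threshold)
  det
}

#' Export detections as COCO results JSON and a verdict CSV
#'
#' @param detections A tibble with columns `image_id`, `keypoint`, `u`,
#'   `v`, `score` and (optionally) `visible`.
#' @param json_path,csv_path Output paths (`NULL` skips that file).
#' @return The input, invisibly.
#' @export
write_detections <- function(detections, json_path = NULL, csv_path = NULL) {
  det <- tibble::as_tibble(detections)
  if (!is.null(json_path)) {
    per_img <- split(det, det$image_id)
    res <- lapply(per_img, function(d) {
      d <- d[match(keypoint_names(), d$keypoint), ]
      list(
        image_id = d$image_id[1], category_id = 1L,
        keypoints = as.vector(rbind(d$u, d$v, d$score)),
        score = mean(d$score)
      )
    })
    jsonlite::write_json(unname(res), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) utils::write.csv(det, csv_path, row.names = FALSE)
  invisible(det)
}
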