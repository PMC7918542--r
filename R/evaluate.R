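#' Object keypoint similarity (OKS)
#'
#' Similarity between a detected and an annotated keypoint set:
#' `OKS = sum_i exp(-d_i^2 / (2 s^2 k_i^2)) [v_i > 0] / sum_i [v_i > 0]`,
#' where `d_i` is the Euclidean pixel distance between detection and
#' annotation, `s^2` the person area in pixels, `k_i = 2 sigma_i` the
#' per-keypoint falloff constant, and only annotated/visible keypoints
#' enter the sums. 1 means perfectly recognized keypoints, values near 0
#' complete delocation.
#'
#' @param detection A data frame with columns `keypoint`, `u`, `v` (pixels).
#' @param annotation A data frame with columns `keypoint`, `u`, `v`,
#'   `visible`; at least one keypoint must be visible.
#' @param area Person area `s^2` in pixels squared; defaults to the
#'   `area` column of `annotation` if present.
#' @param scheme The keypoint scheme with falloff constants
#'   ([coco_keypoints()]).
#' @return A scalar in `[0, 1]`.
#' @export
oks <- function(detection, annotation, area = NULL, scheme = coco_keypoints()) {
  det <- tibble::as_tibble(detection)
  ann <- tibble::as_tibble(annotation)
  if (is.null(area)) {
    if (!"area" %in% names(ann)) stop("supply `area` or an annotation area column")
    area <- ann$area[1]
  }
  if (!is.finite(area) || area <= 0) stop("person area must be positive")
  vis <- ann$visible > 0
  if (!any(vis)) stop("OKS undefined: annotation has no visible keypoint")
  m <- match(ann$keypoint[vis], det$keypoint)
  if (anyNA(m)) stop("detection is missing keypoints present in the annotation")
  k <- scheme$k[match(ann$keypoint[vis], scheme$keypoint)]
  d2 <- (det$u[m] - ann$u[vis])^2 + (det$v[m] - ann$v[vis])^2
  mean(exp(-d2 / (2 * area * k^2)))
}

# ---- COCO-style AP/AR ------------------------------------------------------

# per-image greedy matching at one OKS threshold; gts carry an ignore flag
match_image <- function(oks_mat, det_scores, gt_ignore, thr) {
  nd <- nrow(oks_mat); ng <- ncol(oks_mat)
  gt_taken <- rep(FALSE, ng)
  det_tp <- rep(FALSE, nd)
  det_ignore <- rep(FALSE, nd)
  for (d in order(-det_scores)) {
    pick_best <- function(pool) {
      ok <- which(pool & !gt_taken & oks_mat[d, ] >= thr)
      if (!length(ok)) return(NA_integer_)
      ok[which.max(oks_mat[d, ok])]
    }
    g <- pick_best(!gt_ignore)
    if (!is.na(g)) {
      gt_taken[g] <- TRUE
      det_tp[d] <- TRUE
    } else {
      g <- pick_best(gt_ignore)
      if (!is.na(g)) {
        gt_taken[g] <- TRUE
        det_ignore[d] <- TRUE
      }
    }
  }
  list(tp = det_tp, ignore = det_ignore)
}

# 101-point interpolated average precision (COCO convention)
ap_101 <- function(tp, scores, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (!length(tp)) return(0)
  ord <- order(-scores)
  ctp <- cumsum(tp[ord]); cfp <- cumsum(!tp[ord])
  rec <- ctp / n_gt
  prec <- ctp / (ctp + cfp)
  for (i in rev(seq_len(length(prec) - 1))) prec[i] <- max(prec[i], prec[i + 1])
  r_grid <- seq(0, 1, by = 0.01)
  idx <- findInterval(r_grid, rec, left.open = TRUE) + 1L  # first rec >= r
  mean(ifelse(idx <= length(prec), prec[idx], 0))
}

#' COCO-style AP/AR evaluation suite
#'
#' Evaluates keypoint detections against annotations with the COCO metric
#' family: average precision and recall over the ten OKS thresholds
#' 0.50, 0.55, ..., 0.95 (`ap`, `ar`), at the single thresholds 0.50 and
#' 0.75 (`ap50`, `ap75`, `ar50`, `ar75`), and restricted to medium
#' (`32^2 < area <= 96^2`) and large (`area > 96^2`) persons (`ap_m`,
#' `ap_l`, `ar_m`, `ar_l`). Matching is greedy per image: detections in
#' decreasing score order each take the unmatched annotation of highest
#' OKS at or above the threshold; annotations outside the evaluated area
#' range are ignored rather than counted. AP uses 101-point interpolated
#' precision; AR is the recall at each threshold averaged over thresholds.
#'
#' @param detections A tibble with one row per (image, detection, keypoint):
#'   columns `image_id`, `det_id`, `keypoint`, `u`, `v`, `score` (the
#'   detection-level confidence, repeated across its keypoints).
#' @param annotations A tibble with one row per (image, annotation,
#'   keypoint): columns `image_id`, `ann_id`, `keypoint`, `u`, `v`,
#'   `visible`, `area`.
#' @param scheme The keypoint scheme ([coco_keypoints()]).
#' @param thresholds OKS thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @return A `metric_report` with elements `summary` (one-row tibble of the
#'   ten metrics) and `detail` (per threshold and area range: ap, recall,
#'   matched counts). `NA` metrics mean no annotation fell in that area
#'   range.
#' @export
evaluate_keypoints <- function(detections, annotations,
                               scheme = coco_keypoints(),
                               thresholds = seq(0.5, 0.95, by = 0.05)) {
  det <- tibble::as_tibble(detections)
  ann <- tibble::as_tibble(annotations)
  if (!nrow(det) || !nrow(ann)) stop("need at least one detection and one annotation")
  if (!"det_id" %in% names(det)) det$det_id <- 1L
  if (!"ann_id" %in% names(ann)) ann$ann_id <- 1L
  area_ranges <- list(
    all = c(0, Inf),
    medium = c(32^2, 96^2),
    large = c(96^2, Inf)
  )
  images <- union(unique(det$image_id), unique(ann$image_id))
  # precompute per image: detection list, gt list, OKS matrix
  per_image <- lapply(images, function(img) {
    d <- det[det$image_id == img, , drop = FALSE]
    a <- ann[ann$image_id == img, , drop = FALSE]
    dets <- if (nrow(d)) split(d, d$det_id) else list()
    gts <- if (nrow(a)) split(a, a$ann_id) else list()
    gts <- Filter(function(g) any(g$visible > 0), gts)
    om <- matrix(0, length(dets), length(gts))
    for (i in seq_along(dets)) {
      for (j in seq_along(gts)) {
        om[i, j] <- oks(dets[[i]], gts[[j]], scheme = scheme)
      }
    }
    list(
      scores = vapply(dets, function(d) d$score[1], numeric(1)),
      areas = vapply(gts, function(g) g$area[1], numeric(1)),
      oks = om
    )
  })
  detail <- tidyr::expand_grid(
    range = names(area_ranges), threshold = thresholds
  )
  res <- purrr::pmap_dfr(detail, function(range, threshold) {
    rng <- area_ranges[[range]]
    tp <- logical(0); sc <- numeric(0); n_gt <- 0L
    for (pi in per_image) {
      ig <- !(pi$areas > rng[1] & pi$areas <= rng[2])
      n_gt <- n_gt + sum(!ig)
      m <- match_image(pi$oks, pi$scores, ig, threshold)
      keep <- !m$ignore
      tp <- c(tp, m$tp[keep]); sc <- c(sc, pi$scores[keep])
    }
    tibble::tibble(
      ap = ap_101(tp, sc, n_gt),
      recall = if (n_gt > 0) sum(tp) / n_gt else NA_real_,
      n_gt = n_gt, n_tp = sum(tp), n_det = length(tp)
    )
  })
  detail <- dplyr::bind_cols(detail, res)
  pick <- function(rng, thr = NULL, col = "ap") {
    rows <- detail$range == rng & (if (is.null(thr)) TRUE else detail$threshold == thr)
    mean(detail[[col]][rows])
  }
  summary <- tibble::tibble(
    ap = pick("all"), ap50 = pick("all", 0.5), ap75 = pick("all", 0.75),
    ap_m = pick("medium"), ap_l = pick("large"),
    ar = pick("all", col = "recall"),
    ar50 = pick("all", 0.5, "recall"), ar75 = pick("all", 0.75, "recall"),
    ar_m = pick("medium", col = "recall"), ar_l = pick("large", col = "recall")
  )
  structure(list(summary = summary, detail = detail), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> COCO keypoint metrics\n")
  print(as.data.frame(round(x$summary, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.metric_report <- function(x, ...) x$detail

#' @export
glance.metric_report <- function(x, ...) x$summary

# ---- visibility classification metrics -------------------------------------

#' Confusion counts for the visible/occluded decision
#'
#' Tabulates predicted against reference visibility with visible as the
#' positive class: TP = reference-visible predicted visible, FP =
#' reference-occluded predicted visible, FN = reference-visible predicted
#' occluded, TN = reference-occluded predicted occluded.
#'
#' @param pred_visible,ref_visible Equal-length logical (or 0/1) vectors.
#' @return A one-row tibble with integer columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred_visible, ref_visible) {
  if (length(pred_visible) != length(ref_visible)) {
    stop("prediction and reference verdict lists differ in length")
  }
  p <- as.logical(pred_visible > 0)
  r <- as.logical(ref_visible > 0)
  tibble::tibble(
    tp = sum(r & p), fp = sum(!r & p),
    fn = sum(r & !p), tn = sum(!r & !p)
  )
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `f1 = 2 p r / (p + r)`. Works row-wise on a counts table so several
#' models (or joints) can be scored at once.
#'
#' @param counts A data frame with columns `tp`, `fp`, `fn` (and usually
#'   `tn`), e.g. from [confusion_counts()].
#' @return The input with `precision`, `recall` and `f1` columns appended.
#' @export
precision_recall_f1 <- function(counts) {
  cc <- tibble::as_tibble(counts)
  if (any(cc$tp + cc$fp == 0)) stop("precision undefined: TP + FP = 0")
  if (any(cc$tp + cc$fn == 0)) stop("recall undefined: TP + FN = 0")
  cc$precision <- cc$tp / (cc$tp + cc$fp)
  cc$recall <- cc$tp / (cc$tp + cc$fn)
  cc$f1 <- 2 * cc$precision * cc$recall / (cc$precision + cc$recall)
  cc
}

#' Per-joint sensitivity, specificity and F1
#'
#' Scores each keypoint's visible/occluded decision:
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`, plus
#' precision and F1. A zero denominator yields `NA` for that rate (reported
#' as undefined and excluded from any aggregate).
#'
#' @param counts_by_joint A data frame with columns `keypoint`, `tp`,
#'   `fp`, `fn`, `tn` (one row per keypoint).
#' @return The input with `sensitivity`, `specificity`, `precision` and
#'   `f1` columns appended (full precision; round for display).
#' @export
per_joint_metrics <- function(counts_by_joint) {
  cc <- tibble::as_tibble(counts_by_joint)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  cc$sensitivity <- safe_div(cc$tp, cc$tp + cc$fn)
  cc$specificity <- safe_div(cc$tn, cc$tn + cc$fp)
  cc$precision <- safe_div(cc$tp, cc$tp + cc$fp)
  cc$f1 <- 2 * cc$precision * cc$sensitivity / (cc$precision + cc$sensitivity)
  cc
}
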