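# Independent reference implementations (deliberately naive, loop-based)
# used to cross-check the vectorized package code.

# AUC as the exhaustive pairwise probability P(score_vis > score_occ) + 1/2 ties
oracle_auc <- function(scores) {
  vis <- scores$score[scores$visible > 0]
  occ <- scores$score[!(scores$visible > 0)]
  total <- 0
  for (a in vis) {
    for (b in occ) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(vis) * length(occ))
}

# exhaustive sweep over candidate thresholds for the ROC operating point
oracle_select_threshold <- function(scores) {
  vis <- scores$visible > 0
  cand <- c(sort(unique(scores$score), decreasing = TRUE), -Inf)
  best_t <- NA_real_
  best_d <- Inf
  for (t in cand) {
    tpr <- sum(scores$score[vis] > t) / sum(vis)
    fpr <- sum(scores$score[!vis] > t) / sum(!vis)
    d <- sqrt((1 - tpr)^2 + fpr^2)
    if (d < best_d - 1e-15 || (abs(d - best_d) <= 1e-15 && t > best_t)) {
      best_d <- d
      best_t <- t
    }
  }
  best_t
}

oracle_oks <- function(det, ann, scheme = coco_keypoints()) {
  vis <- which(ann$visible > 0)
  total <- 0
  for (i in vis) {
    j <- which(det$keypoint == ann$keypoint[i])
    k <- scheme$k[scheme$keypoint == ann$keypoint[i]]
    d2 <- (det$u[j] - ann$u[i])^2 + (det$v[j] - ann$v[i])^2
    total <- total + exp(-d2 / (2 * ann$area[1] * k^2))
  }
  total / length(vis)
}

# brute-force COCO-style matcher and AP/AR suite over tidy det/ann tables
oracle_ap_ar <- function(det, ann, thresholds = seq(0.5, 0.95, 0.05)) {
  ranges <- list(all = c(0, Inf), medium = c(32^2, 96^2), large = c(96^2, Inf))
  images <- union(unique(det$image_id), unique(ann$image_id))
  one <- function(rng, thr) {
    tp <- logical(0)
    sc <- numeric(0)
    ngt <- 0
    for (img in images) {
      a <- ann[ann$image_id == img, ]
      d <- det[det$image_id == img, ]
      gts <- list()
      for (id in unique(a$ann_id)) {
        g <- a[a$ann_id == id, ]
        if (any(g$visible > 0)) gts[[length(gts) + 1]] <- g
      }
      dets <- list()
      for (id in unique(d$det_id)) dets[[length(dets) + 1]] <- d[d$det_id == id, ]
      if (length(dets) > 1) {
        dets <- dets[order(-vapply(dets, function(x) x$score[1], 0))]
      }
      ignore <- vapply(gts, function(g) {
        !(g$area[1] > rng[1] && g$area[1] <= rng[2])
      }, TRUE)
      ngt <- ngt + sum(!ignore)
      used <- rep(FALSE, length(gts))
      for (dd in dets) {
        best <- -1; bj <- 0
        for (j in seq_along(gts)) {
          if (used[j] || ignore[j]) next
          o <- oracle_oks(dd, gts[[j]])
          if (o >= thr && o > best) { best <- o; bj <- j }
        }
        if (bj > 0) {
          used[bj] <- TRUE
          tp <- c(tp, TRUE); sc <- c(sc, dd$score[1])
          next
        }
        best <- -1; bj <- 0
        for (j in seq_along(gts)) {
          if (used[j] || !ignore[j]) next
          o <- oracle_oks(dd, gts[[j]])
          if (o >= thr && o > best) { best <- o; bj <- j }
        }
        if (bj > 0) used[bj] <- TRUE  # det ignored entirely
        else { tp <- c(tp, FALSE); sc <- c(sc, dd$score[1]) }
      }
    }
    if (ngt == 0) return(c(ap = NA_real_, rec = NA_real_))
    if (!length(tp)) return(c(ap = 0, rec = 0))
    ord <- order(-sc)
    tp <- tp[ord]
    ctp <- cumsum(tp); cfp <- cumsum(!tp)
    rec <- ctp / ngt
    prec <- ctp / (ctp + cfp)
    ap <- 0
    for (r in seq(0, 1, 0.01)) {
      ok <- which(rec >= r)
      ap <- ap + (if (length(ok)) max(prec[ok[1]:length(prec)]) else 0)
    }
    c(ap = ap / 101, rec = max(rec))
  }
  grab <- function(rng, thr = NULL, what = "ap") {
    vals <- vapply(if (is.null(thr)) thresholds else thr,
                   function(t) one(ranges[[rng]], t)[[what]], 0)
    mean(vals)
  }
  tibble::tibble(
    ap = grab("all"), ap50 = grab("all", 0.5), ap75 = grab("all", 0.75),
    ap_m = grab("medium"), ap_l = grab("large"),
    ar = grab("all", what = "rec"),
    ar50 = grab("all", 0.5, "rec"), ar75 = grab("all", 0.75, "rec"),
    ar_m = grab("medium", what = "rec"), ar_l = grab("large", what = "rec")
  )
}
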