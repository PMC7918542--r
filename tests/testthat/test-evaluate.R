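test_that("OKS follows its closed form", {
  # exact match of every visible keypoint
  withr::with_seed(81, {
    ann <- tibble::tibble(
      keypoint = keypoint_names(), u = runif(17, 0, 640), v = runif(17, 0, 480),
      visible = rep(c(1L, 0L), length.out = 17), area = 12000
    )
  })
  det <- ann[, c("keypoint", "u", "v")]
  expect_equal(oks(det, ann), 1.0)
  # single keypoint at the exp(-1) distance
  pair <- single_kp_pair(d = sqrt(2 * 10000 * 0.052^2))
  expect_equal(oks(pair$det, pair$ann), exp(-1), tolerance = 1e-12)
  # arbitrary far detections drive OKS to 0
  far <- det
  far$u <- far$u + 1e5
  expect_lt(oks(far, ann), 1e-12)
  # undefined without a visible keypoint
  ann0 <- ann
  ann0$visible <- 0L
  expect_error(oks(det, ann0), "no visible")
  expect_error(oks(det, ann[, setdiff(names(ann), "area")]), "area")
})

test_that("OKS is strictly decreasing in any visible keypoint's distance", {
  ds <- c(0, 5, 20, 50, 200)
  vals <- vapply(ds, function(d) {
    pair <- single_kp_pair(d)
    oks(pair$det, pair$ann)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("the AP/AR suite scores perfect and uniform-OKS detections correctly", {
  withr::with_seed(82, {
    ann <- purrr::map_dfr(1:5, function(img) {
      tibble::tibble(
        image_id = img, ann_id = 1L, keypoint = keypoint_names(),
        u = runif(17, 100, 500), v = runif(17, 100, 400),
        visible = 1L, area = 11000
      )
    })
  })
  det <- dplyr::mutate(ann, det_id = 1L, score = 0.9)
  rep <- evaluate_keypoints(det, ann)
  g <- glance(rep)
  expect_equal(unname(unlist(g[c("ap", "ap50", "ap75", "ap_l",
                                 "ar", "ar50", "ar75", "ar_l")])),
               rep(1, 8))
  expect_true(is.na(g$ap_m))  # no medium-sized person in the fixture
  # single visible keypoint per image at OKS just above 0.6
  k_nose <- coco_keypoints()$k[1]
  d <- sqrt(-2 * 11000 * k_nose^2 * log(0.6000001))
  ann1 <- ann
  ann1$visible <- ifelse(ann1$keypoint == "nose", 1L, 0L)
  det1 <- dplyr::mutate(ann1, det_id = 1L, score = 0.9,
                        u = u + ifelse(keypoint == "nose", d, 0))
  g1 <- glance(evaluate_keypoints(det1, ann1))
  expect_equal(g1$ap50, 1)
  expect_equal(g1$ap75, 0)
  expect_equal(g1$ap, 3 / 10)
  expect_equal(g1$ar, 3 / 10)
})

test_that("the AP/AR suite equals the brute-force reference matcher", {
  for (s in 1:30) {
    fx <- random_eval_fixture(900 + s)
    got <- glance(evaluate_keypoints(fx$det, fx$ann))
    want <- oracle_ap_ar(fx$det, fx$ann)
    expect_equal(as.data.frame(got), as.data.frame(want), tolerance = 1e-12)
  }
})

test_that("AP and AR never increase as uniform positional error grows", {
  fx <- random_eval_fixture(321)
  vals <- purrr::map_dfr(c(0, 5, 15, 40, 120), function(shift) {
    det <- fx$det
    det$u <- det$u + shift
    glance(evaluate_keypoints(det, fx$ann))
  })
  expect_true(all(diff(vals$ap) <= 1e-12))
  expect_true(all(diff(vals$ar) <= 1e-12))
})

test_that("confusion counts tabulate the visible/occluded decision", {
  pred <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  ref <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  cc <- confusion_counts(pred, ref)
  expect_equal(as.integer(cc[1, c("tp", "fp", "fn", "tn")]), c(2L, 1L, 1L, 1L))
  # perfect prediction
  cp <- confusion_counts(ref, ref)
  expect_equal(cp$fp + cp$fn, 0L)
  # everything predicted visible
  ca <- confusion_counts(rep(TRUE, 5), ref)
  expect_equal(ca$tn, 0L)
  expect_equal(ca$fp, sum(!ref))
  expect_error(confusion_counts(pred[1:3], ref), "length")
})

test_that("precision/recall/F1 follow their formulas", {
  cc <- tibble::tibble(tp = 80, fp = 20, fn = 40, tn = 60)
  out <- precision_recall_f1(cc)
  expect_equal(out$precision, 0.8)
  expect_equal(out$recall, 2 / 3)
  expect_equal(out$f1, 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3))
  # harmonic-mean identity: p = r implies f1 = p
  eq <- precision_recall_f1(tibble::tibble(tp = 50, fp = 10, fn = 10, tn = 5))
  expect_equal(eq$f1, eq$precision)
  expect_error(precision_recall_f1(tibble::tibble(tp = 0, fp = 0, fn = 3, tn = 1)),
               "precision")
  expect_error(precision_recall_f1(tibble::tibble(tp = 0, fp = 2, fn = 0, tn = 1)),
               "recall")
})

test_that("per-joint metrics handle balanced and degenerate counts", {
  cc <- tibble::tibble(keypoint = c("a", "b", "c"),
                       tp = c(10, 5, 0), fp = c(2, 0, 0),
                       fn = c(10, 3, 2), tn = c(8, 0, 4))
  out <- per_joint_metrics(cc)
  expect_equal(out$sensitivity[1], 0.5)  # TP = FN
  expect_equal(out$specificity[1], 0.8)
  expect_true(is.na(out$specificity[2]))  # TN + FP = 0
  expect_true(is.na(out$precision[3]))    # TP + FP = 0
})
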