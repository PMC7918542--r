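test_that("argmax decoding scales to the input frame and breaks ties row-major", {
  kp <- grid_keypoints()
  kp$u[1] <- 10; kp$v[1] <- 20
  det <- decode_heatmaps(make_target_heatmaps(kp))
  expect_equal(det$u[1], 40)
  expect_equal(det$v[1], 80)
  expect_equal(det$score[1], 1.0)
  # constant maps decode to (0, 0) by the documented tie rule
  flat <- depthpose:::new_heatmap_stack(array(0.2, c(96, 72, 17)))
  detf <- decode_heatmaps(flat)
  expect_true(all(detf$u == 0 & detf$v == 0))
  expect_true(all(detf$score == 0.2))
})

test_that("sub-pixel refinement recovers continuous Gaussian peaks exactly", {
  kp <- grid_keypoints()
  kp$u <- kp$u + 0.37
  kp$v <- kp$v - 0.21
  stack <- make_target_heatmaps(kp)
  det <- decode_heatmaps(stack, refine = TRUE)
  expect_equal(det$hu, kp$u, tolerance = 1e-9)
  expect_equal(det$hv, kp$v, tolerance = 1e-9)
})

test_that("ROC curves have the contractual endpoints and shape", {
  sep <- tibble::tibble(score = c(0.9, 0.8, 0.2, 0.1),
                        visible = c(TRUE, TRUE, FALSE, FALSE))
  roc <- build_roc(sep)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # passes the ideal corner
  expect_true(any(roc$fpr == 0 & roc$tpr == 0))
  expect_true(any(roc$fpr == 1 & roc$tpr == 1))
  expect_equal(attr(roc, "auc"), 1)
  # all-equal scores collapse to the two endpoints
  same <- tibble::tibble(score = rep(0.5, 6), visible = rep(c(TRUE, FALSE), 3))
  roc2 <- build_roc(same)
  expect_equal(nrow(roc2), 2L)
  expect_equal(roc2$fpr, c(0, 1))
  expect_equal(roc2$tpr, c(0, 1))
  # monotone in the threshold, contained in the unit square
  withr::with_seed(61, {
    sc <- generate_score_sample(80, 60, visible = c(0.7, 0.2), occluded = c(0.5, 0.2))
  })
  roc3 <- build_roc(sc)
  expect_true(all(diff(roc3$tpr) >= 0))  # thresholds decrease along the curve
  expect_true(all(diff(roc3$fpr) >= 0))
  expect_true(all(roc3$fpr >= 0 & roc3$fpr <= 1 & roc3$tpr >= 0 & roc3$tpr <= 1))
  d <- tidy(roc3)$dist
  expect_true(all(d >= 0 & d <= sqrt(2)))
  expect_error(build_roc(tibble::tibble(score = 1:3, visible = TRUE)),
               "at least one")
})

test_that("trapezoidal AUC equals the exhaustive pairwise estimate", {
  withr::with_seed(62, {
    sc <- tibble::tibble(
      score = c(runif(100, 0.2, 0.8), runif(100, 0.0, 0.6)),
      visible = rep(c(TRUE, FALSE), each = 100)
    )
  })
  expect_equal(attr(build_roc(sc), "auc"), oracle_auc(sc), tolerance = 1e-9)
  # independent library cross-check
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = sc$visible, predictor = sc$score,
    direction = "<", quiet = TRUE
  )))
  expect_equal(attr(build_roc(sc), "auc"), proc_auc, tolerance = 1e-9)
  # with heavy ties
  sc$score <- round(sc$score, 1)
  expect_equal(attr(build_roc(sc), "auc"), oracle_auc(sc), tolerance = 1e-9)
})

test_that("threshold selection minimizes the distance to (fpr, tpr) = (0, 1)", {
  sep <- tibble::tibble(score = c(0.9, 0.8, 0.2, 0.1),
                        visible = c(TRUE, TRUE, FALSE, FALSE))
  t_star <- select_threshold(build_roc(sep))
  # perfectly separable: the largest zero-distance threshold is max occluded
  expect_equal(as.numeric(t_star), 0.2)
  expect_equal(attr(t_star, "dist"), 0)
  expect_equal(attr(t_star, "fpr"), 0)
  expect_equal(attr(t_star, "tpr"), 1)
})

test_that("threshold selection equals the exhaustive sweep oracle", {
  for (s in 1:100) {
    sc <- generate_score_sample(
      n_visible = 20 + (s %% 30), n_occluded = 15 + (s %% 20),
      visible = c(0.6 + 0.3 * (s %% 3) / 3, 0.1 + 0.05 * (s %% 4)),
      occluded = c(0.4, 0.15), seed = 7000 + s
    )
    if (s %% 2 == 0) sc$score <- round(sc$score, 2)  # force ties
    expect_equal(as.numeric(select_threshold(build_roc(sc))),
                 oracle_select_threshold(sc))
  }
})

test_that("visibility filtering uses a strict threshold", {
  det <- tibble::tibble(keypoint = "nose", u = 1, v = 1, score = 0.9)
  expect_true(filter_visibility(det, 0.83)$visible)
  det$score <- 0.83
  expect_false(filter_visibility(det, 0.83)$visible)
  det$score <- 0.0001
  expect_true(filter_visibility(det, 0)$visible)
})

test_that("detections map back to original coordinates affinely", {
  det <- tibble::tibble(keypoint = "nose", u = 40, v = 60, score = 1)
  ident <- crop_transform(1, 0, 0, 288, 384)
  expect_equal(map_to_original(det, ident)$u, 40)
  tr <- crop_transform(2, 100, 50, 144, 192)
  out <- map_to_original(det, tr)
  expect_equal(out$u, 120)
  expect_equal(out$v, 80)
})

test_that("detection exports write COCO results JSON and a verdict CSV", {
  det <- tibble::tibble(
    image_id = 1L, keypoint = keypoint_names(),
    u = 1:17, v = 21:37, score = seq(0.1, 0.9, length.out = 17),
    visible = rep(c(TRUE, FALSE), length.out = 17)
  )
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_detections(det, fj, fc)
  parsed <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(nrow(parsed), 1L)
  expect_equal(length(parsed$keypoints[[1]]), 51L)
  expect_equal(parsed$keypoints[[1]][1:3], c(1, 21, 0.1))
  back <- utils::read.csv(fc)
  expect_equal(nrow(back), 17L)
})
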