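# fixtures built in code

# a person-like annotation + detection pair per image; small random fixtures
# exercising multiple detections, occluded joints, and medium/large areas
random_eval_fixture <- function(seed) {
  withr::with_seed(seed, {
    n_img <- sample(1:5, 1)
    anns <- list()
    dets <- list()
    for (img in seq_len(n_img)) {
      for (a in seq_len(sample(1:2, 1))) {
        ctr <- runif(2, 150, 350)
        area <- runif(1, 800, 15000)  # spans the medium/large boundary
        vis <- as.integer(runif(17) < 0.8)
        if (!any(vis)) vis[sample(17, 1)] <- 1L
        spread <- sqrt(area) / 3
        ann <- tibble::tibble(
          image_id = img, ann_id = a, keypoint = keypoint_names(),
          u = ctr[1] + rnorm(17, 0, spread), v = ctr[2] + rnorm(17, 0, spread),
          visible = vis, area = area
        )
        anns[[length(anns) + 1]] <- ann
        noise <- sqrt(area) * runif(1, 0.01, 0.4)
        dets[[length(dets) + 1]] <- tibble::tibble(
          image_id = img, det_id = a, keypoint = ann$keypoint,
          u = ann$u + rnorm(17, 0, noise), v = ann$v + rnorm(17, 0, noise),
          score = runif(1)
        )
      }
      if (runif(1) < 0.3) {  # spurious detection far from any person
        dets[[length(dets) + 1]] <- tibble::tibble(
          image_id = img, det_id = 99L, keypoint = keypoint_names(),
          u = runif(17, 500, 600), v = runif(17, 400, 470), score = runif(1)
        )
      }
    }
    list(det = dplyr::bind_rows(dets), ann = dplyr::bind_rows(anns))
  })
}

# 17 keypoints on a grid in heatmap coordinates, all in-bounds
grid_keypoints <- function(width = 72, height = 96, visible = rep(1L, 17)) {
  tibble::tibble(
    keypoint = keypoint_names(),
    u = rep(round(seq(12, 60, length.out = 6)), 3)[1:17],
    v = rep(round(seq(12, 84, length.out = 6)), each = 3)[1:17],
    visible = visible
  )
}

new_model_input_for_test <- function(image) {
  depthpose:::new_model_input(
    image, crop_transform(1, 0, 0, ncol(image), nrow(image))
  )
}

# single-keypoint annotation/detection pair at a chosen pixel distance
single_kp_pair <- function(d, area = 10000, keypoint = "nose") {
  ann <- tibble::tibble(keypoint = keypoint, u = 100, v = 100,
                        visible = 1L, area = area)
  det <- tibble::tibble(keypoint = keypoint, u = 100 + d, v = 100)
  list(det = det, ann = ann)
}
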