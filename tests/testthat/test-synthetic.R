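test_that("scene generation is deterministic and internally consistent", {
  spec <- scene_spec(seed = 91, n_person = 1000L, n_floor = 1500L)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$cloud, b$cloud)
  expect_identical(a$joints2d, b$joints2d)
  # projecting GT 3D reproduces GT 2D within rounding
  uv <- project_points(a$joints3d, a$cam)
  expect_true(all(abs(uv$u - a$joints2d$u) <= 0.5 + 1e-9))
  expect_true(all(abs(uv$v - a$joints2d$v) <= 0.5 + 1e-9))
  # provenance labels partition the cloud
  expect_equal(sort(unique(a$cloud$label)), c("floor", "person"))
  expect_equal(sum(a$cloud$label == "floor"), 1500L)
  expect_gt(a$area, 0)
  expect_error(scene_spec(distance = 0.5), "working range")
  expect_error(scene_spec(occlusions = "elbow"), "unknown keypoints")
})

test_that("noiseless renders show body surface depth at visible joints", {
  sc <- generate_scene(scene_spec(seed = 92, noise_sd = 0, n_floor = 0L,
                                  n_person = 20000L))
  depth <- render_depth_image(sc$cloud, sc$cam)
  vis <- sc$joints2d[sc$joints2d$visible > 0, ]
  truth <- sc$joints3d[match(vis$keypoint, sc$joints3d$keypoint), ]
  d <- depth[cbind(vis$v + 1, vis$u + 1)]
  hit <- d > 0
  expect_gt(mean(hit), 0.7)  # most joint pixels are covered by surface samples
  # readings lie on the body: within one capsule radius of the joint in the
  # median case, never beyond the front-to-back body extent (a front-surface
  # sampling hole can expose the back surface of the same capsule)
  expect_lt(median(abs(d[hit] - (-truth$z[hit]))), 0.07)
  expect_true(all(abs(d[hit] - (-truth$z[hit])) < 0.25))
})

test_that("forced occlusions remove surface cover and flag the joint", {
  sc <- generate_scene(scene_spec(seed = 93, occlusions = c("left_wrist"),
                                  n_person = 2000L, n_floor = 0L))
  expect_equal(sc$joints2d$visible[sc$joints2d$keypoint == "left_wrist"], 0L)
  wrist <- sc$joints3d[sc$joints3d$keypoint == "left_wrist", ]
  d2 <- (sc$cloud$x - wrist$x)^2 + (sc$cloud$y - wrist$y)^2 + (sc$cloud$z - wrist$z)^2
  expect_gt(min(d2), 0.1^2)  # neighborhood cleared
})

test_that("walk sequences subsample frames and approach monotonically", {
  spec <- scene_spec(seed = 94, n_person = 300L, n_floor = 200L)
  seq10 <- generate_walk_sequence(spec, n_frames = 60, stride = 6)
  expect_length(seq10, 10L)
  z <- vapply(seq10, function(s) s$spec$distance, numeric(1))
  expect_true(all(diff(z) < 0))
  expect_equal(z[1], 4.2)
  # 30 fps at stride 6 is a 5 Hz effective sampling rate
  expect_equal(30 / 6, 5)
  one <- generate_walk_sequence(spec, n_frames = 1)
  expect_length(one, 1L)
})

test_that("datasets write with a leave-one-subject-out split", {
  scenes <- list()
  for (s in 1:4) {
    spec <- scene_spec(subject = paste0("s", s), seed = 950 + s,
                       n_person = 300L, n_floor = 200L)
    scenes <- c(scenes, generate_walk_sequence(spec, n_frames = 25, stride = 5))
  }
  dir <- withr::local_tempdir()
  manifest <- write_dataset(scenes, dir, seed = 5)
  expect_equal(nrow(manifest), 20L)
  expect_setequal(list.files(file.path(dir, "scenes")),
                  paste0(manifest$file, ".ply"))
  expect_setequal(list.files(file.path(dir, "depth")),
                  paste0(manifest$file, ".png"))
  # test split holds exactly one subject, and all of that subject's scenes
  test_subj <- unique(manifest$subject[manifest$split == "test"])
  expect_length(test_subj, 1L)
  expect_true(all(manifest$split[manifest$subject == test_subj] == "test"))
  # remaining scenes split 70:15 within one scene of the target
  rest <- manifest[manifest$subject != test_subj, ]
  expect_lte(abs(sum(rest$split == "train") - nrow(rest) * 0.7 / 0.85), 1)
  # deterministic manifests under the same seed
  dir2 <- withr::local_tempdir()
  manifest2 <- write_dataset(scenes, dir2, seed = 5)
  expect_identical(manifest, manifest2)
  expect_identical(readLines(file.path(dir, "annotations.json")),
                   readLines(file.path(dir2, "annotations.json")))
  one_subject <- scenes[1:5]
  expect_error(write_dataset(one_subject, withr::local_tempdir(), seed = 1),
               "at least 2 subjects")
})

test_that("COCO annotations round-trip through JSON", {
  scenes <- generate_walk_sequence(
    scene_spec(seed = 96, n_person = 400L, n_floor = 200L), n_frames = 10, stride = 5
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_coco_annotations(scenes, c("a", "b"), f)
  back <- read_coco_annotations(f)
  expect_equal(nrow(back$annotations), 34L)
  expect_equal(nrow(back$images), 2L)
  kp1 <- back$annotations[back$annotations$image_id == 1, ]
  expect_equal(kp1$u, scenes[[1]]$joints2d$u)
  expect_equal(kp1$visible, scenes[[1]]$joints2d$visible)
  expect_equal(kp1$area[1], scenes[[1]]$area)
})

test_that("score samples respect their distributions and seeds", {
  a <- generate_score_sample(50, 40, seed = 97)
  b <- generate_score_sample(50, 40, seed = 97)
  expect_identical(a, b)
  expect_equal(sum(a$visible), 50L)
  # disjoint supports give a perfect ROC
  sep <- generate_score_sample(100, 100, visible = c(0.9, 0.001),
                               occluded = c(0.1, 0.001), seed = 98)
  expect_equal(attr(build_roc(sep), "auc"), 1)
  # identical distributions give chance-level AUC (binomial sampling band)
  same <- generate_score_sample(10000, 10000, visible = c(0.5, 0.1),
                                occluded = c(0.5, 0.1), seed = 99)
  expect_equal(attr(build_roc(same), "auc"), 0.5, tolerance = 0.02)
})

test_that("every generated scene passes the default pipeline", {
  for (s in c(101, 102)) {
    sc <- generate_scene(scene_spec(seed = s, distance = 2 + s %% 3,
                                    n_person = 1200L, n_floor = 2500L))
    mi <- preprocess_scene(sc$cloud, sc$cam, preprocess_config(seed = 1))
    expect_s3_class(mi, "model_input")
    expect_gt(sum(mi$image > 0), 100)
  }
})
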