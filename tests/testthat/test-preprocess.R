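planar_cloud <- function(n, seed, noise = 0) {
  withr::with_seed(seed, {
    p <- tibble::tibble(x = runif(n, -1, 1), y = runif(n, -1, 1))
    p$z <- -2 + 0.1 * p$x - 0.05 * p$y + rnorm(n, 0, noise)
  })
  p[, c("x", "y", "z")]
}

test_that("MLS smoothing leaves exact planes fixed and preserves counts", {
  pl <- planar_cloud(400, 31)
  sm <- smooth_mls(pl, 0.2)
  expect_equal(as.matrix(sm), as.matrix(pl), tolerance = 1e-9)
  expect_equal(nrow(sm), nrow(pl))
  # a single isolated point has too few neighbors and passes through
  one <- tibble::tibble(x = 0.3, y = -0.2, z = -1.5)
  expect_equal(as.matrix(smooth_mls(one)), as.matrix(one))
  expect_error(smooth_mls(one[0, ]), "empty")
})

test_that("MLS smoothing reduces the RMS distance to a noisy plane", {
  noisy <- planar_cloud(1500, 32, noise = 0.01)
  rms_to_plane <- function(p) {
    A <- cbind(p$x, p$y, 1)
    sqrt(mean((p$z - A %*% qr.solve(A, p$z))^2))
  }
  sm <- smooth_mls(noisy, 0.1)
  expect_lt(rms_to_plane(sm), rms_to_plane(noisy))
})

test_that("RANSAC floor removal separates floor from person points", {
  # labeled scene: 10k floor points (sigma 0.005) + 5k person points >= 0.1 m above
  withr::with_seed(41, {
    floor <- tibble::tibble(
      x = runif(10000, -2, 2), y = rnorm(10000, -0.5, 0.005),
      z = runif(10000, -4.5, -1), label = "floor"
    )
    person <- tibble::tibble(
      x = runif(5000, -0.3, 0.3), y = runif(5000, -0.39, 1.2),
      z = rnorm(5000, -3, 0.1), label = "person"
    )
  })
  cloud <- dplyr::bind_rows(floor, person)
  kept <- remove_floor_plane(cloud, seed = 7)
  floor_removed <- 1 - sum(kept$label == "floor") / nrow(floor)
  person_removed <- 1 - sum(kept$label == "person") / nrow(person)
  expect_gte(floor_removed, 0.99)
  expect_lte(person_removed, 0.01)
  # plane coefficients are unit-normal and horizontal-ish (y-normal)
  pl <- attr(kept, "plane")
  expect_equal(sum(pl[1:3]^2), 1)
  expect_gt(abs(pl[2]), 0.99)
})

test_that("RANSAC empties a perfectly planar cloud and is seed-deterministic", {
  pl <- planar_cloud(300, 42)
  out <- remove_floor_plane(pl, seed = 3)
  expect_equal(nrow(out), 0L)
  a <- remove_floor_plane(planar_cloud(500, 43, noise = 0.05), seed = 9)
  b <- remove_floor_plane(planar_cloud(500, 43, noise = 0.05), seed = 9)
  expect_identical(attr(a, "inliers"), attr(b, "inliers"))
  expect_error(remove_floor_plane(pl[1:2, ]), "at least 3")
})

test_that("lateral crop retains the closed x interval", {
  expect_equal(nrow(crop_lateral(tibble::tibble(x = 1.5, y = 0, z = -1), -1, 1)), 0L)
  withr::with_seed(44, {
    pts <- tibble::tibble(x = runif(100, -2, 2), y = 0, z = -2)
  })
  expect_equal(nrow(crop_lateral(pts, -Inf, Inf)), 100L)
  expect_equal(nrow(crop_lateral(pts, -1, 1)), sum(pts$x >= -1 & pts$x <= 1))
  expect_error(crop_lateral(pts, 1, -1), "x_min")
})

test_that("centre-of-mass depth crop removes clutter beyond 50 cm", {
  same <- tibble::tibble(x = rnorm(50), y = rnorm(50), z = -3)
  expect_equal(nrow(crop_depth_com(same)), 50L)
  person <- tibble::tibble(x = 0, y = seq(0, 1, length.out = 200), z = -3)
  clutter <- tibble::tibble(x = 0, y = 0.5, z = rep(-3.8, 10))
  out <- crop_depth_com(dplyr::bind_rows(person, clutter))
  expect_equal(nrow(out), 200L)
  expect_true(all(out$z == -3))
  # closed interval at exactly the threshold
  edge <- tibble::tibble(x = 0, y = 0, z = c(-3, -3, -3.5))  # z_com = -3.1667
  z_com <- mean(edge$z)
  edge2 <- tibble::tibble(x = 0, y = 0, z = c(z_com, z_com + 0.5, z_com - 0.5))
  expect_equal(nrow(crop_depth_com(edge2)), 3L)
  expect_error(crop_depth_com(person[0, ]), "empty")
})

test_that("gray normalization maps foreground to [1, 255] and keeps 0 background", {
  img <- matrix(0, 4, 4)
  img[1, 1:3] <- c(2, 3, 4)
  g <- normalize_depth_to_gray(img)
  expect_equal(g[1, 1:3], c(1L, 128L, 255L))
  expect_true(all(g[img == 0] == 0L))
  expect_equal(attr(g, "norm"), list(min_depth = 2, max_depth = 4))
  single <- matrix(c(0, 2.5), 1, 2)
  expect_equal(normalize_depth_to_gray(single)[1, 2], 255L)
  expect_error(normalize_depth_to_gray(matrix(0, 2, 2)), "all-background")
})

test_that("crop-and-scale finds the 3:4 window and round-trips coordinates", {
  g <- matrix(0L, 480, 640)
  g[101:292, 201:344] <- 80L  # 144 x 192 blob, exact 3:4
  mi <- crop_and_scale(g)
  expect_equal(mi$transform$scale, 2)
  expect_equal(mi$transform$offset_u, 200)
  expect_equal(mi$transform$offset_v, 100)
  expect_equal(dim(mi$image), c(384L, 288L))
  # blob corner round-trip within one original pixel
  corner_model <- tibble::tibble(
    u = (200 - mi$transform$offset_u) * mi$transform$scale,
    v = (100 - mi$transform$offset_v) * mi$transform$scale
  )
  back <- map_to_original(corner_model, mi$transform)
  expect_equal(back$u, 200, tolerance = 1)
  expect_equal(back$v, 100, tolerance = 1)
  expect_error(crop_and_scale(matrix(0L, 10, 10)), "all-background")
})

test_that("crop windows exceeding the image are zero-padded", {
  g <- matrix(0L, 100, 100)
  g[1:40, 1:30] <- 50L  # 3:4 blob touching the top-left corner
  mi <- crop_and_scale(g)
  expect_equal(dim(mi$image), c(384L, 288L))
  expect_true(all(mi$image %in% c(0L, 50L)))
  # nonzero pixels survive the resample
  expect_gt(sum(mi$image > 0), 0)
})

test_that("crop transform round-trips arbitrary interior pixels within 1 px", {
  withr::with_seed(47, {
    g <- matrix(0L, 200, 300)
    g[60:150, 100:170] <- sample(1:255, 91 * 71, replace = TRUE)
    mi <- crop_and_scale(g)
    tr <- mi$transform
    orig <- tibble::tibble(u = runif(50, 100, 170), v = runif(50, 60, 150))
    model <- tibble::tibble(u = (orig$u - tr$offset_u) * tr$scale,
                            v = (orig$v - tr$offset_v) * tr$scale)
    back <- map_to_original(model, tr)
    expect_lt(max(abs(back$u - orig$u)), 1)
    expect_lt(max(abs(back$v - orig$v)), 1)
  })
})

test_that("model tensors are standardized per channel", {
  g <- matrix(0L, 8, 6)
  g[1, 1] <- 255L
  mi <- new_model_input_for_test(g)
  arr <- to_model_tensor(mi)
  expect_equal(dim(arr), c(3L, 8L, 6L))
  expect_equal(arr[, 2, 2], c(-0.485 / 0.229, -0.456 / 0.224, -0.406 / 0.225))
  expect_equal(arr[, 1, 1],
               c((1 - 0.485) / 0.229, (1 - 0.456) / 0.224, (1 - 0.406) / 0.225))
})

test_that("the full pipeline is contracting and keeps ground truth in the crop", {
  sc <- generate_scene(scene_spec(seed = 51, n_person = 1500L, n_floor = 3000L))
  cfg <- preprocess_config(seed = 1)
  mi <- preprocess_scene(sc$cloud, sc$cam, cfg)
  log <- attr(mi, "log")
  pts_stages <- log$n[log$stage %in%
    c("input", "smooth_mls", "remove_floor_plane", "crop_lateral", "crop_depth_com")]
  expect_true(all(diff(pts_stages) <= 0))
  # all visible ground-truth joints land inside the crop window
  tr <- mi$transform
  vis <- sc$joints2d[sc$joints2d$visible > 0, ]
  mu <- (vis$u - tr$offset_u) * tr$scale
  mv <- (vis$v - tr$offset_v) * tr$scale
  expect_true(all(mu >= 0 & mu < 288 & mv >= 0 & mv < 384))
})

test_that("elimination stages are no-ops on scenes without floor or clutter", {
  sc <- generate_scene(scene_spec(seed = 52, n_person = 1200L, n_floor = 0L,
                                  noise_sd = 0))
  cam <- sc$cam
  full <- preprocess_scene(sc$cloud, cam,
                           preprocess_config(mls_radius = NA, seed = 1))
  bare <- preprocess_scene(sc$cloud, cam,
                           preprocess_config(mls_radius = NA, plane_dist = NA,
                                             x_bounds = NULL, z_crop = NA))
  expect_equal(full$image, bare$image, ignore_attr = TRUE)
  expect_equal(full$transform$scale, bare$transform$scale)
})

test_that("clutter violating the 50 cm rule is absent from the model input", {
  clutter <- list(center = c(0.5, 0.3, -4.1), size = c(0.3, 0.3, 0.1), n = 400L)
  sc <- generate_scene(scene_spec(seed = 53, distance = 3, n_person = 1500L,
                                  n_floor = 0L, clutter = clutter, noise_sd = 0))
  mi <- preprocess_scene(sc$cloud, sc$cam, preprocess_config(plane_dist = NA))
  # render the clutter alone and check its pixels are background in the crop
  cl <- sc$cloud[sc$cloud$label == "clutter", ]
  img <- render_depth_image(cl, sc$cam)
  nz <- which(unclass(img) > 0, arr.ind = TRUE)
  tr <- mi$transform
  mu <- round((nz[, 2] - 1 - tr$offset_u) * tr$scale)
  mv <- round((nz[, 1] - 1 - tr$offset_v) * tr$scale)
  inside <- mu >= 0 & mu < 288 & mv >= 0 & mv < 384
  expect_true(all(mi$image[cbind(mv[inside] + 1, mu[inside] + 1)] == 0))
})

test_that("stage errors carry the failing stage name", {
  cam <- camera_intrinsics()
  empty <- tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0))
  expect_error(preprocess_scene(empty, cam), "smooth_mls")
})
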