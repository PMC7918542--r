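#' Specification of a synthetic depth scene
#'
#' Describes one labeled scene for the generator: a single person modeled
#' as capsules (cylinders with hemispherical caps) around a 17-joint
#' skeleton, standing on a floor plane, viewed by a knee-height depth
#' camera 1-4.2 m away, with optional box clutter, Gaussian depth noise
#' along the viewing ray, and forced occlusions.
#'
#' @param subject Subject identifier (used by dataset splits).
#' @param distance Person distance from the camera in meters (1-4.2, the
#'   sensor's working range in the emulated recording setup).
#' @param lateral Lateral offset of the person from the optical axis (m).
#' @param stature Person height in meters (default 1.75).
#' @param floor_y Floor-plane height in camera coordinates (m); the camera
#'   sits at knee height, so the floor is at -0.5 by default.
#' @param cam The [camera_intrinsics()] of the virtual sensor.
#' @param n_person,n_floor Surface sample counts for person and floor.
#' @param noise_sd Depth noise standard deviation in meters, applied along
#'   each viewing ray (default 0.005).
#' @param clutter Optional clutter spec:
#'   `list(center = c(x, y, z), size = c(dx, dy, dz), n = count)`.
#' @param occlusions Character vector of keypoint names to occlude
#'   explicitly (their surface neighborhood is removed, as if hidden).
#' @param phase Gait-cycle phase in radians (0 = neutral standing).
#' @param swing Gait swing amplitude in meters along the walking (z) axis.
#' @param seed Integer seed; the same spec generates the identical scene.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(subject = "s1", distance = 3, lateral = 0,
                       stature = 1.75, floor_y = -0.5,
                       cam = camera_intrinsics(),
                       n_person = 4000L, n_floor = 8000L,
                       noise_sd = 0.005, clutter = NULL,
                       occlusions = character(), phase = 0,
                       swing = 0.25, seed = 1L) {
  if (distance < 1 || distance > 4.2) {
    stop("person distance must lie in the sensor's working range [1, 4.2] m")
  }
  stopifnot(stature > 0, n_person >= 0, n_floor >= 0, noise_sd >= 0, swing >= 0)
  bad <- setdiff(occlusions, keypoint_names())
  if (length(bad)) stop("unknown keypoints in occlusion list: ", paste(bad, collapse = ", "))
  structure(
    list(subject = subject, distance = distance, lateral = lateral,
         stature = stature, floor_y = floor_y, cam = cam,
         n_person = as.integer(n_person), n_floor = as.integer(n_floor),
         noise_sd = noise_sd, clutter = clutter, occlusions = occlusions,
         phase = phase, swing = swing, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# 17-joint skeleton of a standing/walking person; y measured from the floor
skeleton_joints <- function(spec) {
  S <- spec$stature
  x0 <- spec$lateral
  y0 <- spec$floor_y
  z0 <- -spec$distance
  sw <- spec$swing * sin(spec$phase)
  h <- function(f) y0 + f * S
  j <- list(
    nose           = c(0,        h(0.910), z0 + 0.090),
    left_eye       = c(0.021,    h(0.935), z0 + 0.070),
    right_eye      = c(-0.021,   h(0.935), z0 + 0.070),
    left_ear       = c(0.045,    h(0.925), z0 - 0.010),
    right_ear      = c(-0.045,   h(0.925), z0 - 0.010),
    left_shoulder  = c(0.115,    h(0.820), z0),
    right_shoulder = c(-0.115,   h(0.820), z0),
    left_elbow     = c(0.135,    h(0.630), z0 - 0.5 * 0.6 * sw),
    right_elbow    = c(-0.135,   h(0.630), z0 + 0.5 * 0.6 * sw),
    left_wrist     = c(0.140,    h(0.485), z0 - 0.6 * sw),
    right_wrist    = c(-0.140,   h(0.485), z0 + 0.6 * sw),
    left_hip       = c(0.060,    h(0.530), z0),
    right_hip      = c(-0.060,   h(0.530), z0),
    left_knee      = c(0.060,    h(0.285), z0 + 0.5 * sw),
    right_knee     = c(-0.060,   h(0.285), z0 - 0.5 * sw),
    left_ankle     = c(0.060,    h(0.055), z0 + sw),
    right_ankle    = c(-0.060,   h(0.055), z0 - sw)
  )
  # lateral widths scale with stature around the 1.75 m default
  m <- do.call(rbind, j)
  m[, 1] <- m[, 1] * (S / 1.75) + x0
  tibble::tibble(keypoint = rownames(m), x = unname(m[, 1]),
                 y = unname(m[, 2]), z = unname(m[, 3]))
}

# capsule set: segments with radii and the joints each capsule touches
skeleton_capsules <- function(joints, stature) {
  J <- as.matrix(joints[, c("x", "y", "z")])
  rownames(J) <- joints$keypoint
  r <- stature / 1.75
  mid_sh <- (J["left_shoulder", ] + J["right_shoulder", ]) / 2
  mid_hip <- (J["left_hip", ] + J["right_hip", ]) / 2
  head_c <- (J["left_ear", ] + J["right_ear", ]) / 2 + c(0, 0.01, 0)
  cap <- function(p1, p2, radius, touches) {
    list(p1 = p1, p2 = p2, r = radius * r, touches = touches)
  }
  list(
    cap(J["left_shoulder", ], J["left_elbow", ], 0.045, c("left_shoulder", "left_elbow")),
    cap(J["right_shoulder", ], J["right_elbow", ], 0.045, c("right_shoulder", "right_elbow")),
    cap(J["left_elbow", ], J["left_wrist", ], 0.040, c("left_elbow", "left_wrist")),
    cap(J["right_elbow", ], J["right_wrist", ], 0.040, c("right_elbow", "right_wrist")),
    cap(J["left_hip", ], J["left_knee", ], 0.070, c("left_hip", "left_knee")),
    cap(J["right_hip", ], J["right_knee", ], 0.070, c("right_hip", "right_knee")),
    cap(J["left_knee", ], J["left_ankle", ], 0.050, c("left_knee", "left_ankle")),
    cap(J["right_knee", ], J["right_ankle", ], 0.050, c("right_knee", "right_ankle")),
    cap(mid_sh, mid_hip, 0.130,
        c("left_shoulder", "right_shoulder", "left_hip", "right_hip")),
    cap(J["left_shoulder", ], J["right_shoulder", ], 0.050,
        c("left_shoulder", "right_shoulder")),
    cap(J["left_hip", ], J["right_hip", ], 0.070, c("left_hip", "right_hip")),
    cap(mid_sh, head_c, 0.050,
        c("nose", "left_shoulder", "right_shoulder")),
    cap(head_c, head_c, 0.100,
        c("nose", "left_eye", "right_eye", "left_ear", "right_ear"))
  )
}

capsule_area <- function(cp) {
  len <- sqrt(sum((cp$p2 - cp$p1)^2))
  2 * pi * cp$r * len + 4 * pi * cp$r^2
}

# uniform-ish surface samples of one capsule
sample_capsule <- function(cp, n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  axis <- cp$p2 - cp$p1
  len <- sqrt(sum(axis^2))
  a_cyl <- 2 * pi * cp$r * len
  a_cap <- 4 * pi * cp$r^2
  on_cyl <- stats::runif(n) < a_cyl / (a_cyl + a_cap)
  e3 <- if (len > 0) axis / len else c(0, 0, 1)
  ref <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * e3) * e3; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  out <- matrix(0, n, 3)
  n_cyl <- sum(on_cyl)
  if (n_cyl) {
    t <- stats::runif(n_cyl); phi <- stats::runif(n_cyl, 0, 2 * pi)
    out[on_cyl, ] <- rep(cp$p1, each = n_cyl) + outer(t * len, e3) +
      cp$r * (outer(cos(phi), e1) + outer(sin(phi), e2))
  }
  n_cap <- n - n_cyl
  if (n_cap) {
    # random points on the unit sphere, attached to a random end
    v <- matrix(stats::rnorm(3 * n_cap), n_cap, 3)
    v <- v / sqrt(rowSums(v^2))
    ends <- ifelse(stats::runif(n_cap) < 0.5, 0, 1)
    ctr <- rep(cp$p1, each = n_cap) + outer(ends * len, e3)
    out[!on_cyl, ] <- ctr + cp$r * v
  }
  out
}

# min distance between the ray segment origin->q (scaled to s in [0, smax])
# and the segment p1->p2
segment_segment_dist <- function(q, p1, p2, smax = 1) {
  d1 <- q * smax          # ray direction segment from origin
  d2 <- p2 - p1
  r <- -p1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-15 && e <= 1e-15) return(sqrt(sum(p1^2)))
  if (a <= 1e-15) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c1 <- sum(d1 * r)
    if (e <= 1e-15) {
      t <- 0; s <- min(max(-c1 / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-15) min(max((b * f - c1 * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c1) / a, 0), 1) }
    }
  }
  sqrt(sum((s * d1 - (p1 + t * d2))^2))
}

# a joint is occluded when a capsule it does not belong to crosses the
# camera ray in front of it
joint_occluded <- function(joint_name, J, capsules) {
  q <- J[joint_name, ]
  for (cp in capsules) {
    if (joint_name %in% cp$touches) next
    # only the part of the ray clearly in front of the joint
    if (segment_segment_dist(q, cp$p1, cp$p2, smax = 0.97) < cp$r) return(TRUE)
  }
  FALSE
}

polygon_area <- function(u, v) {
  n <- length(u)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(u[j] * v - u * v[j])) / 2
}

#' Generate a labeled synthetic depth scene
#'
#' Samples surface points on the capsule body model around the 17-joint
#' skeleton, adds floor-plane and optional clutter points, applies Gaussian
#' depth noise along each viewing ray, and derives the ground truth: 3D
#' joints, 2D joints (projected and rounded to integer pixels), a
#' visibility list (a joint is occluded when a non-adjacent body capsule
#' crosses its camera ray in front of it, when it was explicitly occluded,
#' or when it projects outside the sensor), the person silhouette polygon
#' (convex hull of the projected person points) with its area, and a
#' per-point provenance label. Deterministic under the spec seed.
#'
#' @param spec A [scene_spec()].
#' @return A `labeled_scene`: list with elements `cloud` (tibble `x`, `y`,
#'   `z`, `label`), `joints3d`, `joints2d`, `polygon`, `area`, `cam`,
#'   `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, {
    joints <- skeleton_joints(spec)
    J <- as.matrix(joints[, c("x", "y", "z")])
    rownames(J) <- joints$keypoint
    capsules <- skeleton_capsules(joints, spec$stature)

    areas <- vapply(capsules, capsule_area, numeric(1))
    n_per <- if (spec$n_person > 0) {
      stats::rmultinom(1, spec$n_person, areas / sum(areas))[, 1]
    } else rep(0L, length(capsules))
    person <- do.call(rbind, Map(sample_capsule, capsules, n_per))
    if (is.null(person)) person <- matrix(numeric(0), 0, 3)

    # forced occlusions: the joint's surface neighborhood is hidden
    occluded_forced <- spec$occlusions
    if (length(occluded_forced) && nrow(person)) {
      drop <- rep(FALSE, nrow(person))
      for (kp in occluded_forced) {
        q <- J[kp, ]
        d2 <- (person[, 1] - q[1])^2 + (person[, 2] - q[2])^2 + (person[, 3] - q[3])^2
        drop <- drop | d2 < 0.12^2
      }
      person <- person[!drop, , drop = FALSE]
    }

    floor <- if (spec$n_floor > 0) {
      cbind(
        stats::runif(spec$n_floor, -2.2, 2.2),
        spec$floor_y,
        stats::runif(spec$n_floor, -4.5, -0.8)
      )
    } else matrix(numeric(0), 0, 3)

    clutter <- if (!is.null(spec$clutter)) {
      cl <- spec$clutter
      sweep(
        (matrix(stats::runif(3 * cl$n), cl$n, 3) - 0.5) %*% diag(cl$size),
        2, cl$center, `+`
      )
    } else matrix(numeric(0), 0, 3)

    pts <- rbind(person, floor, clutter)
    label <- rep(c("person", "floor", "clutter"),
                 c(nrow(person), nrow(floor), nrow(clutter)))
    if (spec$noise_sd > 0 && nrow(pts)) {
      # sensor depth noise acts along the viewing ray
      rng <- sqrt(rowSums(pts^2))
      eps <- stats::rnorm(nrow(pts), 0, spec$noise_sd)
      pts <- pts * (1 + eps / rng)
    }
    cloud <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3], label = label)

    self_occ <- vapply(joints$keypoint, joint_occluded, logical(1),
                       J = J, capsules = capsules)
    uv <- project_points(joints, spec$cam)
    ui <- round_half_away(uv$u); vi <- round_half_away(uv$v)
    in_img <- ui >= 0 & ui < spec$cam$width & vi >= 0 & vi < spec$cam$height
    visible <- in_img & !self_occ & !(joints$keypoint %in% occluded_forced)
    joints2d <- tibble::tibble(
      keypoint = joints$keypoint, u = ui, v = vi, visible = as.integer(visible)
    )

    polygon <- tibble::tibble(u = numeric(0), v = numeric(0))
    area <- 0
    if (nrow(person)) {
      puv <- project_points(
        tibble::tibble(x = person[, 1], y = person[, 2], z = person[, 3]),
        spec$cam
      )
      hull <- grDevices::chull(puv$u, puv$v)
      polygon <- tibble::tibble(u = puv$u[hull], v = puv$v[hull])
      area <- polygon_area(polygon$u, polygon$v)
    }

    structure(
      list(cloud = cloud, joints3d = joints, joints2d = joints2d,
           polygon = polygon, area = area, cam = spec$cam, spec = spec),
      class = "labeled_scene"
    )
  })
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat(sprintf(
    "<labeled_scene> subject %s at %.2f m: %d points (%s), %d/17 visible joints, area %.0f px^2\n",
    x$spec$subject, x$spec$distance, nrow(x$cloud),
    paste(names(table(x$cloud$label)), table(x$cloud$label),
          sep = "=", collapse = ", "),
    sum(x$joints2d$visible), x$area
  ))
  invisible(x)
}

#' Generate a walking sequence of scenes
#'
#' Moves the person along the depth axis from `z_from` to `z_to` (meters
#' from the camera) over `n_frames` video frames with a sinusoidal gait
#' cycle, and emits every `stride`-th frame — subsampling a 30 fps
#' recording with stride 6 yields the 5 Hz effective rate used for
#' still-image datasets.
#'
#' @param spec A base [scene_spec()]; per-frame distance, phase and seed
#'   are derived from it.
#' @param n_frames Number of video frames walked (>= 1).
#' @param stride Emit every `stride`-th frame (default 6).
#' @param z_from,z_to Start and end distances in meters.
#' @param fps Recording frame rate (default 30), `cadence` steps/s.
#' @param cadence Gait cadence in step cycles per second (default 0.9).
#' @return A list of `labeled_scene`s (length `ceiling(n_frames / stride)`).
#' @export
generate_walk_sequence <- function(spec, n_frames, stride = 6L,
                                   z_from = 4.2, z_to = 1, fps = 30,
                                   cadence = 0.9) {
  stopifnot(inherits(spec, "scene_spec"), n_frames >= 1, stride >= 1)
  dist <- if (n_frames == 1) z_from else {
    seq(z_from, z_to, length.out = n_frames)
  }
  keep <- seq(1L, as.integer(n_frames), by = as.integer(stride))
  lapply(keep, function(i) {
    s <- spec
    s$distance <- dist[i]
    s$phase <- 2 * pi * cadence * (i - 1) / fps
    s$seed <- as.integer(spec$seed + i)
    generate_scene(s)
  })
}

#' Draw a labeled sample of detection scores
#'
#' Seeded fixture generator for threshold-selection experiments: visible
#' and occluded scores are drawn from clipped-normal distributions
#' (clipping to `[0, 1]`, the score scale of heatmap maxima).
#'
#' @param n_visible,n_occluded Sample sizes (>= 1 each).
#' @param visible,occluded Length-2 `c(mean, sd)` of the two score
#'   distributions.
#' @param seed Optional integer seed.
#' @return A tibble with columns `score` and `visible` (logical), visible
#'   rows first.
#' @export
generate_score_sample <- function(n_visible, n_occluded,
                                  visible = c(0.95, 0.03),
                                  occluded = c(0.45, 0.2),
                                  seed = NULL) {
  stopifnot(n_visible >= 1, n_occluded >= 1)
  run <- function() {
    tibble::tibble(
      score = c(clip01(stats::rnorm(n_visible, visible[1], visible[2])),
                clip01(stats::rnorm(n_occluded, occluded[1], occluded[2]))),
      visible = rep(c(TRUE, FALSE), c(n_visible, n_occluded))
    )
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}
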