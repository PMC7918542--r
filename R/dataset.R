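#' Write a synthetic dataset to disk
#'
#' Lays out a list of labeled scenes as an on-disk dataset:
#' `scenes/*.ply` point clouds, `depth/*.png` 16-bit millimeter depth
#' renders, `annotations.json` (COCO keypoint format, with visibility
#' flags and silhouette polygons), `intrinsics.yaml`, and `manifest.csv`
#' with one row per scene (`file`, `subject`, `split`, `seed`).
#'
#' Splitting follows the still-image protocol: the test split holds all
#' scenes of exactly one randomly chosen subject (leave one subject out),
#' and the remaining subjects' scenes are split into training and
#' validation in the `train : val` proportion (70 : 15 by default). With
#' `leave_one_out = FALSE` all scenes are split at random by the three
#' fractions. Deterministic under `seed`.
#'
#' @param scenes A list of `labeled_scene`s ([generate_scene()]).
#' @param dir Output directory (created if missing).
#' @param split Named fractions `c(train, val, test)` summing to 1.
#' @param leave_one_out Reserve one whole subject for the test split?
#'   Requires at least two subjects.
#' @param seed Integer seed for subject choice and shuffling.
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(scenes, dir, split = c(train = 0.7, val = 0.15, test = 0.15),
                          leave_one_out = TRUE, seed = 1L) {
  stopifnot(length(scenes) >= 1, all(vapply(scenes, inherits, TRUE, "labeled_scene")))
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  subjects <- vapply(scenes, function(s) s$spec$subject, character(1))
  n <- length(scenes)
  assign_split <- with_local_seed(seed, {
    out <- character(n)
    if (leave_one_out) {
      subj <- unique(subjects)
      if (length(subj) < 2) {
        stop("leave-one-subject-out needs at least 2 subjects, got ", length(subj))
      }
      test_subject <- sample(subj, 1)
      out[subjects == test_subject] <- "test"
      rest <- which(subjects != test_subject)
      rest <- sample(rest)
      n_train <- round(length(rest) * split[["train"]] / (split[["train"]] + split[["val"]]))
      out[rest[seq_len(n_train)]] <- "train"
      out[rest[-seq_len(n_train)]] <- "val"
    } else {
      ord <- sample(n)
      n_train <- round(n * split[["train"]])
      n_val <- round(n * split[["val"]])
      out[ord[seq_len(n_train)]] <- "train"
      out[ord[n_train + seq_len(n_val)]] <- "val"
      out[ord[-seq_len(n_train + n_val)]] <- "test"
    }
    out
  })
  dir.create(file.path(dir, "scenes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "depth"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("scene_%03d", seq_len(n))
  for (i in seq_len(n)) {
    write_ply(scenes[[i]]$cloud, file.path(dir, "scenes", paste0(ids[i], ".ply")))
    depth <- render_depth_image(scenes[[i]]$cloud, scenes[[i]]$cam)
    write_depth_png(depth, file.path(dir, "depth", paste0(ids[i], ".png")))
  }
  write_intrinsics(scenes[[1]]$cam, file.path(dir, "intrinsics.yaml"))
  write_coco_annotations(scenes, ids, file.path(dir, "annotations.json"))
  manifest <- tibble::tibble(
    file = ids, subject = subjects, split = assign_split,
    seed = vapply(scenes, function(s) s$spec$seed, integer(1))
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' COCO keypoint annotation JSON
#'
#' `write_coco_annotations()` serializes labeled scenes into the COCO
#' keypoint layout (`images` / `annotations` / `categories`, keypoints as
#' flat `x, y, v` triplets with v = 2 for visible and 0 for unannotated,
#' polygon `segmentation` and `area`). `read_coco_annotations()` parses
#' such a file into tidy tibbles.
#'
#' @param scenes A list of `labeled_scene`s.
#' @param ids Character image identifiers (one per scene).
#' @param path JSON file path.
#' @return `write_coco_annotations()` returns `path` invisibly;
#'   `read_coco_annotations()` a list with tibbles `annotations`
#'   (`image_id`, `ann_id`, `keypoint`, `u`, `v`, `visible`, `area`) and
#'   `images` (`image_id`, `file_name`, `width`, `height`).
#' @export
write_coco_annotations <- function(scenes, ids, path) {
  stopifnot(length(scenes) == length(ids))
  images <- lapply(seq_along(scenes), function(i) {
    list(id = i, file_name = paste0("depth/", ids[i], ".png"),
         width = scenes[[i]]$cam$width, height = scenes[[i]]$cam$height)
  })
  annotations <- lapply(seq_along(scenes), function(i) {
    s <- scenes[[i]]
    kp <- s$joints2d[match(keypoint_names(), s$joints2d$keypoint), ]
    v <- ifelse(kp$visible > 0, 2L, 0L)
    list(
      id = i, image_id = i, category_id = 1L,
      keypoints = as.vector(rbind(kp$u, kp$v, v)),
      num_keypoints = sum(v > 0),
      area = s$area,
      segmentation = list(as.vector(rbind(s$polygon$u, s$polygon$v))),
      iscrowd = 0L
    )
  })
  categories <- list(list(
    id = 1L, name = "person", supercategory = "person",
    keypoints = keypoint_names()
  ))
  jsonlite::write_json(
    list(images = images, annotations = annotations, categories = categories),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_coco_annotations
#' @export
read_coco_annotations <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  images <- purrr::map_dfr(doc$images, function(im) {
    tibble::tibble(image_id = im$id, file_name = im$file_name,
                   width = im$width, height = im$height)
  })
  annotations <- purrr::map_dfr(doc$annotations, function(a) {
    k <- matrix(unlist(a$keypoints), nrow = 3)
    tibble::tibble(
      image_id = a$image_id, ann_id = a$id,
      keypoint = keypoint_names(),
      u = k[1, ], v = k[2, ], visible = as.integer(k[3, ] > 0),
      area = a$area
    )
  })
  list(annotations = annotations, images = images)
}
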