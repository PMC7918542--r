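#' Ground-truth keypoints in heatmap coordinates
#'
#' Maps a scene's annotated 2D joints (original-image pixels) through a
#' crop transform into the model-input frame and down to the heatmap
#' resolution — the coordinate frame a heatmap predictor works in.
#'
#' @param joints2d A tibble with columns `keypoint`, `u`, `v`, `visible`
#'   (original-image pixels).
#' @param transform The [crop_transform()] of the preprocessing run.
#' @param hm_scale Model-input pixels per heatmap pixel (default 4).
#' @return A tibble `keypoint`, `u`, `v`, `visible` in heatmap coordinates.
#' @export
keypoints_to_heatmap_frame <- function(joints2d, transform, hm_scale = 4) {
  stopifnot(inherits(transform, "crop_transform"))
  kp <- tibble::as_tibble(joints2d)
  tibble::tibble(
    keypoint = kp$keypoint,
    u = (kp$u - transform$offset_u) * transform$scale / hm_scale,
    v = (kp$v - transform$offset_v) * transform$scale / hm_scale,
    visible = kp$visible
  )
}

#' Run preprocessing and the toy predictor on one scene
#'
#' Convenience wrapper chaining [preprocess_scene()], [toy_predict()],
#' [decode_heatmaps()] and [map_to_original()] for a labeled synthetic
#' scene, so end-to-end experiments are a single call.
#'
#' @param scene A `labeled_scene`.
#' @param config A [preprocess_config()].
#' @param refine Sub-pixel peak refinement in decoding (see
#'   [decode_heatmaps()]).
#' @param ... Passed to [toy_predict()] (`jitter_sd`, `score_visible`,
#'   `score_occluded`, `seed`).
#' @return A list: `detections` (original-frame tibble with `score`),
#'   `input` (the `model_input`), `heatmaps`.
#' @export
detect_scene <- function(scene, config = preprocess_config(), refine = FALSE, ...) {
  stopifnot(inherits(scene, "labeled_scene"))
  input <- preprocess_scene(scene$cloud, scene$cam, config)
  hm_w <- config$input_w %/% 4L
  hm_h <- config$input_h %/% 4L
  kp_hm <- keypoints_to_heatmap_frame(scene$joints2d, input$transform)
  stack <- toy_predict(kp_hm, width = hm_w, height = hm_h, ...)
  det <- decode_heatmaps(stack, scale = 4, refine = refine)
  det <- map_to_original(det, input$transform)
  list(detections = det, input = input, heatmaps = stack)
}

# ---- run configuration and commands ----------------------------------------

#' Run configuration
#'
#' Bundles paths and parameters for the command wrappers
#' ([cmd_simulate()], [cmd_preprocess()], [cmd_evaluate()]). A YAML or
#' JSON file with a subset of these keys can be loaded with
#' [read_run_config()]; unknown keys are rejected.
#'
#' @param dataset Dataset directory (input of preprocess/evaluate).
#' @param output Output directory.
#' @param n_subjects,scenes_per_subject,stride Simulation layout.
#' @param noise_sd,n_person,n_floor Generator parameters (see
#'   [scene_spec()]).
#' @param predictor Predictor choice; `"toy"` is the built-in contract
#'   implementation.
#' @param jitter_sd,score_visible,score_occluded Toy-predictor noise model.
#' @param threshold Visibility threshold: a number in `(0, 1]` or
#'   `"select"` to pick it from the ROC curve.
#' @param refine Sub-pixel decoding refinement.
#' @param preprocess A [preprocess_config()].
#' @param seed Master seed.
#' @param verbose Log stage messages to stderr?
#' @return A named list of class `run_config`.
#' @export
run_config <- function(dataset = NULL, output = NULL,
                       n_subjects = 2L, scenes_per_subject = 5L, stride = 6L,
                       noise_sd = 0.005, n_person = 4000L, n_floor = 8000L,
                       predictor = "toy",
                       jitter_sd = 0, score_visible = c(1, 0),
                       score_occluded = c(0, 0),
                       threshold = "select", refine = FALSE,
                       preprocess = preprocess_config(),
                       seed = 1L, verbose = FALSE) {
  if (is.numeric(threshold) && (threshold <= 0 || threshold > 1)) {
    stop("a fixed threshold must lie in (0, 1]")
  }
  if (!is.numeric(threshold) && !identical(threshold, "select")) {
    stop('threshold must be numeric or "select"')
  }
  if (!identical(predictor, "toy")) stop("unknown predictor: ", predictor)
  structure(
    list(dataset = dataset, output = output, n_subjects = as.integer(n_subjects),
         scenes_per_subject = as.integer(scenes_per_subject),
         stride = as.integer(stride), noise_sd = noise_sd,
         n_person = as.integer(n_person), n_floor = as.integer(n_floor),
         predictor = predictor, jitter_sd = jitter_sd,
         score_visible = score_visible, score_occluded = score_occluded,
         threshold = threshold, refine = refine, preprocess = preprocess,
         seed = as.integer(seed), verbose = verbose),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML (or JSON) config file.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$preprocess)) {
    cfg$preprocess <- do.call(preprocess_config, cfg$preprocess)
  }
  do.call(run_config, cfg)
}

dp_log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Simulate, preprocess and evaluate commands
#'
#' Thin command wrappers binding the modules into reproducible runs; the
#' `depthpose` script under `inst/exec` exposes them as shell subcommands.
#'
#' `cmd_simulate()` generates one walking sequence per subject and writes
#' the dataset ([write_dataset()]) to `config$output`.
#'
#' `cmd_preprocess()` reads every scene point cloud of
#' `config$dataset`, runs [preprocess_scene()] and writes a model-input
#' PNG + JSON sidecar per scene into `config$output`; per-file failures
#' are reported in the returned status table rather than aborting the run.
#'
#' `cmd_evaluate()` runs the predictor on every scene, applies the
#' visibility threshold (fixed, or ROC-selected when
#' `threshold = "select"`), and writes the metric report (AP/AR suite,
#' confusion counts, per-joint metrics, spatial-error summary) to
#' `config$output`.
#'
#' @param config A [run_config()].
#' @return `cmd_simulate()` the manifest; `cmd_preprocess()` a status
#'   tibble; `cmd_evaluate()` the report list. All invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$output)) stop("config error: output directory required")
  dp_log(config, "simulating %d subjects x %d scenes (seed %d)",
         config$n_subjects, config$scenes_per_subject, config$seed)
  scenes <- list()
  for (s in seq_len(config$n_subjects)) {
    spec <- scene_spec(
      subject = sprintf("s%02d", s),
      stature = 1.60 + 0.08 * ((s - 1) %% 5),  # varied anthropometry
      n_person = config$n_person, n_floor = config$n_floor,
      noise_sd = config$noise_sd,
      seed = config$seed + 10000L * s
    )
    scenes <- c(scenes, generate_walk_sequence(
      spec, n_frames = config$scenes_per_subject * config$stride,
      stride = config$stride
    ))
  }
  manifest <- write_dataset(scenes, config$output, seed = config$seed)
  dp_log(config, "wrote %d scenes to %s", nrow(manifest), config$output)
  invisible(manifest)
}

#' @rdname cmd_simulate
#' @export
cmd_preprocess <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$dataset)) stop("config error: dataset directory required")
  if (is.null(config$output)) stop("config error: output directory required")
  manifest <- utils::read.csv(file.path(config$dataset, "manifest.csv"))
  cam <- read_intrinsics(file.path(config$dataset, "intrinsics.yaml"))
  dir.create(file.path(config$output, "inputs"), recursive = TRUE, showWarnings = FALSE)
  pc <- config$preprocess
  dp_log(config, "preprocess: mls_radius=%s plane_dist=%s z_crop=%s input=%dx%d",
         pc$mls_radius, pc$plane_dist, pc$z_crop, pc$input_w, pc$input_h)
  status <- purrr::map_dfr(manifest$file, function(id) {
    res <- tryCatch({
      cloud <- read_ply(file.path(config$dataset, "scenes", paste0(id, ".ply")))
      mi <- preprocess_scene(cloud, cam, pc)
      write_model_input(mi, file.path(config$output, "inputs", paste0(id, ".png")))
      tibble::tibble(file = id, ok = TRUE, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(file = id, ok = FALSE, error = conditionMessage(e))
    })
    dp_log(config, "%s: %s", id, if (res$ok) "ok" else res$error)
    res
  })
  utils::write.csv(status, file.path(config$output, "preprocess_status.csv"),
                   row.names = FALSE)
  invisible(status)
}

#' @rdname cmd_simulate
#' @export
cmd_evaluate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$dataset)) stop("config error: dataset directory required")
  if (is.null(config$output)) stop("config error: output directory required")
  dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
  coco <- read_coco_annotations(file.path(config$dataset, "annotations.json"))
  cam <- read_intrinsics(file.path(config$dataset, "intrinsics.yaml"))
  manifest <- utils::read.csv(file.path(config$dataset, "manifest.csv"))
  pc <- config$preprocess
  dp_log(config, "evaluating %d scenes (OKS sigmas: %s)",
         nrow(manifest), paste(coco_keypoints()$sigma, collapse = ", "))

  per_scene <- purrr::map(seq_len(nrow(manifest)), function(i) {
    id <- manifest$file[i]
    ann <- coco$annotations[coco$annotations$image_id == i, ]
    cloud <- read_ply(file.path(config$dataset, "scenes", paste0(id, ".ply")))
    input <- preprocess_scene(cloud, cam, pc)
    kp_hm <- keypoints_to_heatmap_frame(ann, input$transform)
    stack <- toy_predict(
      kp_hm, width = pc$input_w %/% 4L, height = pc$input_h %/% 4L,
      jitter_sd = config$jitter_sd,
      score_visible = config$score_visible,
      score_occluded = config$score_occluded,
      seed = config$seed + i
    )
    det <- map_to_original(decode_heatmaps(stack, refine = config$refine),
                           input$transform)
    det$image_id <- i
    list(id = id, det = det, ann = ann)
  })

  detections <- dplyr::bind_rows(purrr::map(per_scene, "det"))
  annotations <- dplyr::bind_rows(purrr::map(per_scene, "ann"))
  ref_vis <- annotations$visible[match(
    paste(detections$image_id, detections$keypoint),
    paste(annotations$image_id, annotations$keypoint)
  )]

  threshold <- config$threshold
  roc <- NULL
  if (identical(threshold, "select")) {
    roc <- build_roc(tibble::tibble(score = detections$score, visible = ref_vis))
    threshold <- select_threshold(roc)
    dp_log(config, "selected threshold %.4f (fpr %.3f, tpr %.3f)",
           threshold, attr(threshold, "fpr"), attr(threshold, "tpr"))
  }
  detections <- filter_visibility(detections, threshold)

  det_eval <- detections
  det_eval$det_id <- 1L
  det_eval <- dplyr::mutate(dplyr::group_by(det_eval, .data$image_id),
                            score = mean(.data$score))
  det_eval <- dplyr::ungroup(det_eval)
  report <- evaluate_keypoints(det_eval, annotations)

  conf <- confusion_counts(detections$visible, ref_vis)
  overall <- precision_recall_f1(conf)
  by_joint <- per_joint_metrics(dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(keypoint = detections$keypoint,
                     pred = detections$visible, ref = ref_vis > 0),
      .data$keypoint
    ),
    tp = sum(.data$ref & .data$pred), fp = sum(!.data$ref & .data$pred),
    fn = sum(.data$ref & !.data$pred), tn = sum(!.data$ref & !.data$pred),
    .groups = "drop"
  ))

  # spatial errors of true-positive keypoints, annotation-derived reference
  tp_det <- detections[detections$visible & ref_vis > 0, ]
  errs <- NULL
  if (nrow(tp_det)) {
    loc <- purrr::map_dfr(split(tp_det, tp_det$image_id), function(d) {
      i <- d$image_id[1]
      depth <- read_depth_png(
        file.path(config$dataset, "depth", paste0(manifest$file[i], ".png")), cam
      )
      ann <- annotations[annotations$image_id == i, ]
      ref3d <- localize_keypoints(ann, depth, cam)
      det3d <- localize_keypoints(d, depth, cam)
      spatial_errors(det3d, ref3d)
    })
    errs <- spatial_error_summary(loc)
    utils::write.csv(errs, file.path(config$output, "spatial_errors.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(by_joint, file.path(config$output, "per_joint_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(
      metrics = as.list(report$summary),
      threshold = as.numeric(threshold),
      roc = if (!is.null(roc)) as.list(glance(roc)) else NULL,
      confusion = as.list(conf),
      precision = overall$precision, recall = overall$recall, f1 = overall$f1
    ),
    file.path(config$output, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(metrics = report, confusion = conf, overall = overall,
                 per_joint = by_joint, spatial = errs,
                 threshold = as.numeric(threshold), roc = roc))
}
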