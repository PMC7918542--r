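new_heatmap_stack <- function(arr) {
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] == 17L)
  dimnames(arr)[[3]] <- keypoint_names()
  structure(arr, class = c("heatmap_stack", "array"))
}

#' @export
print.heatmap_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<heatmap_stack> 17 maps of %dx%d px, score range [%.3g, %.3g]\n",
              d[2], d[1], min(x), max(x)))
  invisible(x)
}

gaussian_map <- function(u0, v0, width, height, amp = 1) {
  u <- seq_len(width) - 1
  v <- seq_len(height) - 1
  amp * exp(-outer((v - v0)^2, (u - u0)^2, `+`) / 2)
}

#' Ground-truth target heatmaps
#'
#' Builds the training targets for a heatmap predictor: each visible
#' keypoint gets a unit-peak 2D Gaussian with standard deviation 1 pixel
#' centred on its (heatmap-frame) coordinate, sampled at pixel centres;
#' occluded keypoints get an all-zero map. The Gaussian is evaluated over
#' the whole map (not truncated). A peak outside the map raises a
#' clipped-peak warning but is still evaluated.
#'
#' @param keypoints A data frame with 17 rows and columns `u`, `v`
#'   (heatmap-frame pixels, 0-based) and `visible`.
#' @param width,height Heatmap size in pixels (default 72 x 96, one quarter
#'   of the 288 x 384 model input).
#' @return A `heatmap_stack` (array `height x width x 17`).
#' @export
make_target_heatmaps <- function(keypoints, width = 72L, height = 96L) {
  kp <- tibble::as_tibble(keypoints)
  stopifnot(nrow(kp) == 17L, all(c("u", "v", "visible") %in% names(kp)))
  vis <- as_visible_list(kp$visible)
  arr <- array(0, c(height, width, 17L))
  for (i in which(vis)) {
    if (kp$u[i] < 0 || kp$u[i] > width - 1 || kp$v[i] < 0 || kp$v[i] > height - 1) {
      warning("keypoint ", i, " peak lies outside the heatmap (clipped peak)")
    }
    arr[, , i] <- gaussian_map(kp$u[i], kp$v[i], width, height)
  }
  new_heatmap_stack(arr)
}

#' Joints mean-squared-error loss
#'
#' The training loss of heatmap pose models: the mean over visible joints
#' of half the mean squared pixel difference between predicted and target
#' heatmaps. Occluded joints' maps do not enter the loss.
#'
#' @param pred,target `heatmap_stack`s of identical shape.
#' @param visible A visible-list (17 binary flags); at least one joint must
#'   be visible.
#' @return A non-negative scalar.
#' @export
joints_mse_loss <- function(pred, target, visible) {
  stopifnot(identical(dim(pred), dim(target)))
  vis <- as_visible_list(visible)
  n <- sum(vis)
  if (n == 0) stop("loss undefined: no visible joints")
  per_joint <- vapply(which(vis), function(i) {
    0.5 * mean((pred[, , i] - target[, , i])^2)
  }, numeric(1))
  mean(per_joint)
}

#' Deterministic toy heatmap predictor
#'
#' A seeded stand-in for a trained CNN backbone, satisfying the predictor
#' contract (ground truth in, heatmap stack out) so the decoding,
#' thresholding and evaluation stages can be exercised end to end. Visible
#' joints get a Gaussian bump at the ground-truth location plus isotropic
#' pixel jitter, with peak amplitude drawn from the visible-score
#' distribution; occluded joints get a bump at a uniformly random location
#' with amplitude from the occluded-score distribution. Score draws are
#' normal, clipped to `[0, 1]`.
#'
#' With `jitter_sd = 0`, `score_visible = c(1, 0)` and
#' `score_occluded = c(0, 0)` the predictor is a noiseless oracle: decoding
#' recovers the ground truth exactly and visibility perfectly.
#'
#' @param keypoints A data frame with 17 rows, columns `u`, `v`
#'   (heatmap-frame ground truth) and `visible`.
#' @param width,height Heatmap size in pixels.
#' @param jitter_sd Positional jitter standard deviation in heatmap pixels.
#' @param score_visible,score_occluded Length-2 `c(mean, sd)` of the peak
#'   amplitude distributions.
#' @param seed Optional integer seed; the same seed yields identical
#'   stacks.
#' @return A `heatmap_stack`.
#' @export
toy_predict <- function(keypoints, width = 72L, height = 96L,
                        jitter_sd = 0,
                        score_visible = c(0.95, 0.03),
                        score_occluded = c(0.45, 0.2),
                        seed = NULL) {
  kp <- tibble::as_tibble(keypoints)
  stopifnot(nrow(kp) == 17L, all(c("u", "v", "visible") %in% names(kp)))
  vis <- as_visible_list(kp$visible)
  run <- function() {
    arr <- array(0, c(height, width, 17L))
    for (i in 1:17) {
      if (vis[i]) {
        amp <- clip01(stats::rnorm(1, score_visible[1], score_visible[2]))
        u0 <- kp$u[i] + stats::rnorm(1, 0, jitter_sd)
        v0 <- kp$v[i] + stats::rnorm(1, 0, jitter_sd)
      } else {
        amp <- clip01(stats::rnorm(1, score_occluded[1], score_occluded[2]))
        u0 <- stats::runif(1, 0, width - 1)
        v0 <- stats::runif(1, 0, height - 1)
      }
      if (amp > 0) arr[, , i] <- gaussian_map(u0, v0, width, height, amp)
    }
    new_heatmap_stack(arr)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
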