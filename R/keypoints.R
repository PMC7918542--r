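#' The 17-keypoint COCO body scheme
#'
#' Returns the ordered set of the 17 COCO body keypoints together with the
#' per-keypoint falloff constants used by the object keypoint similarity
#' (OKS): `sigma` is the normalized standard deviation of human annotation
#' scatter for that keypoint, and `k = 2 * sigma` is the constant entering
#' the OKS exponent.
#'
#' The sigma values are the standard COCO constants: 0.026 (nose), 0.025
#' (eyes), 0.035 (ears), 0.079 (shoulders), 0.072 (elbows), 0.062 (wrists),
#' 0.107 (hips), 0.087 (knees) and 0.089 (ankles).
#'
#' @return A tibble with 17 rows and columns `keypoint` (name), `sigma`,
#'   and `k` (`= 2 * sigma`), in canonical COCO order.
#' @examples
#' coco_keypoints()
#' @export
coco_keypoints <- function() {
  sig <- c(
    nose = 0.026,
    left_eye = 0.025, right_eye = 0.025,
    left_ear = 0.035, right_ear = 0.035,
    left_shoulder = 0.079, right_shoulder = 0.079,
    left_elbow = 0.072, right_elbow = 0.072,
    left_wrist = 0.062, right_wrist = 0.062,
    left_hip = 0.107, right_hip = 0.107,
    left_knee = 0.087, right_knee = 0.087,
    left_ankle = 0.089, right_ankle = 0.089
  )
  tibble::tibble(keypoint = names(sig), sigma = unname(sig), k = 2 * unname(sig))
}

#' @rdname coco_keypoints
#' @export
keypoint_names <- function() coco_keypoints()$keypoint

#' Validate a visibility vector
#'
#' A visible-list is a binary vector of length 17 flagging which keypoints
#' are annotated/visible (1) versus occluded/unannotated (0). Integer COCO
#' visibility codes (0/1/2) are collapsed to binary: any positive code
#' counts as visible.
#'
#' @param visible A logical or numeric vector of length 17.
#' @return A logical vector of length 17.
#' @export
as_visible_list <- function(visible) {
  if (length(visible) != 17L) {
    stop("a visible-list must have exactly 17 entries, got ", length(visible))
  }
  v <- as.numeric(visible)
  if (anyNA(v)) stop("visible-list contains NA")
  v > 0
}
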