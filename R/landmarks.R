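#' 33-point pose landmark topology
#'
#' Landmark names of the standard 33-point full-body pose topology used by
#' on-device pose estimators (nose, eyes, ears, mouth corners, shoulders,
#' elbows, wrists, hand points, hips, knees, ankles, heels, foot indices),
#' in their canonical order.
#'
#' @format A character vector of length 33.
#' @export
pose_landmarks <- c(
  "nose",
  "left_eye_inner", "left_eye", "left_eye_outer",
  "right_eye_inner", "right_eye", "right_eye_outer",
  "left_ear", "right_ear",
  "mouth_left", "mouth_right",
  "left_shoulder", "right_shoulder",
  "left_elbow", "right_elbow",
  "left_wrist", "right_wrist",
  "left_pinky", "right_pinky",
  "left_index", "right_index",
  "left_thumb", "right_thumb",
  "left_hip", "right_hip",
  "left_knee", "right_knee",
  "left_ankle", "right_ankle",
  "left_heel", "right_heel",
  "left_foot_index", "right_foot_index"
)

#' Seven gait class codes
#'
#' Normal gait plus the six simulated impairment classes, in lexicographic
#' order (the order used for deterministic tie-breaking in majority votes).
#'
#' @format A character vector of length 7.
#' @export
gait_classes <- c("ANT", "CIR", "CRO", "NOR", "PAR", "TRE", "VAU")

# anatomical groupings used by the importance analysis
lower_limb_landmarks <- c(
  "left_hip", "right_hip", "left_knee", "right_knee",
  "left_ankle", "right_ankle", "left_heel", "right_heel",
  "left_foot_index", "right_foot_index"
)

upper_limb_landmarks <- c(
  "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_wrist", "right_wrist", "left_pinky", "right_pinky",
  "left_index", "right_index", "left_thumb", "right_thumb"
)

#' Classify landmarks into anatomical groups
#'
#' @param landmark Character vector of landmark names.
#' @return Character vector with values `"lower_limb"`, `"upper_limb"` or
#'   `"head"`.
#' @export
landmark_group <- function(landmark) {
  stopifnot(all(landmark %in% pose_landmarks))
  dplyr::case_when(
    landmark %in% lower_limb_landmarks ~ "lower_limb",
    landmark %in% upper_limb_landmarks ~ "upper_limb",
    TRUE ~ "head"
  )
}
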