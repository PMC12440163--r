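# Pose-sequence preprocessing: empty-frame removal, temporal gap
# interpolation, 30 fps resampling, rolling-median hip centring, frontal
# height rescaling, and 1-second sliding-window segmentation.
#
# The fixed pipeline order is drop_empty -> interpolate -> resample ->
# hip_center -> rescale (frontal only) -> segment; none of the steps reads
# the gait label.

.check_pose_cols <- function(poses) {
  need <- c("video_id", "frame_index", "time_s", "landmark_name",
            "x", "y", "z", "visible")
  miss <- setdiff(need, names(poses))
  if (length(miss)) stop("pose table lacks columns: ",
                         paste(miss, collapse = ", "))
  invisible(poses)
}

#' Drop frames in which no landmark was detected
#'
#' Removes frames whose 33 landmarks are all missing and re-indexes the time
#' axis (frame indices become consecutive; `time_s` keeps original spacing).
#'
#' @param poses Long pose tibble (one or more videos).
#' @return Filtered pose tibble.
#' @export
drop_empty_frames <- function(poses) {
  .check_pose_cols(poses)
  out <- poses |>
    dplyr::group_by(.data$video_id, .data$frame_index) |>
    dplyr::filter(any(.data$visible == 1)) |>
    dplyr::group_by(.data$video_id) |>
    dplyr::mutate(frame_index = dplyr::dense_rank(.data$frame_index)) |>
    dplyr::ungroup()
  if (nrow(out) == 0) stop("no usable frames: every frame is empty")
  out
}

#' Linearly interpolate missing landmarks over time
#'
#' Interior gaps of each landmark channel are filled by linear interpolation
#' between the nearest observed frames; leading/trailing gaps take the
#' nearest observed value. Every landmark must be observed at least once per
#' video.
#'
#' @param poses Long pose tibble.
#' @return Pose tibble with no missing values and `visible = 1` throughout.
#' @export
interpolate_missing <- function(poses) {
  .check_pose_cols(poses)
  fill1 <- function(v, t) {
    ok <- !is.na(v)
    if (all(ok)) return(v)
    stats::approx(t[ok], v[ok], xout = t, rule = 2)$y
  }
  out <- poses |>
    dplyr::group_by(.data$video_id, .data$landmark_name) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$frame_index), ]
      if (all(is.na(d$x))) {
        stop("landmark never observed: ", key$landmark_name,
             " in ", key$video_id)
      }
      d$x <- fill1(d$x, d$frame_index)
      d$y <- fill1(d$y, d$frame_index)
      d$z <- fill1(d$z, d$frame_index)
      d$visible <- 1L
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$video_id, .data$frame_index, .data$landmark_name)
  out
}

#' Resample pose sequences to 30 fps
#'
#' Linear interpolation of every channel onto a uniform 30 Hz grid spanning
#' the original duration. Sequences already at 30 fps pass through unchanged;
#' upsampling (fps < 30) is not supported.
#'
#' @param poses Long pose tibble with no missing values.
#' @param fps Original frame rate (scalar or per-video named vector);
#'   inferred from `time_s` when `NULL`.
#' @return Pose tibble on a 30 fps grid.
#' @export
resample_to_30fps <- function(poses, fps = NULL) {
  .check_pose_cols(poses)
  poses |>
    dplyr::group_by(.data$video_id) |>
    dplyr::group_modify(function(d, key) {
      tu <- sort(unique(d$time_s))
      f <- if (is.null(fps)) 1 / stats::median(diff(tu)) else
        if (length(fps) > 1) fps[[key$video_id]] else fps
      if (f < 30 - 1e-6) stop("fps < 30: upsampling unsupported")
      if (abs(f - 30) < 1e-6) return(d)
      grid <- seq(0, max(tu) - min(tu), by = 1 / 30) + min(tu)
      d |>
        dplyr::group_by(.data$landmark_name) |>
        dplyr::group_modify(function(dd, k2) {
          dd <- dd[order(dd$time_s), ]
          tibble::tibble(
            frame_index = seq_along(grid),
            time_s = grid - min(tu),
            x = stats::approx(dd$time_s, dd$x, xout = grid, rule = 2)$y,
            y = stats::approx(dd$time_s, dd$y, xout = grid, rule = 2)$y,
            z = stats::approx(dd$time_s, dd$z, xout = grid, rule = 2)$y,
            visible = 1L
          )
        }) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$video_id, .data$frame_index, .data$landmark_name)
}

# rolling median over a centred window of half-width `half` frames, clipped
# at the sequence ends
.sliding_median <- function(v, half) {
  n <- length(v)
  vapply(seq_len(n), function(i) {
    stats::median(v[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Centre poses on the rolling-median hip position
#'
#' For every frame, subtracts per channel the median (over a 2-second,
#' 60-frame window centred on the frame, clipped at sequence ends) of the
#' hip centre, i.e. the midpoint of left and right hip. Median centring over
#' 2 s removes camera-position bias and slow drift while preserving the
#' natural hip sway within the window.
#'
#' @param poses Long pose tibble at 30 fps with no missing values.
#' @return Hip-centred pose tibble.
#' @export
hip_center <- function(poses) {
  .check_pose_cols(poses)
  poses |>
    dplyr::group_by(.data$video_id) |>
    dplyr::group_modify(function(d, key) {
      nf <- length(unique(d$frame_index))
      if (nf < 2) stop("sequence too short to hip-centre")
      d <- d[order(d$frame_index, d$landmark_name), ]
      for (ch in c("x", "y", "z")) {
        m <- matrix(d[[ch]], nrow = 33)   # landmarks x frames
        rownames(m) <- sort(pose_landmarks)
        hip <- (m["left_hip", ] + m["right_hip", ]) / 2
        med <- .sliding_median(hip, 30)
        d[[ch]] <- as.vector(sweep(m, 2, med))
      }
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$video_id, .data$frame_index, .data$landmark_name)
}

#' Rescale frontal-view poses to a common stature
#'
#' Divides all channels of each frame by a smoothed body-height estimate (the
#' vertical extent from nose to ankle midpoint, median-smoothed over the same
#' 2 s window as hip centring) and multiplies by a fixed reference height, so
#' perspective size changes along the walk are removed. Sagittal sequences
#' are returned unchanged (their scale is already near-constant).
#'
#' The height estimate is a nose-to-ankle *difference*, which the preceding
#' hip-centring step leaves untouched, so the pipeline position is safe.
#'
#' @param poses Long pose tibble at 30 fps with no missing values.
#' @param view `"frontal"` or `"sagittal"` (scalar, or named per-video
#'   vector/tibble lookup via `manifest`).
#' @param manifest Optional manifest tibble supplying per-video views.
#' @param reference_height Target stature in pixels.
#' @return Rescaled pose tibble.
#' @export
rescale_frontal <- function(poses, view = NULL, manifest = NULL,
                            reference_height = 400) {
  .check_pose_cols(poses)
  lookup <- function(vid) {
    if (!is.null(manifest)) {
      manifest$view[match(vid, manifest$video_id)]
    } else if (length(view) > 1) view[[vid]] else view
  }
  poses |>
    dplyr::group_by(.data$video_id) |>
    dplyr::group_modify(function(d, key) {
      vw <- lookup(key$video_id)
      if (is.null(vw) || is.na(vw)) stop("view unknown for ", key$video_id)
      if (vw == "sagittal") return(d)
      d <- d[order(d$frame_index, d$landmark_name), ]
      ys <- matrix(d$y, nrow = 33)
      rownames(ys) <- sort(pose_landmarks)
      height <- ys["nose", ] - (ys["left_ankle", ] + ys["right_ankle", ]) / 2
      height <- .sliding_median(height, 30)
      if (any(height <= 0)) stop("nonpositive body-height estimate in ",
                                 key$video_id)
      sc <- reference_height / height
      for (ch in c("x", "y", "z")) {
        m <- matrix(d[[ch]], nrow = 33)
        d[[ch]] <- as.vector(sweep(m, 2, sc, `*`))
      }
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$video_id, .data$frame_index, .data$landmark_name)
}

#' Segment preprocessed sequences into 1-second analysis windows
#'
#' Sliding windows of 30 frames with 50% overlap (starts at frames 0, 15,
#' 30, ...); trailing partial windows are discarded. Each window packs its
#' 99 keypoint-channel series into a 30 x 99 matrix (columns named
#' `<landmark>_<channel>`) stored in a list column.
#'
#' @param poses Long pose tibble at 30 fps with no missing values.
#' @param manifest Optional manifest; its `subject_id`, `view`, `direction`
#'   and `label` columns are carried onto each window.
#' @param window Window length in frames. @param step Hop size in frames.
#' @return Tibble with one row per window: `window_id`, `video_id`,
#'   `start_frame`, the manifest metadata when given, and `data` (list of
#'   30 x 99 matrices).
#' @export
segment_windows <- function(poses, manifest = NULL, window = 30L,
                            step = 15L) {
  .check_pose_cols(poses)
  lms <- sort(pose_landmarks)
  cn <- as.vector(t(outer(lms, c("x", "y", "z"), paste, sep = "_")))
  out <- poses |>
    dplyr::group_by(.data$video_id) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$frame_index, d$landmark_name), ]
      nf <- length(unique(d$frame_index))
      if (nf < window) return(tibble::tibble())
      wide <- matrix(NA_real_, nrow = nf, ncol = 99)
      colnames(wide) <- cn
      for (i in seq_along(lms)) {
        rows <- seq(i, by = 33, length.out = nf)
        wide[, 3 * i - 2] <- d$x[rows]
        wide[, 3 * i - 1] <- d$y[rows]
        wide[, 3 * i] <- d$z[rows]
      }
      starts <- seq(0, nf - window, by = step)
      tibble::tibble(
        start_frame = starts,
        data = lapply(starts, function(s) wide[(s + 1):(s + window), ])
      )
    }) |>
    dplyr::ungroup()
  if (nrow(out) == 0) {
    return(tibble::tibble(window_id = character(), video_id = character(),
                          start_frame = integer(), data = list()))
  }
  out$window_id <- sprintf("%s_w%03d", out$video_id,
                           out$start_frame %/% step)
  if (!is.null(manifest)) {
    meta <- manifest[, intersect(c("video_id", "subject_id", "view",
                                   "direction", "label"), names(manifest))]
    out <- dplyr::left_join(out, meta, by = "video_id")
  }
  dplyr::relocate(out, "window_id", "video_id", "start_frame")
}

#' Run the full preprocessing pipeline
#'
#' Applies, in fixed order: empty-frame removal, gap interpolation, 30 fps
#' resampling, rolling-median hip centring, and frontal height rescaling.
#'
#' @param poses Long pose tibble. @param manifest Manifest tibble (supplies
#'   per-video fps and view).
#' @return Preprocessed pose tibble (30 fps, complete, centred, rescaled).
#' @export
preprocess_poses <- function(poses, manifest) {
  fps <- stats::setNames(manifest$fps, manifest$video_id)
  poses |>
    drop_empty_frames() |>
    interpolate_missing() |>
    resample_to_30fps(fps = fps) |>
    hip_center() |>
    rescale_frontal(manifest = manifest)
}
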