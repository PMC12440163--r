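# Preprocessing: empty-frame removal, interpolation, resampling, centring,
# rescaling, windowing.

simple_poses <- function(nT = 100, fps = 30, fill = 0) {
  arr <- array(fill, dim = c(nT, 33, 3))
  pose_tibble_from_array(arr, fps = fps)
}

test_that("empty frames are dropped, order preserved, all-empty rejected", {
  p <- simple_poses(100)
  p$x <- seq_len(nrow(p))   # traceable values
  expect_equal(drop_empty_frames(p), p)     # no empty frames: identity
  kill <- p$frame_index %in% c(5, 6, 50, 90:96)
  p2 <- p
  p2$visible[kill] <- 0L
  out <- drop_empty_frames(p2)
  expect_equal(length(unique(out$frame_index)), 90)
  expect_equal(max(out$frame_index), 90)    # re-indexed
  expect_false(is.unsorted(out$x[out$landmark_name == "nose"]))  # stable
  p3 <- p
  p3$visible <- 0L
  expect_error(drop_empty_frames(p3), "no usable frames")
})

test_that("linear interpolation fills gaps; edges take nearest value", {
  p <- simple_poses(3)
  sel <- p$landmark_name == "nose"
  p$x[sel] <- c(1, NA, 3)
  p$visible[sel][2] <- 0L
  out <- interpolate_missing(p)
  expect_equal(out$x[out$landmark_name == "nose"], c(1, 2, 3))
  expect_true(all(out$visible == 1))

  p <- simple_poses(4)
  sel <- p$landmark_name == "left_wrist"
  p$x[sel] <- c(NA, 5, 5, NA)
  out <- interpolate_missing(p)
  expect_equal(out$x[out$landmark_name == "left_wrist"], c(5, 5, 5, 5))

  p <- simple_poses(4)
  p$x[p$landmark_name == "nose"] <- NA
  expect_error(interpolate_missing(p), "never observed: nose")
})

test_that("interpolation error on a gapped sinusoid obeys the h^2 bound", {
  set.seed(42)
  fps <- 30; nT <- 300; A <- 3; om <- 2 * pi * 1.2
  t <- (seq_len(nT) - 1) / fps
  truth <- A * sin(om * t)
  p <- simple_poses(nT)
  sel <- p$landmark_name == "right_ankle"
  miss <- sort(sample(2:(nT - 1), round(0.1 * nT)))
  v <- truth; v[miss] <- NA
  p$y[sel] <- v
  out <- interpolate_missing(p)
  got <- out$y[out$landmark_name == "right_ankle"]
  runs <- rle(is.na(v))
  h <- (max(runs$lengths[runs$values]) + 1) / fps   # widest gap, seconds
  bound <- h^2 * A * om^2 / 8
  expect_lte(max(abs(got - truth)), bound + 1e-9)
})

test_that("resampling to 30 fps: identity, count, linearity, no upsampling", {
  p <- simple_poses(50, fps = 30)
  p$x <- rnorm(nrow(p))
  expect_equal(
    resample_to_30fps(p, fps = 30),
    dplyr::arrange(p, video_id, frame_index, landmark_name))

  p60 <- simple_poses(120, fps = 60)
  ramp <- 2 * (seq_len(120) - 1) / 60 + 1          # linear in time
  p60$x[p60$landmark_name == "nose"] <- ramp
  out <- resample_to_30fps(p60, fps = 60)
  expect_equal(length(unique(out$frame_index)), 60)
  got <- out$x[out$landmark_name == "nose"]
  tt <- out$time_s[out$landmark_name == "nose"]
  expect_equal(got, 2 * tt + 1, tolerance = 1e-9)  # still exactly linear

  expect_error(resample_to_30fps(simple_poses(10, fps = 25), fps = 25),
               "upsampling")
})

test_that("hip centring removes the rolling-median hip and keeps geometry", {
  nT <- 120
  arr <- array(0, dim = c(nT, 33, 3))
  for (i in seq_len(33)) arr[, i, 1] <- i   # distinct constant x per landmark
  arr[, , 2] <- 7                           # constant y everywhere
  p <- pose_tibble_from_array(arr)
  out <- hip_center(p)
  hips <- out[out$landmark_name %in% c("left_hip", "right_hip"), ]
  hipmid <- tapply((hips$x), hips$frame_index, mean)
  expect_equal(unname(as.numeric(hipmid)), rep(0, nT), tolerance = 1e-12)
  expect_equal(out$y, rep(0, nrow(out)))    # constant removed everywhere

  # inter-landmark distances within a frame unchanged
  f1 <- out[out$frame_index == 1, ]
  expect_equal(diff(sort(f1$x)), diff(sort(seq_len(33))), tolerance = 1e-12)
})

test_that("hip centring matches a brute-force sliding median oracle", {
  set.seed(1)
  nT <- 150
  ramp <- 0.5 * seq_len(nT)                  # slow drift
  wig <- 2 * sin(2 * pi * (seq_len(nT)) / 20)
  offs <- rnorm(33)                          # per-landmark offset
  arr <- array(0, dim = c(nT, 33, 3))
  for (i in seq_len(33)) arr[, i, 1] <- ramp + wig + offs[i]
  p <- pose_tibble_from_array(arr)
  out <- hip_center(p)
  hip_series <- ramp + wig +
    (offs[match("left_hip", pose_landmarks)] +
     offs[match("right_hip", pose_landmarks)]) / 2
  # independent oracle: direct median over clipped windows
  oracle <- vapply(seq_len(nT), function(t) {
    idx <- max(1, t - 30):min(nT, t + 30)
    median(hip_series[idx])
  }, numeric(1))
  got <- out$x[out$landmark_name == "nose"]
  nose <- ramp + wig + offs[match("nose", pose_landmarks)]
  expect_equal(got, nose - oracle, tolerance = 1e-9)
  # window clipping at t = 1 uses frames 1..31
  expect_equal(got[1], nose[1] - median(hip_series[1:31]), tolerance = 1e-12)
  # the fast oscillation survives centring (drift removed, sway kept)
  expect_gt(stats::sd(got), 1)
})

test_that("frontal rescaling undoes a rigid approach-walk size change", {
  # projection oracle: a rigid body whose projected size grows smoothly
  # 1x -> 2x along the walk; after rescaling, interior frame heights are
  # constant within 1% (boundary frames use clipped median windows)
  nT <- 240
  scale_t <- seq(1, 2, length.out = nT)
  base_y <- seq(0, 1.6, length.out = 33)    # distinct height per landmark
  base_y[match("nose", pose_landmarks)] <- 1.55
  base_y[match(c("left_ankle", "right_ankle"), pose_landmarks)] <- 0.05
  arr <- array(0, dim = c(nT, 33, 3))
  for (i in seq_len(33)) {
    arr[, i, 1] <- 100 * scale_t
    arr[, i, 2] <- 300 * base_y[i] * scale_t
  }
  p <- pose_tibble_from_array(arr)
  out <- rescale_frontal(p, view = "frontal")
  w <- tidyr::pivot_wider(out, id_cols = "frame_index",
                          names_from = "landmark_name", values_from = "y")
  height <- w$nose - (w$left_ankle + w$right_ankle) / 2
  interior <- 31:(nT - 31)
  expect_lt(diff(range(height[interior])) / mean(height[interior]), 0.01)

  # global pixel-scale invariance
  p2 <- p
  p2$x <- 2 * p2$x; p2$y <- 2 * p2$y; p2$z <- 2 * p2$z
  out2 <- rescale_frontal(p2, view = "frontal")
  expect_equal(out2$y, out$y, tolerance = 1e-9)

  # a rendered approach walk: median-smoothed stature is stabilised
  cfg <- gait_config(n_subjects = 1, seed = 6, keypoint_jitter_sd = 0,
                     depth_noise_sd = 0, occlusion_prob = 0)
  fro <- render_sequence(1, "NOR", "frontal", "left", cfg)
  man <- tibble::tibble(video_id = fro$video_id[1], view = "frontal",
                        fps = 60)
  pp <- resample_to_30fps(interpolate_missing(fro), fps = 60)
  outw <- rescale_frontal(pp, manifest = man)
  ww <- tidyr::pivot_wider(outw, id_cols = "frame_index",
                           names_from = "landmark_name", values_from = "y")
  hw <- stats::runmed(ww$nose - (ww$left_ankle + ww$right_ankle) / 2, 31)
  ii <- 31:(length(hw) - 31)
  expect_lt(diff(range(hw[ii])) / mean(hw[ii]), 0.05)
  raw <- tidyr::pivot_wider(pp, id_cols = "frame_index",
                            names_from = "landmark_name",
                            values_from = "y")
  hraw <- stats::runmed(raw$nose - (raw$left_ankle + raw$right_ankle) / 2, 31)
  expect_gt(diff(range(hraw[ii])) / mean(hraw[ii]), 0.5)  # before: ~2x

  # sagittal input passes through unchanged
  sag <- dplyr::arrange(simple_poses(50), video_id, frame_index,
                        landmark_name)
  sag$y <- rnorm(nrow(sag))
  expect_equal(rescale_frontal(sag, view = "sagittal"), sag)
})

test_that("window segmentation: counts, overlap, label inheritance", {
  p <- simple_poses(150)
  p$x <- rnorm(nrow(p))
  man <- tibble::tibble(video_id = "v1", subject_id = "S01",
                        view = "sagittal", direction = "right",
                        label = "CIR")
  w <- segment_windows(p, man)
  expect_equal(nrow(w), 9)                       # floor((150-30)/15)+1
  expect_equal(w$start_frame, seq(0, 120, by = 15))
  expect_true(all(w$label == "CIR"))
  expect_equal(dim(w$data[[1]]), c(30, 99))
  # overlap: second half of window 1 equals first half of window 2
  expect_equal(w$data[[1]][16:30, ], w$data[[2]][1:15, ])
  expect_equal(nrow(segment_windows(simple_poses(30))), 1)
  expect_equal(nrow(segment_windows(simple_poses(29))), 0)
})

test_that("preprocessing is label-blind and idempotent", {
  cfg <- gait_config(n_subjects = 1, seed = 8, occlusion_prob = 0.05)
  ds <- make_pose_set(cfg, 1, classes = "ANT", views = "sagittal",
                      directions = "right")
  pp <- preprocess_poses(ds$poses, ds$manifest)
  man2 <- ds$manifest
  man2$label <- "NOR"                            # scrambled labels
  expect_equal(preprocess_poses(ds$poses, ds$manifest)[, c("x", "y", "z")],
               preprocess_poses(ds$poses, man2)[, c("x", "y", "z")])
  # near-idempotence on already-preprocessed output, away from sequence
  # boundaries (clipped median windows are re-estimated at the edges)
  man30 <- ds$manifest
  man30$fps <- 30
  pp2 <- preprocess_poses(pp, man30)
  nf <- max(pp$frame_index)
  interior <- pp$frame_index > 31 & pp$frame_index < nf - 31
  expect_equal(pp2$x[interior], pp$x[interior], tolerance = 0.01)
  expect_equal(pp2$y[interior], pp$y[interior], tolerance = 0.01)
})
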