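# Kinematic walker and dataset generator.

test_that("base gait cycle is 1-periodic and converges at the phase wrap", {
  b <- base_gait_cycle(c(0, 1 - 1e-6))
  a0 <- as.matrix(b[b$phase == 0, c("x", "y", "z")])
  a1 <- as.matrix(b[b$phase > 0.5, c("x", "y", "z")])
  expect_lt(max(abs(a0 - a1)), 1e-4)
})

test_that("left-side pose equals the mirrored right side half a cycle later", {
  b <- base_gait_cycle(c(0.2, 0.7))
  left <- b[b$phase == 0.2 & grepl("^left_", b$landmark_name), ]
  right <- b[b$phase == 0.7 & grepl("^right_", b$landmark_name), ]
  left <- left[order(left$landmark_name), ]
  right <- right[order(right$landmark_name), ]
  expect_equal(left$x, right$x, tolerance = 1e-10)
  expect_equal(left$y, right$y, tolerance = 1e-10)
  expect_equal(left$z, -right$z, tolerance = 1e-10)
})

test_that("heel vertical channel is dominated by the cadence frequency", {
  ph <- seq(0, 1, length.out = 129)[-129]
  b <- base_gait_cycle(ph)
  heel <- b$y[b$landmark_name == "right_heel"]
  mag <- Mod(stats::fft(heel - mean(heel)))[2:64]   # bins 1..63 cycles
  expect_equal(which.max(mag), 1)                   # 1 cycle per cycle
  # heel height has exactly one maximum per cycle
  d <- diff(heel)
  expect_equal(sum(d[-1] < 0 & d[-length(d)] >= 0), 1)
})

test_that("impairments vanish at magnitude zero and reject unknown labels", {
  ph <- seq(0, 0.99, by = 0.01)
  b <- base_gait_cycle(ph)
  expect_equal(apply_impairment(b, "NOR", 1), b)
  for (cl in gait_classes) {
    expect_equal(apply_impairment(b, cl, 0)$y, b$y, tolerance = 1e-12)
  }
  expect_error(apply_impairment(b, "XYZ"), "unknown gait label")
  expect_error(gait_params("walk"), "unknown gait label")
  # a real impairment changes the trajectories
  expect_gt(max(abs(apply_impairment(b, "CIR", 1)$z - b$z)), 0.01)
})

test_that("per-class cycle counts track the clinical ordering", {
  cfg <- gait_config(n_subjects = 2, seed = 7)
  printed <- c(ANT = 7.6, CIR = 5.8, CRO = 7.2, NOR = 4.6, PAR = 10.4,
               TRE = 6.4, VAU = 5.4)
  counts <- vapply(gait_classes, function(cl) {
    mean(vapply(1:2, function(s) {
      count_gait_cycles(render_sequence(s, cl, "sagittal", "right", cfg))
    }, numeric(1)))
  }, numeric(1))
  expect_gte(counts[["NOR"]], 4)       # clinical band for normal walks
  expect_lte(counts[["NOR"]], 7)
  expect_gt(counts[["PAR"]], counts[["NOR"]])  # shuffling gait: most cycles
  expect_gt(cor(counts, printed[gait_classes]), 0.8)
})

test_that("cycle counting matches synthetic ground truth and closed form", {
  tt <- seq(0, 10, by = 1 / 30)
  arr <- array(0, dim = c(length(tt), 33, 3))
  arr[, , 2] <- 5 * sin(2 * pi * 0.5 * tt)   # 5 periods in 10 s
  p <- pose_tibble_from_array(arr)
  expect_lte(abs(count_gait_cycles(p) - 5), 1)
  arr0 <- array(1, dim = c(70, 33, 3))
  expect_error(count_gait_cycles(pose_tibble_from_array(arr0)),
               "no cycles detectable")
  # halving the stride at fixed visible distance doubles the cycle count
  cfg1 <- gait_config(n_subjects = 1, seed = 5, keypoint_jitter_sd = 0,
                      occlusion_prob = 0)
  half <- lapply(cfg1$stride_length, `/`, 2)
  cfg2 <- gait_config(n_subjects = 1, seed = 5, stride_length = half,
                      keypoint_jitter_sd = 0, occlusion_prob = 0)
  c1 <- count_gait_cycles(render_sequence(1, "NOR", "sagittal", "right", cfg1))
  c2 <- count_gait_cycles(render_sequence(1, "NOR", "sagittal", "right", cfg2))
  expect_lte(abs(c2 - 2 * c1), 2)
})

test_that("sagittal projection has constant scale, frontal is pinhole", {
  cfg <- gait_config(n_subjects = 1, seed = 2, keypoint_jitter_sd = 0,
                     depth_noise_sd = 0, occlusion_prob = 0)
  sag <- render_sequence(1, "NOR", "sagittal", "right", cfg)
  w <- tidyr::pivot_wider(sag, id_cols = "frame_index",
                          names_from = "landmark_name",
                          values_from = c("x", "y"))
  thigh <- sqrt((w$x_right_hip - w$x_right_knee)^2 +
                (w$y_right_hip - w$y_right_knee)^2)
  trunk <- sqrt((w$x_right_hip - w$x_right_shoulder)^2 +
                (w$y_right_hip - w$y_right_shoulder)^2)
  expect_lt(diff(range(thigh)) / mean(thigh), 1e-6)
  expect_lt(diff(range(trunk)) / mean(trunk), 0.02)  # pelvic sway only

  # frontal: pixel height scales as 1/distance (subject walks towards the
  # camera when walking left)
  fro <- render_sequence(1, "NOR", "frontal", "left", cfg)
  wf <- tidyr::pivot_wider(fro, id_cols = "frame_index",
                           names_from = "landmark_name",
                           values_from = c("y", "time_s"))
  height <- wf$y_nose - (wf$y_left_ankle + wf$y_right_ankle) / 2
  n <- nrow(wf)
  expect_gt(height[n], 1.5 * height[1])          # grows on approach
  # pinhole: height ~ f*H/d with d linear in time, so 1/height is linear
  # in time (up to gait-phase wobble)
  inv <- 1 / height
  fit <- stats::lm(inv ~ wf$time_s_nose)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("occlusions are Bernoulli at the configured rate", {
  cfg <- gait_config(n_subjects = 1, seed = 9, occlusion_prob = 0.1)
  p <- render_sequence(1, "NOR", "sagittal", "right", cfg)
  n <- nrow(p)
  frac <- mean(p$visible == 0)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac - 0.1), 3 * se)
  expect_true(all(is.na(p$x[p$visible == 0])))
})

test_that("dataset generation is balanced, complete and deterministic", {
  cfg <- gait_config(n_subjects = 2, seed = 4)
  ds <- fixture("ds2", function() simulate_gait_dataset(cfg))
  expect_equal(nrow(ds$manifest), 2 * 7 * 2 * 2)
  expect_true(all(table(ds$manifest$label) == 8))
  expect_true(all(table(ds$manifest$view) == 28))
  expect_setequal(unique(ds$poses$video_id), ds$manifest$video_id)
  # determinism: re-rendering a video reproduces it exactly
  p1 <- render_sequence(2, "TRE", "frontal", "left", cfg)
  expect_identical(p1, ds$poses[ds$poses$video_id == p1$video_id[1], ])
  expect_error(simulate_gait_dataset(gait_config(n_subjects = 1)),
               ">= 2")
})

test_that("dataset round-trips through the text format; overwrite guarded", {
  cfg <- gait_config(n_subjects = 2, seed = 4)
  ds <- fixture("ds2", function() simulate_gait_dataset(cfg))
  dir <- withr::local_tempdir()
  out <- file.path(dir, "ds")
  write_gait_dataset(ds, out)
  expect_error(write_gait_dataset(ds, out), "overwrite")
  back <- read_gait_dataset(out)
  expect_equal(back$manifest, ds$manifest)
  expect_equal(
    dplyr::arrange(back$poses, video_id, frame_index, landmark_name),
    dplyr::arrange(ds$poses, video_id, frame_index, landmark_name),
    tolerance = 1e-9)
})

test_that("bone lengths stay constant within a subject", {
  cfg <- gait_config(n_subjects = 1, seed = 3, keypoint_jitter_sd = 0,
                     depth_noise_sd = 0, occlusion_prob = 0)
  for (cl in c("NOR", "CIR", "CRO")) {
    p <- render_sequence(1, cl, "sagittal", "right", cfg)
    w <- tidyr::pivot_wider(p, id_cols = "frame_index",
                            names_from = "landmark_name",
                            values_from = c("x", "y", "z"))
    sc <- cfg$focal_px / cfg$camera_distance
    shank <- sqrt((w$x_left_knee - w$x_left_ankle)^2 +
                  (w$y_left_knee - w$y_left_ankle)^2 +
                  (w$z_left_knee - w$z_left_ankle)^2)
    expect_lt(diff(range(shank)) / mean(shank), 1e-6)
  }
})
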