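# Shared fixtures, built lazily and cached for the duration of the test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# render only the requested subject x class x view x direction combinations
# (cheaper than simulate_gait_dataset when a test needs a slice)
make_pose_set <- function(config, subjects, classes = gait_classes,
                          views = c("frontal", "sagittal"),
                          directions = c("right", "left")) {
  grid <- expand.grid(direction = directions, view = views, label = classes,
                      subject = subjects, stringsAsFactors = FALSE)
  poses <- vector("list", nrow(grid))
  man <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- render_sequence(g$subject, g$label, g$view, g$direction, config)
    poses[[i]] <- p
    man[[i]] <- tibble::tibble(
      video_id = p$video_id[1], subject_id = sprintf("S%02d", g$subject),
      view = g$view, direction = g$direction, label = g$label,
      fps = config$raw_fps, n_frames = max(p$frame_index))
  }
  list(manifest = dplyr::bind_rows(man), poses = dplyr::bind_rows(poses))
}

make_feature_set <- function(config, subjects, classes = gait_classes,
                             views = c("frontal", "sagittal"),
                             directions = c("right", "left"),
                             catalog = feature_catalog("reduced")) {
  ds <- make_pose_set(config, subjects, classes, views, directions)
  pp <- preprocess_poses(ds$poses, ds$manifest)
  w <- segment_windows(pp, ds$manifest)
  compute_feature_matrix(w, catalog)
}

# small hand-buildable synthetic feature table: per-class mean shifts on a
# few informative columns plus noise and a mild subject effect; used to
# exercise the CV machinery without the full pipeline
toy_feature_set <- function(n_subjects = 6, n_windows = 3, n_features = 12,
                            n_informative = 6, effect = 3, seed = 1,
                            views = c("frontal", "sagittal")) {
  set.seed(seed)
  grid <- expand.grid(win = seq_len(n_windows), direction = "right",
                      view = views, label = gait_classes,
                      subject = seq_len(n_subjects),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  x <- matrix(rnorm(n * n_features), n, n_features)
  cls <- match(grid$label, gait_classes)
  for (j in seq_len(n_informative)) {
    x[, j] <- x[, j] + effect * sin(cls + j) + 0.3 * grid$subject / n_subjects
  }
  colnames(x) <- sprintf("left_knee_x__feat%02d", seq_len(n_features))
  dplyr::bind_cols(
    tibble::tibble(
      window_id = sprintf("t%04d", seq_len(n)),
      video_id = sprintf("S%02d_%s_%s_%s", grid$subject, grid$label,
                         substr(grid$view, 1, 3), grid$direction),
      subject_id = sprintf("S%02d", grid$subject),
      view = grid$view, direction = grid$direction, label = grid$label,
      start_frame = 0L),
    tibble::as_tibble(x))
}

# long pose tibble from a T x 33 x 3 array (test construction helper)
pose_tibble_from_array <- function(arr, fps = 30, video_id = "v1") {
  nT <- dim(arr)[1]
  tibble::tibble(
    video_id = video_id,
    frame_index = rep(seq_len(nT), each = 33),
    time_s = rep((seq_len(nT) - 1) / fps, each = 33),
    landmark_name = rep(pose_landmarks, nT),
    x = as.vector(t(arr[, , 1])),
    y = as.vector(t(arr[, , 2])),
    z = as.vector(t(arr[, , 3])),
    visible = 1L
  )
}

# the 10-subject two-view dataset at default impairment magnitudes used by
# the end-to-end acceptance checks
acceptance_features <- function() {
  fixture("acceptance_features", function() {
    cfg <- gait_config(n_subjects = 10, seed = 20260926)
    make_feature_set(cfg, subjects = 1:10)
  })
}

run_oracle <- function(series_mat, catalog) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  sf <- file.path(dir, "series.csv")
  cf <- file.path(dir, "catalog.csv")
  of <- file.path(dir, "oracle.csv")
  utils::write.table(series_mat, sf, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  readr::write_csv(catalog, cf, na = "")
  script <- testthat::test_path("oracle_features.py")
  status <- system2("python", c(script, sf, cf, of))
  stopifnot(status == 0)
  as.matrix(utils::read.csv(of, header = FALSE))
}
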