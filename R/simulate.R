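# Synthetic multi-view pathological gait generator.
#
# A procedural kinematic walker produces 33-landmark 3D trajectories for one
# full overground walk; per-class modifiers impose the clinical signatures of
# the six impairment classes; a pinhole camera model renders frontal and
# sagittal pixel coordinates with keypoint jitter, noisy relative depth and
# Bernoulli occlusions.

# per-class walking-speed signatures, expressed as the mean stride length (m)
# and cadence (strides/s) reached at impairment magnitude 1. Stride means are
# calibrated so that the number of gait cycles visible in a rendered video
# (visible path length / stride) matches typical per-class cycle counts of
# clinical 10 m walks (ANT 7.6, CIR 5.8, CRO 7.2, NOR 4.6, PAR 10.4, TRE 6.4,
# VAU 5.4 cycles per video).
.class_stride_mean <- c(
  ANT = 6.4 / 7.6, CIR = 6.4 / 5.8, CRO = 6.4 / 7.2, NOR = 6.4 / 4.6,
  PAR = 6.4 / 10.4, TRE = 6.4 / 6.4, VAU = 6.4 / 5.4
)
.class_cadence_mean <- c(
  ANT = 0.92, CIR = 0.85, CRO = 0.88, NOR = 0.95,
  PAR = 1.15, TRE = 0.90, VAU = 0.90
)

#' Simulation configuration for the synthetic gait dataset
#'
#' Bundles every knob of the generator. The defaults describe the emulated
#' study protocol: a 10 m straight overground walk recorded at 60 fps by two
#' cameras placed 4 m from the walking line (one frontal, one sagittal), with
#' asymmetric impairments performed on the right side. `visible_length` is the
#' stretch of the path inside the camera field of view; frames outside it are
#' not rendered (mimicking the exclusion of frames without a detected pose).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param walk_distance Path length in metres.
#' @param raw_fps Camera frame rate of the raw recordings (>= 30).
#' @param cadence_hz Named list per gait class of `c(lo, hi)` cadence ranges
#'   (strides per second) reached at impairment magnitude 1.
#' @param stride_length Named list per gait class of `c(lo, hi)` stride-length
#'   ranges in metres reached at impairment magnitude 1.
#' @param impairment_magnitude Named numeric vector in `[0, 1]` per class;
#'   scales every class signature (0 reduces every class to normal gait).
#' @param affected_side `"right"` (default) or `"left"`.
#' @param keypoint_jitter_sd Gaussian jitter SD on pixel x/y, in px.
#' @param depth_noise_sd Gaussian noise SD on the relative-depth channel, in
#'   the same pixel-like units (larger than `keypoint_jitter_sd` by default:
#'   monocular depth is the least reliable channel).
#' @param occlusion_prob Probability that a landmark is missing in a frame.
#' @param camera_distance Camera distance from the walking line, metres.
#' @param visible_length Path length covered by the camera field of view, m.
#' @param focal_px Pinhole focal length in pixels.
#' @param seed Integer seed fixing every downstream draw.
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(n_subjects = 10,
                        walk_distance = 10,
                        raw_fps = 60,
                        cadence_hz = NULL,
                        stride_length = NULL,
                        impairment_magnitude = NULL,
                        affected_side = c("right", "left"),
                        keypoint_jitter_sd = 2,
                        depth_noise_sd = 6,
                        occlusion_prob = 0.02,
                        camera_distance = 4,
                        visible_length = 6.4,
                        focal_px = 1400,
                        seed = 1L) {
  affected_side <- match.arg(affected_side)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (walk_distance <= 0) stop("walk_distance must be positive")
  if (raw_fps < 30) stop("raw_fps must be >= 30")
  if (occlusion_prob < 0 || occlusion_prob >= 1) {
    stop("occlusion_prob must be in [0, 1)")
  }
  if (visible_length <= 0 || visible_length > walk_distance) {
    stop("visible_length must be in (0, walk_distance]")
  }
  rng <- function(mean, half) c(mean * (1 - half), mean * (1 + half))
  if (is.null(stride_length)) {
    stride_length <- lapply(.class_stride_mean, rng, half = 0.07)
  }
  if (is.null(cadence_hz)) {
    cadence_hz <- lapply(.class_cadence_mean, rng, half = 0.05)
  }
  stopifnot(all(gait_classes %in% names(stride_length)),
            all(gait_classes %in% names(cadence_hz)))
  for (cl in gait_classes) {
    s <- stride_length[[cl]]; cz <- cadence_hz[[cl]]
    if (length(s) != 2 || s[1] <= 0 || s[2] < s[1]) {
      stop("degenerate stride_length range for ", cl)
    }
    if (length(cz) != 2 || cz[1] <= 0 || cz[2] < cz[1]) {
      stop("degenerate cadence_hz range for ", cl)
    }
  }
  if (is.null(impairment_magnitude)) {
    impairment_magnitude <- stats::setNames(rep(1, 7), gait_classes)
  }
  if (is.null(names(impairment_magnitude))) {
    impairment_magnitude <- stats::setNames(
      rep_len(impairment_magnitude, 7), gait_classes)
  }
  if (any(impairment_magnitude < 0 | impairment_magnitude > 1)) {
    stop("impairment_magnitude must lie in [0, 1]")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), walk_distance = walk_distance,
    raw_fps = raw_fps, cadence_hz = cadence_hz, stride_length = stride_length,
    impairment_magnitude = impairment_magnitude, affected_side = affected_side,
    keypoint_jitter_sd = keypoint_jitter_sd, depth_noise_sd = depth_noise_sd,
    occlusion_prob = occlusion_prob, camera_distance = camera_distance,
    visible_length = visible_length, focal_px = focal_px,
    seed = as.integer(seed)
  ), class = "gait_config")
}

# evaluate code under a temporary RNG state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.hash_seed <- function(...) {
  v <- c(...)
  h <- 0
  for (x in v) h <- (h * 131 + as.numeric(x)) %% 2147483629
  as.integer(h) + 1L
}

#' Per-class kinematic gait modifiers
#'
#' Returns the walker modifiers encoding one class's clinical signature at a
#' given impairment magnitude. All modifiers are zero (and scales are one) at
#' magnitude 0, so every class degenerates to normal gait; each modifier
#' scales linearly with magnitude.
#'
#' @param label One of [gait_classes].
#' @param magnitude Impairment magnitude in `[0, 1]`.
#' @return Named list of modifiers: `circumduction_amp` (m, lateral swing arc,
#'   CIR), `pelvic_drop_amp` (m, contralateral stance-phase pelvis drop, TRE),
#'   `stance_asymmetry` (fractional reduction of affected stance time and step
#'   length, ANT), `knee_hip_flexion_offset` (fractional lowering of hip
#'   height via sustained flexion, CRO), `trunk_pitch` (rad, forward stoop),
#'   `arm_swing_scale`, `vault_rise` (m, pelvis lift on unaffected stance,
#'   VAU), and the walking-speed scales `stride_scale` / `cadence_scale`
#'   relative to normal gait.
#' @export
gait_params <- function(label, magnitude = 1) {
  if (!(is.character(label) && length(label) == 1 && label %in% gait_classes)) {
    stop("unknown gait label: ", paste(label, collapse = ", "))
  }
  if (magnitude < 0 || magnitude > 1) stop("magnitude must be in [0, 1]")
  m <- if (label == "NOR") 0 else magnitude
  p <- list(
    circumduction_amp = 0, pelvic_drop_amp = 0, stance_asymmetry = 0,
    knee_hip_flexion_offset = 0, trunk_pitch = 0, arm_swing_scale = 1,
    vault_rise = 0,
    stride_scale = 1 + m * (.class_stride_mean[[label]] / .class_stride_mean[["NOR"]] - 1),
    cadence_scale = 1 + m * (.class_cadence_mean[[label]] / .class_cadence_mean[["NOR"]] - 1)
  )
  switch(label,
    NOR = p,
    CIR = { p$circumduction_amp <- 0.14 * m; p },
    TRE = { p$pelvic_drop_amp <- 0.05 * m; p },
    ANT = { p$stance_asymmetry <- 0.30 * m; p },
    CRO = {
      p$knee_hip_flexion_offset <- 0.14 * m
      p$trunk_pitch <- 0.10 * m
      p
    },
    PAR = {
      p$trunk_pitch <- 0.30 * m
      p$arm_swing_scale <- 1 - 0.80 * m
      p
    },
    VAU = { p$vault_rise <- 0.06 * m; p }
  )
}

.anthro <- function(height) {
  H <- height
  list(
    H = H,
    hip_w = 0.0955 * H,       # hip joint lateral half-offset
    shoulder_w = 0.1295 * H,  # shoulder lateral half-offset
    thigh = 0.245 * H,
    shank = 0.246 * H,
    leg = 0.491 * H,
    ankle_h = 0.039 * H,
    trunk = 0.288 * H,        # pelvis centre to shoulder centre
    neck = 0.11 * H,          # shoulder centre to head centre (eye level)
    upper_arm = 0.188 * H,
    forearm = 0.145 * H,
    foot_back = 0.05 * H,     # ankle -> heel
    foot_front = 0.10 * H,    # ankle -> toe
    lift = 0.08 * H           # ankle clearance amplitude
  )
}

# ankle trajectory of one leg along the walk.
# Phi: global leg phase (cycles); d: duty factor; x0: plant offset.
.leg_traj <- function(Phi, d, S, x0, an) {
  k <- floor(Phi)
  ph <- Phi - k
  sw <- ph >= d
  u <- ifelse(sw, (ph - d) / (1 - d), 0)
  g <- ifelse(sw, u - sin(2 * pi * u) / (2 * pi), 0)
  h0 <- 0.6 * d                       # heel-off at 60% of stance
  w <- pmin(pmax((ph - h0) / (1 - h0), 0), 1)
  list(
    x = S * (k + g) + x0,
    y = an$ankle_h + an$lift * sin(pi * w)^2,
    u = u, swing = sw, ph = ph
  )
}

# 3D two-link inverse kinematics, knee bending forward (+x). Returns knee
# position and the (possibly reach-clamped) ankle, preserving bone lengths.
.knee_ik <- function(hx, hy, hz, ax, ay, az, L1, L2) {
  dx <- ax - hx; dy <- ay - hy; dz <- az - hz
  D <- sqrt(dx^2 + dy^2 + dz^2)
  Dm <- pmin(D, 0.999 * (L1 + L2))
  sc <- Dm / pmax(D, 1e-12)
  dx <- dx * sc; dy <- dy * sc; dz <- dz * sc
  a <- (L1^2 - L2^2 + Dm^2) / (2 * Dm)
  h <- sqrt(pmax(L1^2 - a^2, 0))
  ux <- dx / Dm; uy <- dy / Dm; uz <- dz / Dm
  # knee offset direction: forward axis orthogonalised against the leg axis
  nx <- 1 - ux * ux; ny <- -ux * uy; nz <- -ux * uz
  nn <- sqrt(pmax(nx^2 + ny^2 + nz^2, 1e-12))
  list(
    knee = list(x = hx + a * ux + h * nx / nn,
                y = hy + a * uy + h * ny / nn,
                z = hz + a * uz + h * nz / nn),
    ankle = list(x = hx + dx, y = hy + dy, z = hz + dz)
  )
}

# Core walker: body-frame trajectories (x forward along path incl. advance,
# y up, z towards the walker's left) for every landmark at times tt.
.walker_core <- function(tt, an, S, f, duty, mods, affected) {
  aff_right <- affected == "right"
  side_sign <- if (aff_right) -1 else 1   # lateral sign of the affected side
  Phi_L <- f * tt
  Phi_R <- f * tt + 0.5
  d_L <- duty * (1 - (!aff_right) * mods$stance_asymmetry)
  d_R <- duty * (1 - aff_right * mods$stance_asymmetry)
  # plant offsets: symmetric double support, affected step shortened
  c0 <- -0.25 * S
  delta <- 0.25 * mods$stance_asymmetry * S
  x0_L <- 0 - (!aff_right) * delta
  x0_R <- -S / 2 - aff_right * delta

  leg_L <- .leg_traj(Phi_L, d_L, S, x0_L, an)
  leg_R <- .leg_traj(Phi_R, d_R, S, x0_R, an)
  leg_aff <- if (aff_right) leg_R else leg_L
  leg_una <- if (aff_right) leg_L else leg_R

  # pelvis
  x_p <- S * f * tt + c0
  crouch <- mods$knee_hip_flexion_offset
  y0 <- an$ankle_h + 0.88 * an$leg * (1 - crouch)
  vault <- mods$vault_rise * sin(pi * leg_aff$u)^2 * leg_aff$swing
  y_p <- y0 - 0.012 * an$H * cos(4 * pi * Phi_L) + vault
  z_p <- 0.015 * an$H * sin(2 * pi * Phi_L)

  # Trendelenburg: contralateral pelvic drop during affected stance
  st_aff <- leg_aff$ph < (if (aff_right) d_R else d_L)
  shape <- sin(pi * leg_aff$ph / (if (aff_right) d_R else d_L))^1 * st_aff
  drop <- mods$pelvic_drop_amp * shape
  hipL_y <- y_p - (if (aff_right) drop else 0.15 * drop)
  hipR_y <- y_p - (if (aff_right) 0.15 * drop else drop)

  hipL <- list(x = x_p, y = hipL_y, z = z_p + an$hip_w)
  hipR <- list(x = x_p, y = hipR_y, z = z_p - an$hip_w)

  # circumduction: lateral swing arc of the affected leg, away from midline
  circ <- mods$circumduction_amp * sin(pi * leg_aff$u) * leg_aff$swing
  ankleL_z <- z_p + an$hip_w + (if (!aff_right) circ else 0)
  ankleR_z <- z_p - an$hip_w - (if (aff_right) circ else 0)

  ikL <- .knee_ik(hipL$x, hipL$y, hipL$z, leg_L$x, leg_L$y, ankleL_z,
                  an$thigh, an$shank)
  ikR <- .knee_ik(hipR$x, hipR$y, hipR$z, leg_R$x, leg_R$y, ankleR_z,
                  an$thigh, an$shank)

  foot <- function(ik) {
    list(
      heel = list(x = ik$ankle$x - an$foot_back,
                  y = pmax(ik$ankle$y - 0.030 * an$H, 0.004 * an$H),
                  z = ik$ankle$z),
      toe = list(x = ik$ankle$x + an$foot_front,
                 y = pmax(ik$ankle$y - 0.033 * an$H, 0.004 * an$H),
                 z = ik$ankle$z)
    )
  }
  ftL <- foot(ikL); ftR <- foot(ikR)

  # trunk, pitched forward; slight lateral lean with Trendelenburg
  th <- mods$trunk_pitch
  sh_c <- list(
    x = x_p + an$trunk * sin(th),
    y = y_p + an$trunk * cos(th),
    z = z_p + side_sign * 0.7 * drop
  )
  shL <- list(x = sh_c$x, y = sh_c$y, z = sh_c$z + an$shoulder_w)
  shR <- list(x = sh_c$x, y = sh_c$y, z = sh_c$z - an$shoulder_w)

  # arms: sagittal pendulum counter-phased to the same-side leg
  A_arm <- 0.35 * mods$arm_swing_scale
  arm <- function(sh, Phi) {
    al <- -A_arm * sin(2 * pi * Phi) + 0.3 * th
    be <- al + 0.45
    elbow <- list(x = sh$x + an$upper_arm * sin(al),
                  y = sh$y - an$upper_arm * cos(al), z = sh$z)
    wrist <- list(x = elbow$x + an$forearm * sin(be),
                  y = elbow$y - an$forearm * cos(be), z = elbow$z)
    list(elbow = elbow, wrist = wrist,
         hdir_x = sin(be + 0.2), hdir_y = -cos(be + 0.2))
  }
  armL <- arm(shL, Phi_L); armR <- arm(shR, Phi_R)
  hand <- function(a, wz_sign) {
    w <- a$wrist
    list(
      pinky = list(x = w$x + 0.040 * an$H * a$hdir_x,
                   y = w$y + 0.040 * an$H * a$hdir_y,
                   z = w$z - wz_sign * 0.012 * an$H),
      index = list(x = w$x + 0.045 * an$H * a$hdir_x,
                   y = w$y + 0.045 * an$H * a$hdir_y,
                   z = w$z + wz_sign * 0.010 * an$H),
      thumb = list(x = w$x + 0.030 * an$H * a$hdir_x,
                   y = w$y + 0.030 * an$H * a$hdir_y,
                   z = w$z + wz_sign * 0.020 * an$H)
    )
  }
  handL <- hand(armL, 1); handR <- hand(armR, -1)

  # head: rigid offsets from the head centre, pitched with the trunk
  hd <- list(x = sh_c$x + an$neck * sin(th),
             y = sh_c$y + an$neck * cos(th), z = sh_c$z)
  fwd_x <- cos(th); fwd_y <- -sin(th)
  hpt <- function(fwd, up, lat) {
    list(x = hd$x + fwd * fwd_x, y = hd$y + fwd * fwd_y + up, z = hd$z + lat)
  }
  H <- an$H
  lm <- list(
    nose = hpt(0.050 * H, 0, 0),
    left_eye_inner = hpt(0.040 * H, 0.012 * H, 0.015 * H),
    left_eye = hpt(0.038 * H, 0.012 * H, 0.028 * H),
    left_eye_outer = hpt(0.034 * H, 0.012 * H, 0.040 * H),
    right_eye_inner = hpt(0.040 * H, 0.012 * H, -0.015 * H),
    right_eye = hpt(0.038 * H, 0.012 * H, -0.028 * H),
    right_eye_outer = hpt(0.034 * H, 0.012 * H, -0.040 * H),
    left_ear = hpt(0, 0, 0.060 * H),
    right_ear = hpt(0, 0, -0.060 * H),
    mouth_left = hpt(0.045 * H, -0.025 * H, 0.018 * H),
    mouth_right = hpt(0.045 * H, -0.025 * H, -0.018 * H),
    left_shoulder = shL, right_shoulder = shR,
    left_elbow = armL$elbow, right_elbow = armR$elbow,
    left_wrist = armL$wrist, right_wrist = armR$wrist,
    left_pinky = handL$pinky, right_pinky = handR$pinky,
    left_index = handL$index, right_index = handR$index,
    left_thumb = handL$thumb, right_thumb = handR$thumb,
    left_hip = hipL, right_hip = hipR,
    left_knee = ikL$knee, right_knee = ikR$knee,
    left_ankle = ikL$ankle, right_ankle = ikR$ankle,
    left_heel = ftL$heel, right_heel = ftR$heel,
    left_foot_index = ftL$toe, right_foot_index = ftR$toe
  )
  lm <- lm[pose_landmarks]
  n <- length(tt)
  arr <- array(NA_real_, dim = c(n, 33, 3),
               dimnames = list(NULL, pose_landmarks, c("x", "y", "z")))
  for (i in seq_along(lm)) {
    arr[, i, 1] <- lm[[i]]$x
    arr[, i, 2] <- lm[[i]]$y
    arr[, i, 3] <- lm[[i]]$z
  }
  arr
}

.cycle_tibble <- function(arr, phase) {
  np <- length(phase)
  tibble::tibble(
    phase = rep(phase, each = 33),
    landmark_name = rep(pose_landmarks, np),
    x = as.vector(t(arr[, , 1, drop = TRUE])),
    y = as.vector(t(arr[, , 2, drop = TRUE])),
    z = as.vector(t(arr[, , 3, drop = TRUE]))
  )
}

#' Base (normal) gait cycle of the kinematic walker
#'
#' Evaluates the normal-gait walker at the given cycle phases and returns the
#' skeleton in a pelvis-relative body frame (`x` forward, `y` up, `z` towards
#' the walker's left, metres). The trajectories are continuous and 1-periodic
#' in phase; the absolute pelvis advance (`stride * phase`, removed here) is
#' available through the `"stride"` attribute.
#'
#' @param phase Numeric vector of cycle phases (fractions of a full stride).
#' @param anthropometry Subject stature in metres.
#' @param stride Stride length (m/cycle). @param cadence Cadence (strides/s).
#' @param duty Stance duty factor.
#' @return A tibble with columns `phase`, `landmark_name`, `x`, `y`, `z`, of
#'   class `gait_cycle`; attributes `anthropometry`, `stride`, `cadence`,
#'   `duty`.
#' @export
base_gait_cycle <- function(phase, anthropometry = 1.7, stride = 6.4 / 4.6,
                            cadence = 0.95, duty = 0.62) {
  stopifnot(all(phase >= 0), all(phase < 1))
  an <- .anthro(anthropometry)
  arr <- .walker_core(phase / cadence, an, stride, cadence, duty,
                      gait_params("NOR"), "right")
  arr[, , 1] <- arr[, , 1] - stride * phase   # pelvis-relative forward axis
  out <- .cycle_tibble(arr, phase)
  attr(out, "anthropometry") <- anthropometry
  attr(out, "stride") <- stride
  attr(out, "cadence") <- cadence
  attr(out, "duty") <- duty
  class(out) <- c("gait_cycle", class(out))
  out
}

#' Apply a gait-impairment signature to a base cycle
#'
#' Re-evaluates the walker over the phases of `cycle` with the kinematic
#' modifiers of the requested class. `label = "NOR"` or `magnitude = 0`
#' reproduce the input exactly.
#'
#' @param cycle A `gait_cycle` from [base_gait_cycle()].
#' @param label Gait class, one of [gait_classes].
#' @param magnitude Impairment magnitude in `[0, 1]`.
#' @param params Optional modifier list overriding [gait_params()].
#' @param affected_side `"right"` or `"left"`.
#' @return A `gait_cycle` tibble of the same shape as `cycle`.
#' @export
apply_impairment <- function(cycle, label, magnitude = 1, params = NULL,
                             affected_side = "right") {
  stopifnot(inherits(cycle, "gait_cycle"))
  if (is.null(params)) params <- gait_params(label, magnitude)
  phase <- unique(cycle$phase)
  an <- .anthro(attr(cycle, "anthropometry"))
  S <- attr(cycle, "stride") * params$stride_scale
  f <- attr(cycle, "cadence") * params$cadence_scale
  arr <- .walker_core(phase / f, an, S, f, attr(cycle, "duty"), params,
                      affected_side)
  arr[, , 1] <- arr[, , 1] - S * phase
  out <- .cycle_tibble(arr, phase)
  for (a in c("anthropometry", "duty")) attr(out, a) <- attr(cycle, a)
  attr(out, "stride") <- S
  attr(out, "cadence") <- f
  class(out) <- c("gait_cycle", class(out))
  out
}

# deterministic per-subject draws (anthropometry + per-class gait parameters)
.subject_params <- function(config, subject) {
  .with_seed(.hash_seed(config$seed, 104729, subject), {
    H <- min(max(stats::rnorm(1, 1.70, 0.07), 1.50), 1.95)
    cls <- lapply(gait_classes, function(cl) {
      s <- stats::runif(1, config$stride_length[[cl]][1],
                        config$stride_length[[cl]][2])
      f <- stats::runif(1, config$cadence_hz[[cl]][1],
                        config$cadence_hz[[cl]][2])
      c(stride = s, cadence = f)
    })
    names(cls) <- gait_classes
    list(height = H, class_gait = cls)
  })
}

#' Render one synthetic gait video as a pose-landmark time series
#'
#' Simulates one subject walking the full path under one gait class, projects
#' the skeleton through the pinhole camera of the requested view, and emits
#' the frames during which the subject is inside the camera field of view.
#' The frontal view shows genuine perspective (pixel size proportional to
#' 1/distance); the sagittal view has constant scale. The relative-depth
#' channel (`z`, hip-relative, pixel-like units) carries more noise than the
#' planar channels; occluded landmarks are missing (`NA`, `visible = 0`).
#'
#' @param subject Subject index (1-based).
#' @param label Gait class.
#' @param view `"frontal"` or `"sagittal"`.
#' @param direction Walking direction, `"left"` or `"right"`. Walking right
#'   moves away from the frontal camera; walking left moves towards it.
#' @param config A [gait_config()].
#' @return Tibble with columns `video_id`, `frame_index`, `time_s`,
#'   `landmark_name`, `x`, `y`, `z`, `visible`.
#' @export
render_sequence <- function(subject, label, view = c("frontal", "sagittal"),
                            direction = c("right", "left"), config) {
  view <- match.arg(view)
  direction <- match.arg(direction)
  stopifnot(label %in% gait_classes, inherits(config, "gait_config"))
  if (config$walk_distance <= 0) stop("walk_distance must be positive")
  sp <- .subject_params(config, subject)
  an <- .anthro(sp$height)
  mag <- if (label == "NOR") 0 else config$impairment_magnitude[[label]]
  params <- gait_params(label, mag)
  # walking speed: interpolate subject's class draw towards their NOR draw
  nor <- sp$class_gait[["NOR"]]; clg <- sp$class_gait[[label]]
  S <- nor[["stride"]] + mag * (clg[["stride"]] - nor[["stride"]])
  f <- nor[["cadence"]] + mag * (clg[["cadence"]] - nor[["cadence"]])
  if (label == "NOR") { S <- nor[["stride"]]; f <- nor[["cadence"]] }

  speed <- S * f
  centre <- config$walk_distance / 2
  t0 <- (centre - config$visible_length / 2) / speed
  t1 <- (centre + config$visible_length / 2) / speed
  tt <- seq(t0, t1, by = 1 / config$raw_fps)
  body <- .walker_core(tt, an, S, f, 0.62, params, config$affected_side)

  # world frame: X along the path (0 -> walk_distance), Y up, Z such that the
  # walker's left hand points to +Z when walking towards +X.
  dir_sign <- if (direction == "right") 1 else -1
  X <- if (direction == "right") body[, , 1] else config$walk_distance - body[, , 1]
  Y <- body[, , 2]
  Zw <- dir_sign * body[, , 3]

  fpx <- config$focal_px
  D <- config$camera_distance
  hipmid <- function(M) (M[, "left_hip"] + M[, "right_hip"]) / 2
  if (view == "sagittal") {
    sc <- fpx / D
    u <- sc * X
    v <- sc * Y
    depth <- Zw                      # distance offset from the camera plane
    z <- (depth - hipmid(depth)) * sc
  } else {
    setback <- 2
    dist <- X + setback              # camera on the path axis, 2 m before 0
    u <- fpx * (-Zw) / dist
    v <- fpx * Y / dist
    z <- (dist - hipmid(dist)) * (fpx / D)
  }

  video_id <- sprintf("S%02d_%s_%s_%s", subject, label,
                      substr(view, 1, 3), direction)
  n <- length(tt)
  # noise stream independent of the class label: identical trajectories
  # (e.g. every class at magnitude 0) render to identical sequences
  .with_seed(.hash_seed(config$seed, 15485863, subject,
                        match(view, c("frontal", "sagittal")),
                        match(direction, c("right", "left"))), {
    u <- u + matrix(stats::rnorm(n * 33, 0, config$keypoint_jitter_sd), n, 33)
    v <- v + matrix(stats::rnorm(n * 33, 0, config$keypoint_jitter_sd), n, 33)
    z <- z + matrix(stats::rnorm(n * 33, 0, config$depth_noise_sd), n, 33)
    occ <- matrix(stats::runif(n * 33) < config$occlusion_prob, n, 33)
  })
  u[occ] <- NA_real_; v[occ] <- NA_real_; z[occ] <- NA_real_

  tibble::tibble(
    video_id = video_id,
    frame_index = rep(seq_len(n), each = 33),
    time_s = rep(tt - t0, each = 33),
    landmark_name = rep(pose_landmarks, n),
    x = as.vector(t(u)),
    y = as.vector(t(v)),
    z = as.vector(t(z)),
    visible = as.integer(!as.vector(t(occ)))
  )
}

#' Simulate a full multi-view gait dataset
#'
#' One video per subject x gait class x camera view x walking direction
#' (a balanced design of `n_subjects * 7 * 2 * 2` sequences). Identical
#' configurations (including the seed) give identical output.
#'
#' @param config A [gait_config()].
#' @return A list of class `gait_dataset` with elements `manifest` (tibble:
#'   `video_id`, `subject_id`, `view`, `direction`, `label`, `fps`,
#'   `n_frames`) and `poses` (long tibble in the [render_sequence()] format).
#' @export
simulate_gait_dataset <- function(config) {
  stopifnot(inherits(config, "gait_config"))
  if (config$n_subjects < 2) stop("n_subjects must be >= 2")
  grid <- expand.grid(
    direction = c("right", "left"), view = c("frontal", "sagittal"),
    label = gait_classes, subject = seq_len(config$n_subjects),
    stringsAsFactors = FALSE
  )
  poses <- vector("list", nrow(grid))
  man <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- render_sequence(g$subject, g$label, g$view, g$direction, config)
    poses[[i]] <- p
    man[[i]] <- tibble::tibble(
      video_id = p$video_id[1],
      subject_id = sprintf("S%02d", g$subject),
      view = g$view, direction = g$direction, label = g$label,
      fps = config$raw_fps, n_frames = max(p$frame_index)
    )
  }
  structure(list(
    manifest = dplyr::bind_rows(man),
    poses = dplyr::bind_rows(poses)
  ), class = "gait_dataset")
}

#' Write / read a gait dataset as delimited text
#'
#' `write_gait_dataset()` stores `manifest.csv` plus one `poses/<video_id>.csv`
#' per video; `read_gait_dataset()` restores the in-memory form.
#'
#' @param dataset A `gait_dataset`.
#' @param dir Output directory.
#' @param overwrite Overwrite an existing directory? Refused by default.
#' @return `dir`, invisibly (`write`); a `gait_dataset` (`read`).
#' @export
write_gait_dataset <- function(dataset, dir, overwrite = FALSE) {
  stopifnot(inherits(dataset, "gait_dataset"))
  if (dir.exists(dir)) {
    if (!overwrite) stop("output path exists; set overwrite = TRUE: ", dir)
    unlink(dir, recursive = TRUE)
  }
  dir.create(file.path(dir, "poses"), recursive = TRUE)
  readr::write_csv(dataset$manifest, file.path(dir, "manifest.csv"))
  for (vid in unique(dataset$poses$video_id)) {
    readr::write_csv(dataset$poses[dataset$poses$video_id == vid, ],
                     file.path(dir, "poses", paste0(vid, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_gait_dataset
#' @export
read_gait_dataset <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  files <- list.files(file.path(dir, "poses"), full.names = TRUE)
  poses <- dplyr::bind_rows(
    lapply(files, readr::read_csv, show_col_types = FALSE))
  structure(list(manifest = tibble::as_tibble(manifest),
                 poses = tibble::as_tibble(poses)),
            class = "gait_dataset")
}

#' Count gait cycles in a pose sequence
#'
#' Counts peaks of the vertical heel trajectory of the (by default) affected
#' side after rolling-median detrending. Used to calibrate the simulator
#' against clinically typical per-class cycle counts; not part of the
#' classification pipeline.
#'
#' @param poses Long pose tibble of one video ([render_sequence()] format).
#' @param fps Frames per second; inferred from `time_s` when `NULL`.
#' @param landmark_name Landmark whose channel is peak-counted.
#' @param channel `"x"`, `"y"` or `"z"`.
#' @return Number of detected cycles (integer-valued numeric).
#' @export
count_gait_cycles <- function(poses, fps = NULL, landmark_name = "right_heel",
                              channel = "y") {
  stopifnot(length(unique(poses$video_id)) <= 1)
  y <- poses[poses$landmark_name == landmark_name, , drop = FALSE]
  y <- y[order(y$frame_index), ]
  if (is.null(fps)) {
    dt <- stats::median(diff(unique(y$time_s)))
    fps <- 1 / dt
  }
  v <- y[[channel]]
  if (length(v) < 2 * fps) stop("sequence must cover at least 2 s")
  ok <- !is.na(v)
  v <- stats::approx(which(ok), v[ok], xout = seq_along(v), rule = 2)$y
  if (max(v) - min(v) < 1e-9) stop("no cycles detectable: constant channel")
  ks <- max(3, 2 * floor(0.075 * fps) + 1)       # ~0.15 s smoothing
  v <- as.numeric(stats::filter(v, rep(1 / ks, ks), sides = 2))
  v <- v[!is.na(v)]
  k <- 2 * floor(0.75 * fps / 2) + 1
  detr <- as.numeric(v - stats::runmed(v, k))
  pk <- pracma::findpeaks(detr,
                          minpeakdistance = max(2, round(0.45 * fps)),
                          minpeakheight = 0.4 * stats::sd(detr))
  if (is.null(pk)) stop("no cycles detectable")
  nrow(pk)
}
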