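# Synthetic landmark-stream simulator.
#
# A parametric 68-point rigid 3D face model (camera-aligned axes: x right,
# y down, z away from the camera, origin at the nose base, millimetres) is
# deformed per frame for blinks (eyelid collapse) and yawns (inner-lip
# separation), rotated rigidly for head events, and projected through the
# package's own camera model. Every generated quantity therefore has an
# exact ground truth. Blink and yawn deformations are confined to landmarks
# outside the 14-point pose set, so scripted head rotations remain the exact
# pose ground truth even mid-yawn.

#' Face shape parameters for the simulator
#'
#' @param scale overall size multiplier of the head model.
#' @param eye_openness multiplier on the neutral eyelid opening (1 gives a
#'   neutral EAR near 0.3).
#' @param lip_thickness multiplier on the outer-lip thickness. Inner-lip
#'   geometry is unaffected, mirroring the real-world motivation for
#'   computing the MAR from inner-lip points: the closed-mouth inner ratio
#'   stays near zero for thin and thick lips alike while outer-lip ratios
#'   differ.
#' @return A list of class `face_shape`.
#' @export
face_shape <- function(scale = 1, eye_openness = 1, lip_thickness = 1) {
  stopifnot(scale > 0, eye_openness > 0.2, eye_openness <= 2,
            lip_thickness > 0, lip_thickness <= 3)
  structure(list(scale = scale, eye_openness = eye_openness,
                 lip_thickness = lip_thickness), class = "face_shape")
}

# full 68-point 3D model consistent with face_model_3d() on the pose subset
face_model68 <- function(shape = face_shape()) {
  m <- matrix(NA_real_, 68, 3)
  # jaw 0-16: arc from left temple through chin to right temple
  t <- (0:16) / 16
  m[lm_rows(0:16), ] <- cbind(-78 * cos(pi * t),
                              -30 + 102 * sin(pi * t),
                              40 - 26 * sin(pi * t))
  # brows 17-26
  m[lm_rows(17:21), ] <- rbind(c(-52, -48, 12), c(-44, -53, 8), c(-35, -55, 5),
                               c(-26, -54, 3), c(-18, -52, 2))
  m[lm_rows(22:26), ] <- rbind(c(18, -52, 2), c(26, -54, 3), c(35, -55, 5),
                               c(44, -53, 8), c(52, -48, 12))
  # nose bridge 27-30 and base 31-35
  m[lm_rows(27:30), ] <- rbind(c(0, -32, 4), c(0, -22, 0), c(0, -12, -5),
                               c(0, -3, -10))
  m[lm_rows(31:35), ] <- rbind(c(-15, 12, 2), c(-8, 14, -1), c(0, 15, -3),
                               c(8, 14, -1), c(15, 12, 2))
  # eyes 36-47: corners fixed, lids offset vertically from the lid line
  lid <- 4 * shape$eye_openness
  m[lm_rows(36:41), ] <- rbind(
    c(-45, -32, 15), c(-38, -31 - lid, 11), c(-27, -31 - lid, 10),
    c(-19, -30, 10), c(-27, -31 + lid, 10), c(-38, -31 + lid, 11))
  m[lm_rows(42:47), ] <- rbind(
    c(19, -30, 10), c(27, -31 - lid, 10), c(38, -31 - lid, 11),
    c(45, -32, 15), c(38, -31 + lid, 11), c(27, -31 + lid, 10))
  # outer lips 48-59; upper/lower offsets from the lip seam scale with lip
  # thickness. The corners (48, 54) and the lower-lip centre (57) belong to
  # the rigid pose set and stay fixed across thickness variants.
  up <- 35 - c(4, 6, 7, 6, 4) * shape$lip_thickness
  lo <- 35 + c(6, 9) * shape$lip_thickness
  m[lm_rows(48), ] <- c(-26, 35, 10)
  m[lm_rows(49:53), ] <- cbind(c(-17, -8, 0, 8, 17), up, c(6, 4, 3, 4, 6))
  m[lm_rows(54), ] <- c(26, 35, 10)
  m[lm_rows(55:56), ] <- cbind(c(17, 8), lo, c(6, 5))
  m[lm_rows(57), ] <- c(0, 46, 7)
  m[lm_rows(58:59), ] <- cbind(c(-8, -17), rev(lo), c(5, 6))
  # inner lips 60-67: closed seam, 1 mm apart
  m[lm_rows(60:67), ] <- rbind(
    c(-20, 35, 8), c(-8, 34.5, 6), c(0, 34.5, 6), c(8, 34.5, 6),
    c(20, 35, 8), c(8, 35.5, 6), c(0, 35.5, 6), c(-8, 35.5, 6))
  m * shape$scale
}

#' Neutral face template
#'
#' Builds the closed-mouth, open-eye 68-point template: the parametric 3D
#' face model projected at the neutral pose (identity rotation, face
#' centred in front of the camera). By construction the template's pose
#' landmarks equal the projection of the 14-point rigid model, its EAR lies
#' in the open-eye band, and its inner-lip MAR is below 0.05 for every
#' shape variant.
#'
#' @param shape a [face_shape()].
#' @param intrinsics a [camera_intrinsics()].
#' @param distance_mm camera-to-face distance along the optical axis.
#' @return A list with `points2d` (68 x 2 pixel template), `model68`
#'   (68 x 3), `model14` (the pose subset, row order of [face_model_3d()]),
#'   `rotation`, `translation`, and `intrinsics`.
#' @export
neutral_template <- function(shape = face_shape(),
                             intrinsics = default_intrinsics(),
                             distance_mm = 450) {
  model68 <- face_model68(shape)
  map <- landmark_index_map()
  translation <- c(0, 0, distance_mm)
  pts <- project_points(model68, diag(3), translation, intrinsics)
  list(points2d = pts,
       model68 = model68,
       model14 = model68[lm_rows(map$pose_points), , drop = FALSE],
       rotation = diag(3), translation = translation,
       intrinsics = intrinsics)
}

#' Construct a scenario event
#'
#' @param type one of `"blink"`, `"yawn"`, `"head_turn"` (yaw),
#'   `"head_nod"` (pitch), `"head_sway"` (roll), `"no_face"`.
#' @param start event start time in seconds.
#' @param duration event duration in seconds (converted to frames at the
#'   script's fps); alternatively give `frames` directly.
#' @param frames event duration in frames (exact; takes precedence over
#'   `duration`). For yawns this is exactly the number of frames the MAR
#'   stays above threshold.
#' @param magnitude blink closure depth in (0, 1]; yawn opening in model mm
#'   (default 18, MAR around 0.6); head events: peak angle in degrees
#'   (signed), |magnitude| <= 60.
#' @return A list of class `scenario_event`.
#' @export
scenario_event <- function(type, start, duration = NULL, frames = NULL,
                           magnitude = NULL) {
  type <- match.arg(type, c("blink", "yawn", "head_turn", "head_nod",
                            "head_sway", "no_face"))
  if (is.null(frames) && is.null(duration))
    stop("scenario_event needs either duration (s) or frames")
  if (is.null(magnitude)) {
    magnitude <- switch(type, blink = 1, yawn = 18, no_face = 0, 25)
  }
  if (type == "blink" && (magnitude <= 0 || magnitude > 1))
    stop("blink closure depth must be in (0, 1]")
  if (type == "yawn" && (magnitude <= 0 || magnitude > 40))
    stop("yawn opening must be in (0, 40] model mm")
  if (startsWith(type, "head") && abs(magnitude) > 60)
    stop("head event magnitude must satisfy |magnitude| <= 60 degrees")
  structure(list(type = type, start = start, duration = duration,
                 frames = frames, magnitude = magnitude),
            class = "scenario_event")
}

#' Construct a scenario script
#'
#' A deterministic recipe for a synthetic landmark stream: capture rate,
#' total duration, an ordered list of events, the landmark noise level, and
#' the random seed. Events that act on the same facial subsystem (two
#' blinks, two yawns, two head events, or anything overlapping a face-loss
#' interval) must not overlap in time.
#'
#' @param fps frames per second; default 25.
#' @param duration total stream duration in seconds.
#' @param events list of [scenario_event()]s.
#' @param noise_sd isotropic Gaussian pixel noise added to every landmark;
#'   default 0.
#' @param seed integer RNG seed for the noise.
#' @return A list of class `scenario_script` with events resolved to frame
#'   ranges (`start_frame`, `n_frames`).
#' @export
scenario_script <- function(fps = 25, duration, events = list(),
                            noise_sd = 0, seed = 1L) {
  stopifnot(fps > 0, duration > 0, noise_sd >= 0)
  total <- as.integer(round(fps * duration))
  events <- lapply(events, function(e) {
    stopifnot(inherits(e, "scenario_event"))
    e$start_frame <- as.integer(round(e$start * fps))
    e$n_frames <- if (!is.null(e$frames)) as.integer(e$frames)
                  else as.integer(round(e$duration * fps))
    if (e$n_frames < 1L) stop("event duration must cover at least one frame")
    if (e$start_frame < 0L || e$start_frame + e$n_frames > total)
      stop("event [", e$start_frame, ", ", e$start_frame + e$n_frames,
           ") falls outside the stream of ", total, " frames")
    e
  })
  ord <- order(vapply(events, function(e) e$start_frame, integer(1)))
  events <- events[ord]
  validate_script_events(events)
  structure(list(fps = fps, duration = duration, total_frames = total,
                 events = events, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scenario_script")
}

validate_script_events <- function(events) {
  spans <- lapply(events, function(e)
    c(e$start_frame, e$start_frame + e$n_frames - 1L))
  types <- vapply(events, function(e) e$type, character(1))
  grp <- function(ty) if (startsWith(ty, "head")) "head" else ty
  for (i in seq_along(events)) for (j in seq_len(i - 1L)) {
    overlap <- spans[[i]][1] <= spans[[j]][2] && spans[[j]][1] <= spans[[i]][2]
    if (!overlap) next
    incompatible <- grp(types[i]) == grp(types[j]) ||
      types[i] == "no_face" || types[j] == "no_face"
    if (incompatible)
      stop("incompatible overlapping events: ", types[j], " and ", types[i],
           " share frames")
  }
  invisible(events)
}

# per-frame profiles -------------------------------------------------------

# blink closure: 2-frame linear ramps around a full-depth plateau
blink_closure <- function(k, n, magnitude) {
  ramp <- min(2L, (n - 1L) %/% 2L)
  magnitude * pmin(pmin(k + 1L, n - k) / (ramp + 1L), 1)
}

# head angle: cosine ramp up to the target, hold, cosine ramp back
head_angle <- function(k, n, magnitude) {
  r <- min(8L, n %/% 4L)
  if (k < r) {
    magnitude * (1 - cos(pi * (k + 1) / (r + 1))) / 2
  } else if (k >= n - r) {
    magnitude * (1 - cos(pi * (n - k) / (r + 1))) / 2
  } else {
    magnitude
  }
}

frame_event_state <- function(script, k) {
  st <- list(closure = 0, opening = 0, pitch = 0, yaw = 0, roll = 0,
             face = TRUE)
  for (e in script$events) {
    rel <- k - e$start_frame
    if (rel < 0L || rel >= e$n_frames) next
    switch(e$type,
      blink = { st$closure <- blink_closure(rel, e$n_frames, e$magnitude) },
      yawn = { st$opening <- e$magnitude },
      head_nod = { st$pitch <- head_angle(rel, e$n_frames, e$magnitude) },
      head_turn = { st$yaw <- head_angle(rel, e$n_frames, e$magnitude) },
      head_sway = { st$roll <- head_angle(rel, e$n_frames, e$magnitude) },
      no_face = { st$face <- FALSE }
    )
  }
  st
}

# apply non-rigid blink/yawn deformation to the 68-point model; only
# landmarks outside the 14-point pose set move
deform_model <- function(model68, closure, opening) {
  m <- model68
  if (closure > 0) {
    for (pair in list(c(37L, 41L), c(38L, 40L), c(43L, 47L), c(44L, 46L))) {
      r <- lm_rows(pair)
      mid <- mean(m[r, 2])
      m[r, 2] <- mid + (m[r, 2] - mid) * (1 - closure)
    }
  }
  if (opening > 0) {
    m[lm_rows(c(61L, 62L, 63L)), 2] <- m[lm_rows(c(61L, 62L, 63L)), 2] -
      0.25 * opening
    m[lm_rows(c(65L, 66L, 67L)), 2] <- m[lm_rows(c(65L, 66L, 67L)), 2] +
      opening
    m[lm_rows(c(49L, 50L, 51L, 52L, 53L)), 2] <-
      m[lm_rows(c(49L, 50L, 51L, 52L, 53L)), 2] - 0.15 * opening
    m[lm_rows(c(55L, 56L, 58L, 59L)), 2] <-
      m[lm_rows(c(55L, 56L, 58L, 59L)), 2] + 0.6 * opening
  }
  m
}

#' Render a scenario script into a landmark stream with ground truth
#'
#' Walks the script frame by frame: applies blink and yawn deformations to
#' the 3D face model, rotates it by the scripted head Euler angles, projects
#' all 68 points through the camera model, records the noise-free feature
#' ground truth, and finally adds seeded Gaussian pixel noise to the emitted
#' landmarks. Identical script and seed give a bit-identical stream.
#'
#' @param script a [scenario_script()].
#' @param shape a [face_shape()].
#' @param config an [assess_config()]; supplies the camera intrinsics, the
#'   feature thresholds used to derive ground-truth states, and the window
#'   length for the per-window ground truth.
#' @param distance_mm camera-to-face distance in millimetres.
#' @return A list with `stream` (a `landmark_stream`) and `truth`, itself a
#'   list of `frames` (per-frame true `ear`, `mar`, `pitch`, `yaw`, `roll`,
#'   `E`, `M`) and `windows` (per-window true `blink_count`, `yawn_count`,
#'   `deep_yawn_count`, `closing_rate`, per-channel out-of-range frame
#'   totals, and `expected_alert`).
#' @export
render_stream <- function(script, shape = face_shape(),
                          config = assess_config(fps = script$fps),
                          distance_mm = 450) {
  stopifnot(inherits(script, "scenario_script"))
  base <- face_model68(shape)
  translation <- c(0, 0, distance_mm)
  intr <- config$intrinsics
  map <- landmark_index_map(nose_lower_right = config$nose_lower_right)
  n <- script$total_frames

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(script$seed)

  frames <- vector("list", n)
  truth <- data.frame(
    frame = 0:(n - 1L), t = (0:(n - 1L)) / script$fps, face = TRUE,
    ear = NA_real_, mar = NA_real_,
    pitch = NA_real_, yaw = NA_real_, roll = NA_real_,
    E = NA_integer_, M = NA_integer_
  )
  for (k in 0:(n - 1L)) {
    st <- frame_event_state(script, k)
    ts <- k / script$fps
    if (!st$face) {
      truth$face[k + 1L] <- FALSE
      frames[[k + 1L]] <- landmark_frame(k, ts, FALSE)
      next
    }
    m <- deform_model(base, st$closure, st$opening)
    R <- euler_to_rotation(st$pitch, st$yaw, st$roll)
    clean <- project_points(m, R, translation, intr)
    fr_clean <- landmark_frame(k, ts, TRUE, clean)
    ear <- frame_ear(fr_clean, config$ear_weight_left, map)
    mar <- frame_mar(fr_clean, map)
    truth$ear[k + 1L] <- ear
    truth$mar[k + 1L] <- mar
    truth$pitch[k + 1L] <- st$pitch
    truth$yaw[k + 1L] <- st$yaw
    truth$roll[k + 1L] <- st$roll
    truth$E[k + 1L] <- classify_eye(ear, config$ear_threshold)
    truth$M[k + 1L] <- classify_mouth(mar, config$mar_threshold)
    pts <- clean
    if (script$noise_sd > 0)
      pts <- pts + matrix(stats::rnorm(136, sd = script$noise_sd), 68, 2)
    frames[[k + 1L]] <- landmark_frame(k, ts, TRUE, pts)
  }
  windows <- truth_windows(script, truth, config)
  list(stream = structure(frames, class = "landmark_stream"),
       truth = list(frames = truth, windows = windows))
}

# per-window ground truth derived from the script and the true per-frame
# feature values; the alert expectation applies the fused rule directly
truth_windows <- function(script, truth, config) {
  w <- config$window_frames
  win_id <- truth$frame %/% w
  ev_window <- function(e) (e$start_frame + e$n_frames - 1L) %/% w
  out <- lapply(sort(unique(win_id)), function(kw) {
    rows <- truth[win_id == kw, , drop = FALSE]
    facef <- rows[rows$face, , drop = FALSE]
    blink_events <- Filter(function(e) e$type == "blink" &&
                             ev_window(e) == kw, script$events)
    yawn_events <- Filter(function(e) e$type == "yawn" &&
                            ev_window(e) == kw, script$events)
    ylen <- vapply(yawn_events, function(e) e$n_frames, integer(1))
    ycls <- classify_yawn(ylen, config$yawn_frames, config$deep_yawn_frames)
    rate <- if (nrow(facef)) mean(facef$E == 0L) else NA_real_
    hf <- c(pitch = sum(abs(facef$pitch) > config$euler_threshold_deg),
            yaw = sum(abs(facef$yaw) > config$euler_threshold_deg),
            roll = sum(abs(facef$roll) > config$euler_threshold_deg))
    alert <- nrow(facef) > 0 && (
      rate > config$closing_rate_threshold ||
        sum(ycls == 1L) >= config$yawn_alert_count ||
        sum(ycls == 2L) >= config$deep_yawn_alert_count ||
        any(hf > config$window_head_frames))
    data.frame(window = kw, face_frames = nrow(facef),
               blink_count = length(blink_events),
               yawn_count = sum(ycls == 1L), deep_yawn_count = sum(ycls == 2L),
               closing_rate = rate,
               pitch_frames = hf[["pitch"]], yaw_frames = hf[["yaw"]],
               roll_frames = hf[["roll"]],
               expected_alert = alert)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Draw a random scenario script
#'
#' Samples a plausible monitoring scenario for testing: a handful of blinks
#' (closure depth 0.7-1, 4-10 frames), at most one mouth-opening episode per
#' window (10-70 frames, so spanning ordinary opening, yawn and deep yawn),
#' and at most one head excursion per window on a random channel (peak 18-40
#' degrees out of range or 5-12 degrees within range, 20 frames up to nearly
#' the window length). Blink and yawn events are placed fully inside one
#' window with open/closed padding on both sides so that the scripted counts
#' are unambiguous ground truth.
#'
#' @param seed integer seed controlling every sampled quantity.
#' @param fps frames per second.
#' @param n_windows number of detection windows to cover.
#' @param window_seconds window length in seconds.
#' @param noise_sd landmark noise passed through to the script.
#' @return A [scenario_script()].
#' @export
random_scenario <- function(seed, fps = 25, n_windows = 1L,
                            window_seconds = 12, noise_sd = 0) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  wf <- as.integer(round(fps * window_seconds))
  events <- list()
  for (kw in seq_len(n_windows) - 1L) {
    base <- kw * wf
    used <- matrix(integer(0), ncol = 2)  # occupied [start, end] frame spans
    reserve <- function(len, pad) {
      for (try in 1:50) {
        s <- base + sample.int(wf - len - 2L * pad, 1L) + pad - 1L
        span <- c(s - pad, s + len - 1L + pad)
        if (nrow(used) == 0 ||
            all(span[2] < used[, 1] | span[1] > used[, 2])) {
          used <<- rbind(used, span)
          return(s)
        }
      }
      NA_integer_
    }
    if (stats::runif(1) < 0.7) {
      len <- sample(20:max(21L, wf - 10L), 1L)
      s <- reserve(len, pad = 1L)
      if (!is.na(s)) {
        mag <- if (stats::runif(1) < 0.7) stats::runif(1, 18, 35)
               else stats::runif(1, 5, 12)
        events[[length(events) + 1L]] <- scenario_event(
          sample(c("head_turn", "head_nod", "head_sway"), 1L),
          start = s / fps, frames = len,
          magnitude = mag * sample(c(-1, 1), 1L))
      }
    }
    if (stats::runif(1) < 0.7) {
      len <- sample(10:min(70L, wf - 10L), 1L)
      s <- reserve(len, pad = 3L)
      if (!is.na(s))
        events[[length(events) + 1L]] <- scenario_event(
          "yawn", start = s / fps, frames = len,
          magnitude = stats::runif(1, 16, 24))
    }
    n_blinks <- sample(0:4, 1L)
    for (b in seq_len(n_blinks)) {
      # occasionally a long microsleep-style closure that drives the
      # eye-closing rate over its threshold
      len <- if (stats::runif(1) < 0.15) sample(60:100, 1L)
             else sample(4:10, 1L)
      s <- reserve(len, pad = 3L)
      if (is.na(s)) next
      events[[length(events) + 1L]] <- scenario_event(
        "blink", start = s / fps, frames = len,
        magnitude = stats::runif(1, 0.7, 1))
    }
    if (stats::runif(1) < 0.2) {
      len <- sample(5:25, 1L)
      s <- reserve(len, pad = 3L)
      if (!is.na(s))
        events[[length(events) + 1L]] <- scenario_event(
          "no_face", start = s / fps, frames = len)
    }
  }
  scenario_script(fps = fps, duration = n_windows * window_seconds,
                  events = events, noise_sd = noise_sd, seed = seed)
}

#' Read a scenario script from a YAML file
#'
#' The file carries scalar keys `fps`, `duration`, `noise_sd`, `seed` and an
#' `events` list whose entries hold `type`, `start` and either `duration`
#' (seconds) or `frames`, plus an optional `magnitude`. See
#' `system.file("extdata", "example_scenario.yaml", package = "facevigil")`.
#'
#' @param path path to a YAML scenario file.
#' @return A [scenario_script()].
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  events <- lapply(raw$events, function(e) do.call(scenario_event, e))
  scenario_script(fps = if (is.null(raw$fps)) 25 else raw$fps,
                  duration = raw$duration, events = events,
                  noise_sd = if (is.null(raw$noise_sd)) 0 else raw$noise_sd,
                  seed = if (is.null(raw$seed)) 1L else raw$seed)
}
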