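#' Compute per-frame features for a landmark stream
#'
#' For every frame with a face present, computes the per-frame EAR and eye
#' state `E`, inner-lip MAR and mouth state `M`, the head pose Euler angles
#' via [solve_pose()], the per-channel out-of-range flags, the running
#' consecutive out-of-range counters, the head-normality code `H`, and the
#' head event code `P`. Counters reset whenever the face is lost, since an
#' unobserved head cannot extend a consecutive run.
#'
#' @param stream a list of [landmark_frame()] objects.
#' @param config an [assess_config()].
#' @return A data frame with one row per frame: `frame`, `t`, `face`, `ear`,
#'   `E`, `mar`, `M`, `pitch`, `yaw`, `roll`, `pitch_out`, `yaw_out`,
#'   `roll_out`, `pcounter`, `ycounter`, `rcounter`, `H`, `head_event`.
#'   Feature columns are `NA` on faceless frames.
#' @export
frame_features <- function(stream, config = assess_config()) {
  validate_stream(stream)
  map <- landmark_index_map(nose_lower_right = config$nose_lower_right)
  n <- length(stream)
  out <- data.frame(
    frame = integer(n), t = numeric(n), face = logical(n),
    ear = NA_real_, E = NA_integer_, mar = NA_real_, M = NA_integer_,
    pitch = NA_real_, yaw = NA_real_, roll = NA_real_,
    pitch_out = NA, yaw_out = NA, roll_out = NA,
    pcounter = 0L, ycounter = 0L, rcounter = 0L,
    H = NA_integer_, head_event = 0L
  )
  hs <- head_state()
  for (i in seq_len(n)) {
    f <- stream[[i]]
    out$frame[i] <- f$frame_index
    out$t[i] <- f$timestamp
    out$face[i] <- f$face_present
    if (!f$face_present) {
      hs <- head_state()
      next
    }
    ear <- frame_ear(f, config$ear_weight_left, map)
    mar <- frame_mar(f, map)
    pose <- solve_pose(config$face_model, pose_points(f, map),
                       config$intrinsics)
    eul <- pose$euler
    hs <- update_head_counters(hs, eul, config$euler_threshold_deg)
    ev <- classify_head_event(hs, config$head_frame_threshold)
    out$ear[i] <- ear
    out$E[i] <- classify_eye(ear, config$ear_threshold)
    out$mar[i] <- mar
    out$M[i] <- classify_mouth(mar, config$mar_threshold)
    out$pitch[i] <- eul["pitch"]; out$yaw[i] <- eul["yaw"]
    out$roll[i] <- eul["roll"]
    out$pitch_out[i] <- abs(eul["pitch"]) > config$euler_threshold_deg
    out$yaw_out[i] <- abs(eul["yaw"]) > config$euler_threshold_deg
    out$roll_out[i] <- abs(eul["roll"]) > config$euler_threshold_deg
    out$pcounter[i] <- hs$pcounter
    out$ycounter[i] <- hs$ycounter
    out$rcounter[i] <- hs$rcounter
    out$H[i] <- classify_head(eul, config$euler_threshold_deg)
    out$head_event[i] <- ev$code
  }
  out
}

# the single fused alert rule shared by assess_window and evaluate_record
apply_alert_rule <- function(has_face, rate, yawn_count, deep_yawn_count,
                             head_frames, config) {
  if (!has_face) {
    return(list(alert = FALSE, reasons = "NO_FACE"))
  }
  reasons <- character(0)
  if (isTRUE(rate > config$closing_rate_threshold))
    reasons <- c(reasons, "CLOSING_RATE")
  if (yawn_count >= config$yawn_alert_count)
    reasons <- c(reasons, "YAWN")
  if (deep_yawn_count >= config$deep_yawn_alert_count)
    reasons <- c(reasons, "DEEP_YAWN")
  nm <- c("HEAD_PITCH", "HEAD_YAW", "HEAD_ROLL")
  over <- head_frames > config$window_head_frames
  reasons <- c(reasons, nm[over])
  list(alert = length(reasons) > 0, reasons = reasons)
}

rep_excursion <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  x[which.max(abs(x))]
}

#' Assess one detection window of per-frame features
#'
#' Aggregates a window of [frame_features()] rows and applies the fused
#' alert rule: an alert is raised when the eye-closing rate exceeds its
#' threshold, or the window contains at least two yawns or one deep yawn, or
#' any Euler channel is out of range for more than the windowed frame budget
#' (120 frames by default, not necessarily consecutive). A window with no
#' face at all yields no alert and the single reason `NO_FACE`.
#'
#' @param features a data frame of [frame_features()] rows covering one
#'   window.
#' @param config an [assess_config()].
#' @param episodes optional precomputed mouth-episode data frame attributed
#'   to this window (as produced by [run_pipeline()] for episodes that may
#'   span window boundaries); when `NULL`, episodes are segmented within the
#'   window.
#' @param window_index integer label for the window; default 0.
#' @return A one-row data frame: `window`, `n_frames`, `face_coverage`,
#'   `eye_closing_rate`, `blink_count`, `yawn_count`, `deep_yawn_count`,
#'   `yaw`, `yaw_frames`, `pitch`, `pitch_frames`, `roll`, `roll_frames`
#'   (representative per-channel value at maximum excursion and total
#'   out-of-range frames), `alert`, `reasons` (semicolon-joined).
#' @export
assess_window <- function(features, config = assess_config(),
                          episodes = NULL, window_index = 0L) {
  if (NROW(features) == 0L) stop("empty window: no frames to assess")
  facef <- features[features$face, , drop = FALSE]
  coverage <- nrow(facef) / nrow(features)
  if (is.null(episodes)) {
    m_states <- ifelse(features$face & !is.na(features$M), features$M, 0L)
    episodes <- segment_mouth_episodes(m_states, features$frame,
                                       config$yawn_frames,
                                       config$deep_yawn_frames)
  }
  if (nrow(facef) == 0L) {
    rule <- apply_alert_rule(FALSE, NA, 0L, 0L, c(0L, 0L, 0L), config)
    return(data.frame(
      window = window_index, n_frames = nrow(features), face_coverage = 0,
      eye_closing_rate = NA_real_, blink_count = 0L,
      yawn_count = 0L, deep_yawn_count = 0L,
      yaw = NA_real_, yaw_frames = 0L, pitch = NA_real_, pitch_frames = 0L,
      roll = NA_real_, roll_frames = 0L,
      alert = rule$alert, reasons = paste(rule$reasons, collapse = ";")
    ))
  }
  rate <- closing_rate(facef$E)
  blinks <- count_blinks(facef$E, config$min_closed_frames)
  yawns <- sum(episodes$yawn_class == 1L)
  deep <- sum(episodes$yawn_class == 2L)
  head_frames <- c(pitch = sum(facef$pitch_out), yaw = sum(facef$yaw_out),
                   roll = sum(facef$roll_out))
  rule <- apply_alert_rule(TRUE, rate, yawns, deep, head_frames, config)
  data.frame(
    window = window_index, n_frames = nrow(features),
    face_coverage = coverage,
    eye_closing_rate = rate, blink_count = blinks,
    yawn_count = yawns, deep_yawn_count = deep,
    yaw = rep_excursion(facef$yaw), yaw_frames = head_frames[["yaw"]],
    pitch = rep_excursion(facef$pitch), pitch_frames = head_frames[["pitch"]],
    roll = rep_excursion(facef$roll), roll_frames = head_frames[["roll"]],
    alert = rule$alert, reasons = paste(rule$reasons, collapse = ";")
  )
}

#' Evaluate a tabulated per-window record
#'
#' Applies the fused alert rule directly to window aggregates, as found in a
#' monitoring report row: face flag, eye-closing rate, yawn and deep-yawn
#' counts, and per-channel representative Euler value plus out-of-range frame
#' count. This is the same clause logic as [assess_window()], exposed for
#' auditing recorded sessions.
#'
#' @param record a list or one-row data frame with fields `face` (0/1),
#'   `eye_closing_rate`, `yawn`, `deep_yawn`, `yaw`, `yaw_frames`, `pitch`,
#'   `pitch_frames`, `roll`, `roll_frames`. When `face` is 0 the remaining
#'   fields may be `NA`.
#' @param config an [assess_config()].
#' @return A list with logical `alert` and character vector `reasons`.
#' @export
evaluate_record <- function(record, config = assess_config()) {
  record <- as.list(record)
  if (is.null(record$face)) stop("record is missing required field 'face'")
  has_face <- as.integer(record$face) == 1L
  if (!has_face) return(apply_alert_rule(FALSE, NA, 0L, 0L, rep(0L, 3), config))
  required <- c("eye_closing_rate", "yawn", "deep_yawn",
                "yaw_frames", "pitch_frames", "roll_frames")
  missing <- required[!vapply(required, function(k)
    !is.null(record[[k]]) && !is.na(record[[k]]), logical(1))]
  if (length(missing) > 0)
    stop("record is missing required field(s): ", paste(missing, collapse = ", "))
  head_frames <- c(as.integer(record$pitch_frames),
                   as.integer(record$yaw_frames),
                   as.integer(record$roll_frames))
  apply_alert_rule(TRUE, record$eye_closing_rate,
                   as.integer(record$yawn), as.integer(record$deep_yawn),
                   head_frames, config)
}

#' Run the full assessment pipeline on a landmark stream
#'
#' Computes per-frame features, segments mouth-opening episodes over the
#' whole stream (so an episode spanning a window boundary keeps its global
#' frame counter and is attributed to the window in which it ends), splits
#' the stream into fixed windows of `config$window_frames`, and assesses each
#' window. Deterministic given the stream and configuration.
#'
#' @param stream a list of [landmark_frame()] objects, e.g. from
#'   [read_landmark_stream()] or [render_stream()].
#' @param config an [assess_config()].
#' @return A list with `windows` (one row per window, see [assess_window()]),
#'   `frames` (the per-frame feature log), and `episodes` (the mouth-episode
#'   table with a `window` attribution column).
#' @export
run_pipeline <- function(stream, config = assess_config()) {
  features <- frame_features(stream, config)
  m_states <- ifelse(features$face & !is.na(features$M), features$M, 0L)
  episodes <- segment_mouth_episodes(m_states, features$frame,
                                     config$yawn_frames,
                                     config$deep_yawn_frames)
  w <- config$window_frames
  episodes$window <- if (nrow(episodes)) episodes$end_frame %/% w else integer(0)
  win_id <- features$frame %/% w
  windows <- lapply(sort(unique(win_id)), function(k) {
    assess_window(features[win_id == k, , drop = FALSE], config,
                  episodes = episodes[episodes$window == k, , drop = FALSE],
                  window_index = k)
  })
  windows <- do.call(rbind, windows)
  rownames(windows) <- NULL
  list(windows = windows, frames = features, episodes = episodes)
}

#' Write a per-window assessment report to CSV
#'
#' @param windows the `windows` data frame from [run_pipeline()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(windows, path) {
  utils::write.csv(windows, path, row.names = FALSE)
  invisible(path)
}

#' Bundled example session records
#'
#' A small set of per-minute monitoring records (one row per one-minute
#' window: face flag, eye-closing rate, yawn and deep-yawn counts, and
#' per-channel representative Euler angle with its out-of-range frame count,
#' plus the alert that was issued), bundled for examples and tests of
#' [evaluate_record()].
#'
#' @return A data frame of session records with an `alert` column of
#'   `"Y"`/`"N"` labels.
#' @export
example_session_records <- function() {
  path <- system.file("extdata", "session_records.csv", package = "facevigil",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
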