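#' Assessment configuration
#'
#' Collects every tunable parameter of the pipeline with its default. All
#' frame-count thresholds are stored in frames; at the default 25 fps the
#' 60-second detection window is 1500 frames.
#'
#' @param ear_threshold EAR open/closed threshold (default 0.20).
#' @param ear_weight_left weight of the left eye in the per-frame EAR average
#'   (default 0.5).
#' @param min_closed_frames minimum closed-run length counted as a blink
#'   (default 1).
#' @param mar_threshold MAR open/closed threshold (default 0.35).
#' @param yawn_frames open-mouth frame threshold above which an episode is a
#'   yawn (default 25).
#' @param deep_yawn_frames frame threshold above which an episode is a deep
#'   yawn (default 50).
#' @param euler_threshold_deg half-width of the normal head-angle band in
#'   degrees (default 15).
#' @param head_frame_threshold consecutive out-of-range frames for a head
#'   event (default 60).
#' @param window_head_frames total out-of-range frames per channel within a
#'   window above which the window alerts (default 120).
#' @param closing_rate_threshold eye-closing rate above which a window alerts
#'   (default 0.20, strict inequality).
#' @param yawn_alert_count number of yawns within a window that triggers an
#'   alert (default 2).
#' @param deep_yawn_alert_count number of deep yawns within a window that
#'   triggers an alert (default 1).
#' @param fps capture rate in frames per second (default 25).
#' @param window_seconds detection window length in seconds (default 60).
#' @param intrinsics a [camera_intrinsics()]; default the uncalibrated
#'   640 x 480 webcam approximation from [default_intrinsics()].
#' @param face_model a 14 x 3 model matrix for pose estimation; default
#'   [face_model_3d()].
#' @param nose_lower_right landmark id used as the right nose-base pose
#'   point; default 35.
#' @return A list of class `assess_config`.
#' @export
assess_config <- function(ear_threshold = 0.20,
                          ear_weight_left = 0.5,
                          min_closed_frames = 1L,
                          mar_threshold = 0.35,
                          yawn_frames = 25L,
                          deep_yawn_frames = 50L,
                          euler_threshold_deg = 15,
                          head_frame_threshold = 60L,
                          window_head_frames = 120L,
                          closing_rate_threshold = 0.20,
                          yawn_alert_count = 2L,
                          deep_yawn_alert_count = 1L,
                          fps = 25,
                          window_seconds = 60,
                          intrinsics = default_intrinsics(),
                          face_model = face_model_3d(),
                          nose_lower_right = 35L) {
  cfg <- list(
    ear_threshold = ear_threshold,
    ear_weight_left = ear_weight_left,
    min_closed_frames = as.integer(min_closed_frames),
    mar_threshold = mar_threshold,
    yawn_frames = as.integer(yawn_frames),
    deep_yawn_frames = as.integer(deep_yawn_frames),
    euler_threshold_deg = euler_threshold_deg,
    head_frame_threshold = as.integer(head_frame_threshold),
    window_head_frames = as.integer(window_head_frames),
    closing_rate_threshold = closing_rate_threshold,
    yawn_alert_count = as.integer(yawn_alert_count),
    deep_yawn_alert_count = as.integer(deep_yawn_alert_count),
    fps = fps,
    window_seconds = window_seconds,
    intrinsics = intrinsics,
    face_model = face_model,
    nose_lower_right = as.integer(nose_lower_right)
  )
  stopifnot(cfg$fps > 0, cfg$window_seconds > 0,
            cfg$yawn_frames < cfg$deep_yawn_frames,
            inherits(cfg$intrinsics, "camera_intrinsics"))
  cfg$window_frames <- as.integer(round(cfg$fps * cfg$window_seconds))
  class(cfg) <- "assess_config"
  cfg
}

#' Read an assessment configuration from a YAML file
#'
#' Scalar keys override [assess_config()] defaults; an `intrinsics` mapping
#' (keys `fx`, `fy`, `cx`, `cy` and optional `k1`..`k3`, `p1`, `p2`) builds a
#' [camera_intrinsics()]. Unknown keys are an error, to catch typos in
#' threshold names.
#'
#' @param path path to a YAML configuration file.
#' @return A list of class `assess_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$intrinsics)) {
    raw$intrinsics <- do.call(camera_intrinsics, raw$intrinsics)
  }
  allowed <- names(formals(assess_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(assess_config, raw)
}
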