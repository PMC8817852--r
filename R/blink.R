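#' Eye aspect ratio (EAR) of six eye landmarks
#'
#' The EAR is the sum of the two vertical eyelid distances divided by twice
#' the horizontal eye-corner distance:
#' \deqn{EAR = \frac{\|P_2-P_6\| + \|P_3-P_5\|}{2\,\|P_1-P_4\|}.}
#' It is close to a constant around 0.3 while the eye is open and collapses
#' toward 0 as the lids close, and is invariant under translation, rotation
#' and uniform scaling of the six points.
#'
#' @param points a 6 x 2 numeric matrix, rows ordered P1..P6 as returned by
#'   [eye_points()].
#' @return The EAR, a non-negative dimensionless scalar.
#' @export
compute_ear <- function(points) {
  points <- as.matrix(points)
  stopifnot(identical(dim(points), c(6L, 2L)), all(is.finite(points)))
  horiz <- sqrt(sum((points[1, ] - points[4, ])^2))
  if (horiz <= 0)
    stop("degenerate eye geometry: zero horizontal extent between P1 and P4")
  v1 <- sqrt(sum((points[2, ] - points[6, ])^2))
  v2 <- sqrt(sum((points[3, ] - points[5, ])^2))
  (v1 + v2) / (2 * horiz)
}

#' Per-frame EAR as the weighted average of the two eyes
#'
#' @param frame a [landmark_frame()] with a face present.
#' @param weight_left weight of the left eye in the average; the right eye
#'   gets `1 - weight_left`. Default 0.5 (unweighted mean).
#' @param map a [landmark_index_map()].
#' @return The combined EAR for the frame.
#' @export
frame_ear <- function(frame, weight_left = 0.5, map = landmark_index_map()) {
  stopifnot(weight_left >= 0, weight_left <= 1)
  el <- compute_ear(eye_points(frame, "left", map))
  er <- compute_ear(eye_points(frame, "right", map))
  weight_left * el + (1 - weight_left) * er
}

#' Classify the eye state from an EAR value
#'
#' The eye is open (`E = 1`) when the ratio is at or above the threshold and
#' closed (`E = 0`) below it; the boundary belongs to the open state.
#'
#' @param alpha EAR value(s), non-negative.
#' @param threshold open/closed decision threshold; default 0.20.
#' @return Integer code(s) `E`: 1 = open, 0 = closed (vectorised over `alpha`).
#' @export
classify_eye <- function(alpha, threshold = 0.20) {
  stopifnot(all(alpha >= 0), threshold >= 0)
  as.integer(alpha >= threshold)
}

#' Count blinks in a sequence of per-frame eye-state codes
#'
#' A blink is a completed open-close-open transition: a maximal run of closed
#' frames (`E = 0`) that is preceded and followed by an open frame and lasts
#' at least `min_closed_frames`. Runs touching the start or end of the
#' sequence are not counted, since the reopening (or the closure) was not
#' observed.
#'
#' @param states integer vector of eye codes drawn from `{0, 1}`.
#' @param min_closed_frames minimum closed-run length for a counted blink;
#'   default 1 (no debouncing).
#' @return The number of blinks.
#' @export
count_blinks <- function(states, min_closed_frames = 1L) {
  states <- as.integer(states)
  stopifnot(all(states %in% c(0L, 1L)), min_closed_frames >= 1L)
  if (length(states) < 3L) return(0L)
  r <- rle(states)
  n <- length(r$values)
  interior_closed <- r$values == 0L &
    seq_len(n) > 1L & seq_len(n) < n &
    r$lengths >= min_closed_frames
  sum(interior_closed)
}

#' Eye-closing rate (PERCLOS) of a window of eye-state codes
#'
#' The fraction of frames in which the eyes are classified closed — the
#' standard PERCLOS drowsiness proxy.
#'
#' @param states integer vector of eye codes drawn from `{0, 1}`; typically
#'   one detection window's worth of face-present frames.
#' @return The closing rate in `[0, 1]`.
#' @export
closing_rate <- function(states) {
  states <- as.integer(states)
  if (length(states) == 0L)
    stop("empty window: closing rate is undefined with no face-present frames")
  stopifnot(all(states %in% c(0L, 1L)))
  sum(states == 0L) / length(states)
}
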