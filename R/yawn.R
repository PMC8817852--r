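#' Inner-lip mouth aspect ratio (MAR)
#'
#' The MAR is computed from inner-lip landmarks only, so that lip thickness
#' does not inflate the closed-mouth baseline across different faces:
#' \deqn{MAR = \frac{\|A_1-A_2\| + \|B_1-B_2\|}{2\,\|H_1-H_2\|},}
#' where A and B are the two vertical inner-lip point pairs and H the inner
#' mouth-corner pair. The ratio is near 0 with the mouth closed, rises when
#' the mouth opens, and is invariant under similarity transforms.
#'
#' @param vertical_a,vertical_b 2 x 2 matrices, one vertical inner-lip point
#'   pair each (as returned by [inner_mouth_points()]).
#' @param horizontal 2 x 2 matrix, the inner mouth-corner pair.
#' @return The MAR, a non-negative dimensionless scalar.
#' @export
compute_mar <- function(vertical_a, vertical_b, horizontal) {
  va <- as.matrix(vertical_a); vb <- as.matrix(vertical_b)
  h <- as.matrix(horizontal)
  stopifnot(identical(dim(va), c(2L, 2L)), identical(dim(vb), c(2L, 2L)),
            identical(dim(h), c(2L, 2L)))
  width <- sqrt(sum((h[1, ] - h[2, ])^2))
  if (width <= 0)
    stop("degenerate mouth geometry: zero width between inner mouth corners")
  da <- sqrt(sum((va[1, ] - va[2, ])^2))
  db <- sqrt(sum((vb[1, ] - vb[2, ])^2))
  (da + db) / (2 * width)
}

#' Per-frame inner-lip MAR
#'
#' @param frame a [landmark_frame()] with a face present.
#' @param map a [landmark_index_map()].
#' @return The MAR for the frame.
#' @export
frame_mar <- function(frame, map = landmark_index_map()) {
  p <- inner_mouth_points(frame, map)
  compute_mar(p$vertical_a, p$vertical_b, p$horizontal)
}

#' Classify the mouth state from a MAR value
#'
#' The mouth is open (`M = 1`) when the ratio is at or above the threshold
#' and closed (`M = 0`) below it.
#'
#' @param beta MAR value(s), non-negative.
#' @param threshold open/closed decision threshold; default 0.35.
#' @return Integer code(s) `M`: 1 = open, 0 = closed (vectorised over `beta`).
#' @export
classify_mouth <- function(beta, threshold = 0.35) {
  stopifnot(all(beta >= 0), threshold >= 0)
  as.integer(beta >= threshold)
}

#' Classify a mouth-opening episode by its duration
#'
#' An opening episode is graded by the number of consecutive open-mouth
#' frames (its COUNTER): ordinary opening such as speaking (`Y = 0`) up to
#' `yawn_frames`, a yawn (`Y = 1`) above `yawn_frames` and up to
#' `deep_yawn_frames`, and a deep yawn (`Y = 2`) beyond that. Deep yawning is
#' the strongest single fatigue indicator in the fused alert rule.
#'
#' @param counter consecutive open-mouth frame count(s), non-negative.
#' @param yawn_frames frame threshold separating ordinary opening from a
#'   yawn; default 25.
#' @param deep_yawn_frames frame threshold separating a yawn from a deep
#'   yawn; default 50.
#' @return Integer class code(s) `Y` in `{0, 1, 2}` (vectorised).
#' @export
classify_yawn <- function(counter, yawn_frames = 25L, deep_yawn_frames = 50L) {
  if (any(counter < 0)) stop("episode frame counter must be non-negative")
  stopifnot(yawn_frames < deep_yawn_frames)
  ifelse(counter > deep_yawn_frames, 2L,
         ifelse(counter > yawn_frames, 1L, 0L))
}

#' Segment per-frame mouth states into opening episodes
#'
#' Maximal runs of `M = 1` become episodes; each is classified through
#' [classify_yawn()] by its run length. Episodes are returned in temporal
#' order and partition exactly the open-mouth frames.
#'
#' @param states integer vector of mouth codes drawn from `{0, 1}`.
#' @param frame_index optional vector of frame indices aligned with `states`;
#'   defaults to `0:(length(states)-1)`.
#' @param yawn_frames,deep_yawn_frames thresholds passed to [classify_yawn()].
#' @return A data frame with one row per episode: `start_frame`, `end_frame`,
#'   `counter` (run length in frames), `yawn_class`.
#' @export
segment_mouth_episodes <- function(states, frame_index = NULL,
                                   yawn_frames = 25L, deep_yawn_frames = 50L) {
  states <- as.integer(states)
  stopifnot(all(states %in% c(0L, 1L)))
  if (is.null(frame_index)) frame_index <- seq_along(states) - 1L
  stopifnot(length(frame_index) == length(states))
  if (length(states) == 0L || !any(states == 1L)) {
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      counter = integer(), yawn_class = integer()))
  }
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  open <- which(r$values == 1L)
  data.frame(
    start_frame = frame_index[starts[open]],
    end_frame = frame_index[ends[open]],
    counter = r$lengths[open],
    yawn_class = classify_yawn(r$lengths[open], yawn_frames, deep_yawn_frames)
  )
}
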