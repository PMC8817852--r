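#' facevigil: learning-state assessment from facial landmark streams
#'
#' Tools for assessing attention and fatigue from 68-point facial-landmark
#' video streams: EAR-based blink detection, inner-lip MAR yawn detection,
#' perspective-n-point head-pose estimation with Euler-angle state machines,
#' and a fused per-window alert rule, together with a ground-truthed
#' synthetic stream simulator.
#'
#' @keywords internal
"_PACKAGE"

# Landmark ids throughout this package follow the 68-point face-alignment
# convention used by dlib-style detectors: ids 0..67, jaw 0-16, brows 17-26,
# nose 27-35, eyes 36-47, outer lips 48-59, inner lips 60-67.  R matrices are
# subset through lm_rows() so the off-by-one conversion lives in one place.

lm_rows <- function(ids) ids + 1L

#' Landmark index map for the 68-point face model
#'
#' Returns the fixed groups of landmark ids (0-based, dlib convention) used by
#' the feature extractors: the six points of each eye, the inner-lip point
#' pairs entering the mouth aspect ratio, and the 14 points used for head-pose
#' estimation.
#'
#' The inner-lip pairs are, in the 1-based numbering of face-alignment
#' figures, (62,68) and (64,66) vertical and (61,65) horizontal; as 0-based
#' ids these are (61,67), (63,65) and (60,64). The pose set comprises the four
#' brow corners (17, 21, 22, 26), the four outer/inner eye corners
#' (36, 39, 42, 45), the nose-base corners (31, 35), the outer mouth corners
#' (48, 54), the lower-lip centre (57) and the chin tip (8).
#'
#' @param nose_lower_right id used for the right nose-base corner; default 35,
#'   the bilateral partner of 31.
#' @return A list of class `landmark_index_map` with elements `left_eye`,
#'   `right_eye` (6 ids each, ordered P1..P6), `inner_mouth_vertical_pairs`
#'   (list of two length-2 id vectors), `inner_mouth_horizontal_pair`
#'   (length-2 id vector), and `pose_points` (named vector of 14 ids).
#' @examples
#' landmark_index_map()$left_eye
#' @export
landmark_index_map <- function(nose_lower_right = 35L) {
  nose_lower_right <- as.integer(nose_lower_right)
  stopifnot(nose_lower_right >= 0L, nose_lower_right <= 67L)
  map <- list(
    left_eye  = 36:41,
    right_eye = 42:47,
    inner_mouth_vertical_pairs = list(c(61L, 67L), c(63L, 65L)),
    inner_mouth_horizontal_pair = c(60L, 64L),
    pose_points = c(
      brow_left_outer  = 17L, brow_left_inner  = 21L,
      brow_right_inner = 22L, brow_right_outer = 26L,
      eye_left_outer   = 36L, eye_left_inner   = 39L,
      eye_right_inner  = 42L, eye_right_outer  = 45L,
      nose_lower_left  = 31L, nose_lower_right = nose_lower_right,
      mouth_left       = 48L, mouth_right      = 54L,
      lip_lower_centre = 57L, chin             = 8L
    )
  )
  class(map) <- "landmark_index_map"
  map
}

#' Construct a single landmark frame
#'
#' One video frame's worth of landmark data: a frame index, a timestamp in
#' seconds, a face-presence flag, and (when a face is present) the 68 labelled
#' 2D points in pixel coordinates (origin top-left, y increasing downward).
#'
#' @param frame_index non-negative integer frame number.
#' @param timestamp time of the frame in seconds.
#' @param face_present logical; whether a face was detected in this frame.
#' @param points a 68 x 2 numeric matrix of (x, y) pixel coordinates; must be
#'   `NULL` when `face_present` is `FALSE`.
#' @return An object of class `landmark_frame`.
#' @export
landmark_frame <- function(frame_index, timestamp, face_present, points = NULL) {
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L)
    stop("frame_index must be a non-negative integer")
  if (!is.numeric(timestamp) || length(timestamp) != 1L || !is.finite(timestamp))
    stop("timestamp must be a single finite number")
  face_present <- isTRUE(face_present)
  if (face_present) {
    if (is.null(points))
      stop("points must be a 68 x 2 numeric matrix when face_present is TRUE")
    points <- as.matrix(points)
    if (!is.numeric(points) || !identical(dim(points), c(68L, 2L)))
      stop("points must be a 68 x 2 numeric matrix when face_present is TRUE")
    if (!all(is.finite(points)))
      stop("all landmark coordinates must be finite")
    dimnames(points) <- list(NULL, c("x", "y"))
  } else {
    if (!is.null(points) && NROW(points) > 0L)
      stop("points must be absent when face_present is FALSE")
    points <- NULL
  }
  structure(
    list(frame_index = frame_index, timestamp = as.numeric(timestamp),
         face_present = face_present, points = points),
    class = "landmark_frame"
  )
}

#' @export
print.landmark_frame <- function(x, ...) {
  cat(sprintf("<landmark_frame #%d t=%.3fs face=%s>\n",
              x$frame_index, x$timestamp,
              if (x$face_present) "yes" else "no"))
  invisible(x)
}

stop_absent_face <- function(frame) {
  stop(sprintf("frame %d has no detected face; landmark points are unavailable",
               frame$frame_index))
}

validate_stream <- function(frames) {
  if (length(frames) == 0L) return(invisible(frames))
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  ts  <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (any(diff(idx) <= 0L))
    stop("frame_index must be strictly increasing within a stream")
  if (any(diff(ts) < 0))
    stop("timestamps must be non-decreasing within a stream")
  invisible(frames)
}

#' Read a landmark stream from a JSON-lines file
#'
#' Each line is one JSON object with keys `frame` (integer), `t` (seconds),
#' `face` (0/1), and, when `face` is 1, `pts`: a length-68 array of
#' `[x, y]` pixel pairs. This append-friendly dialect is what
#' [write_landmark_stream()] emits and what the live-detector adapters are
#' expected to produce.
#'
#' @param path path to a JSON-lines landmark stream.
#' @return A list of [landmark_frame()] objects, in file order, with class
#'   `landmark_stream`.
#' @seealso [write_landmark_stream()]
#' @export
read_landmark_stream <- function(path) {
  if (!file.exists(path)) stop("landmark stream file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  frames <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyMatrix = TRUE),
      error = function(e)
        stop(sprintf("malformed landmark record at line %d: %s",
                     i, conditionMessage(e)), call. = FALSE)
    )
    for (key in c("frame", "t", "face")) {
      if (is.null(rec[[key]]))
        stop(sprintf("malformed landmark record at line %d: missing key '%s'",
                     i, key), call. = FALSE)
    }
    face <- as.integer(rec$face) == 1L
    pts <- if (face) {
      if (is.null(rec$pts))
        stop(sprintf("malformed landmark record at line %d: face=1 but no pts", i),
             call. = FALSE)
      matrix(as.numeric(t(rec$pts)), ncol = 2L, byrow = TRUE)
    } else NULL
    frames[[i]] <- landmark_frame(rec$frame, rec$t, face, pts)
  }
  validate_stream(frames)
  structure(frames, class = "landmark_stream")
}

#' Write a landmark stream to a JSON-lines file
#'
#' @param frames a list of [landmark_frame()] objects (a `landmark_stream`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_landmark_stream()]
#' @export
write_landmark_stream <- function(frames, path) {
  validate_stream(frames)
  con <- file(path, open = "w")
  on.exit(close(con))
  for (f in frames) {
    rec <- list(frame = f$frame_index, t = f$timestamp,
                face = as.integer(f$face_present))
    if (f$face_present) {
      rec$pts <- lapply(seq_len(68L), function(i) as.numeric(f$points[i, ]))
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Extract the six eye landmarks of one eye
#'
#' Returns the six points P1..P6 of the requested eye in the conventional
#' layout: P1 the outer corner, P4 the inner corner, P2/P3 on the upper lid,
#' P6/P5 on the lower lid (ids 36-41 for the left eye, 42-47 for the right).
#'
#' @param frame a [landmark_frame()] with a face present.
#' @param side `"left"` or `"right"`.
#' @param map a [landmark_index_map()].
#' @return A 6 x 2 matrix, rows ordered P1..P6.
#' @export
eye_points <- function(frame, side = c("left", "right"),
                       map = landmark_index_map()) {
  side <- match.arg(side)
  if (!frame$face_present) stop_absent_face(frame)
  ids <- if (side == "left") map$left_eye else map$right_eye
  frame$points[lm_rows(ids), , drop = FALSE]
}

#' Extract the inner-lip landmark pairs used for the mouth aspect ratio
#'
#' @param frame a [landmark_frame()] with a face present.
#' @param map a [landmark_index_map()].
#' @return A list with elements `vertical_a`, `vertical_b` (2 x 2 matrices:
#'   upper point then lower point of each vertical pair) and `horizontal`
#'   (2 x 2 matrix: left then right inner mouth corner).
#' @export
inner_mouth_points <- function(frame, map = landmark_index_map()) {
  if (!frame$face_present) stop_absent_face(frame)
  vp <- map$inner_mouth_vertical_pairs
  list(
    vertical_a = frame$points[lm_rows(vp[[1]]), , drop = FALSE],
    vertical_b = frame$points[lm_rows(vp[[2]]), , drop = FALSE],
    horizontal = frame$points[lm_rows(map$inner_mouth_horizontal_pair), ,
                              drop = FALSE]
  )
}

#' Extract the 14 labelled landmarks used for head-pose estimation
#'
#' @param frame a [landmark_frame()] with a face present.
#' @param map a [landmark_index_map()].
#' @return A 14 x 2 matrix with row names giving the point roles, in the
#'   same order as the rows of [face_model_3d()].
#' @export
pose_points <- function(frame, map = landmark_index_map()) {
  if (!frame$face_present) stop_absent_face(frame)
  pts <- frame$points[lm_rows(map$pose_points), , drop = FALSE]
  rownames(pts) <- names(map$pose_points)
  pts
}
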