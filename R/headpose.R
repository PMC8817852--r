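#' Camera intrinsics
#'
#' Pinhole camera parameters with the standard radial (`k1`, `k2`, `k3`) and
#' tangential (`p1`, `p2`) distortion coefficients. All distortion
#' coefficients default to zero.
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels.
#' @param k1,k2,k3 radial distortion coefficients.
#' @param p1,p2 tangential distortion coefficients.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy,
                              k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  stopifnot(fx > 0, fy > 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2),
            class = "camera_intrinsics")
}

#' Default intrinsics for an uncalibrated webcam
#'
#' The common uncalibrated approximation: focal lengths equal to the image
#' width, principal point at the image centre, zero distortion.
#'
#' @param width,height image size in pixels.
#' @return A [camera_intrinsics()] object.
#' @export
default_intrinsics <- function(width = 640, height = 480) {
  camera_intrinsics(fx = width, fy = width, cx = width / 2, cy = height / 2)
}

intrinsics_matrix <- function(intr) {
  matrix(c(intr$fx, 0, intr$cx,
           0, intr$fy, intr$cy,
           0, 0, 1), 3, 3, byrow = TRUE)
}

has_distortion <- function(intr) {
  any(c(intr$k1, intr$k2, intr$k3, intr$p1, intr$p2) != 0)
}

#' Built-in 14-point 3D face model for head-pose estimation
#'
#' A generic anthropometric rigid model of the 14 facial points used for
#' pose estimation, in millimetres. Axes are camera-aligned at the neutral
#' pose: x to the subject's image-right, y downward, z away from the camera,
#' origin at the nose base, so that a frontal face corresponds to the
#' identity rotation. The model is bilaterally symmetric about x = 0 and
#' non-coplanar. It is a synthetic fixture: values are plausible adult
#' averages, not measurements of any individual; users may supply their own
#' model with the same row order.
#'
#' @return A 14 x 3 numeric matrix with row names matching
#'   `landmark_index_map()$pose_points` and columns `x`, `y`, `z`.
#' @export
face_model_3d <- function() {
  m <- rbind(
    brow_left_outer  = c(-52, -48, 12),
    brow_left_inner  = c(-18, -52, 2),
    brow_right_inner = c( 18, -52, 2),
    brow_right_outer = c( 52, -48, 12),
    eye_left_outer   = c(-45, -32, 15),
    eye_left_inner   = c(-19, -30, 10),
    eye_right_inner  = c( 19, -30, 10),
    eye_right_outer  = c( 45, -32, 15),
    nose_lower_left  = c(-15,  12, 2),
    nose_lower_right = c( 15,  12, 2),
    mouth_left       = c(-26,  35, 10),
    mouth_right      = c( 26,  35, 10),
    lip_lower_centre = c(  0,  46, 7),
    chin             = c(  0,  72, 14)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

# distortion model: given normalised undistorted (u, v), return distorted
# (u', v'). Radial terms in r^2, r^4, r^6 plus the two tangential terms.
apply_distortion <- function(uv, intr) {
  u <- uv[, 1]; v <- uv[, 2]
  r2 <- u^2 + v^2
  radial <- 1 + intr$k1 * r2 + intr$k2 * r2^2 + intr$k3 * r2^3
  ud <- u * radial + 2 * intr$p1 * u * v + intr$p2 * (r2 + 2 * u^2)
  vd <- v * radial + 2 * intr$p2 * u * v + intr$p1 * (r2 + 2 * v^2)
  cbind(ud, vd)
}

# invert apply_distortion by fixed-point iteration on the normalised plane
undistort_points <- function(uv, intr, iterations = 30L) {
  if (!has_distortion(intr)) return(uv)
  u0 <- uv[, 1]; v0 <- uv[, 2]
  u <- u0; v <- v0
  for (i in seq_len(iterations)) {
    r2 <- u^2 + v^2
    radial <- 1 + intr$k1 * r2 + intr$k2 * r2^2 + intr$k3 * r2^3
    du <- 2 * intr$p1 * u * v + intr$p2 * (r2 + 2 * u^2)
    dv <- 2 * intr$p2 * u * v + intr$p1 * (r2 + 2 * v^2)
    u <- (u0 - du) / radial
    v <- (v0 - dv) / radial
  }
  cbind(u, v)
}

#' Project 3D model points through the camera model
#'
#' Applies the rigid transform `X = R U + T` from model (world) to camera
#' coordinates, normalises by depth to the image-centre plane, applies lens
#' distortion, and maps to pixel coordinates through the intrinsic matrix.
#' With all distortion coefficients zero this is exactly the pinhole
#' projection.
#'
#' @param points3d an n x 3 matrix of model points.
#' @param rotation a 3 x 3 rotation matrix.
#' @param translation a length-3 translation vector (same units as
#'   `points3d`).
#' @param intrinsics a [camera_intrinsics()].
#' @return An n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(points3d, rotation, translation, intrinsics) {
  P <- as.matrix(points3d)
  stopifnot(ncol(P) == 3L)
  Xc <- P %*% t(rotation) + matrix(translation, nrow(P), 3, byrow = TRUE)
  if (any(Xc[, 3] <= 0))
    stop("point behind camera: non-positive depth after rigid transform")
  uv <- cbind(Xc[, 1] / Xc[, 3], Xc[, 2] / Xc[, 3])
  uv <- apply_distortion(uv, intrinsics)
  cbind(x = intrinsics$fx * uv[, 1] + intrinsics$cx,
        y = intrinsics$fy * uv[, 2] + intrinsics$cy)
}

# Direct linear transform: estimate [R|T] from >= 6 correspondences between
# model points and *normalised undistorted* image coordinates. Solves the
# homogeneous system for the 3x4 matrix by SVD, fixes scale and sign from
# the rotation rows and cheirality, and projects onto SO(3).
dlt_pose <- function(object_points, uv_norm) {
  n <- nrow(object_points)
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    X <- c(object_points[i, ], 1)
    u <- uv_norm[i, 1]; v <- uv_norm[i, 2]
    A[2 * i - 1, ] <- c(X, rep(0, 4), -u * X)
    A[2 * i, ]     <- c(rep(0, 4), X, -v * X)
  }
  sv <- svd(A)
  if (sv$d[11] / sv$d[1] < 1e-10)
    stop("singular configuration: landmark correspondences are degenerate for pose estimation")
  p <- sv$v[, 12]
  M <- matrix(p, 3, 4, byrow = TRUE)
  Rraw <- M[, 1:3]
  scale <- (sum(sqrt(rowSums(Rraw^2)))) / 3
  if (scale < 1e-12)
    stop("singular configuration: degenerate DLT solution")
  M <- M / scale
  # cheirality: mean depth of the model must be positive
  depths <- object_points %*% M[3, 1:3] + M[3, 4]
  if (mean(depths) < 0) M <- -M
  sv2 <- svd(M[, 1:3])
  R <- sv2$u %*% t(sv2$v)
  if (det(R) < 0) R <- sv2$u %*% diag(c(1, 1, -1)) %*% t(sv2$v)
  list(rotation = R, translation = M[, 4])
}

reprojection_residuals <- function(rvec, tvec, object_points, image_points,
                                   intrinsics) {
  proj <- project_points(object_points, rodrigues_to_rotation(rvec), tvec,
                         intrinsics)
  as.numeric(proj - image_points)
}

#' Solve head pose from 2D-3D landmark correspondences (PnP)
#'
#' Recovers the rotation and translation of the rigid 3D face model relative
#' to the camera from corresponding image landmarks: a direct linear
#' transform (DLT) on undistorted normalised coordinates provides the
#' initial estimate, which is refined by Levenberg-damped Gauss-Newton
#' iterations minimising the summed squared reprojection error
#' \eqn{J = \sum_i (\hat x_i - x_i)^2 + (\hat y_i - y_i)^2}. The rotation is
#' parameterised as a Rodrigues vector during refinement and returned
#' orthonormal.
#'
#' @param object_points an n x 3 matrix of rigid model points (n >= 6), e.g.
#'   [face_model_3d()].
#' @param image_points an n x 2 matrix of observed pixel coordinates in the
#'   same row order, e.g. [pose_points()].
#' @param intrinsics a [camera_intrinsics()].
#' @param max_iterations refinement iteration cap; default 100.
#' @param tol convergence threshold on the relative change of the residual
#'   norm; default 1e-12.
#' @return An object of class `head_pose`: a list with `rotation` (3 x 3),
#'   `rvec` (Rodrigues vector), `translation`, `euler` (named degrees triple
#'   from [rotation_to_euler()]), `rms` (reprojection root-mean-square error
#'   in pixels), `iterations`, and `converged`.
#' @export
solve_pose <- function(object_points, image_points, intrinsics,
                       max_iterations = 100L, tol = 1e-12) {
  object_points <- as.matrix(object_points)
  image_points <- as.matrix(image_points)
  n <- nrow(object_points)
  if (n < 6L) stop("at least 6 correspondences are required")
  stopifnot(nrow(image_points) == n, ncol(object_points) == 3L,
            ncol(image_points) == 2L)
  K <- intrinsics_matrix(intrinsics)
  uv <- cbind((image_points[, 1] - intrinsics$cx) / intrinsics$fx,
              (image_points[, 2] - intrinsics$cy) / intrinsics$fy)
  uv <- undistort_points(uv, intrinsics)
  init <- dlt_pose(object_points, uv)
  rvec <- rotation_to_rodrigues(init$rotation)
  tvec <- init$translation

  theta <- c(rvec, tvec)
  res <- reprojection_residuals(theta[1:3], theta[4:6], object_points,
                                image_points, intrinsics)
  cost <- sum(res^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    # numeric Jacobian, central differences
    J <- matrix(0, length(res), 6L)
    h <- pmax(1e-7, abs(theta) * 1e-7)
    for (j in 1:6) {
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + h[j]; tm[j] <- tm[j] - h[j]
      rp <- reprojection_residuals(tp[1:3], tp[4:6], object_points,
                                   image_points, intrinsics)
      rm <- reprojection_residuals(tm[1:3], tm[4:6], object_points,
                                   image_points, intrinsics)
      J[, j] <- (rp - rm) / (2 * h[j])
    }
    g <- crossprod(J, res)
    H <- crossprod(J)
    step_ok <- FALSE
    for (k in 1:20) {
      delta <- tryCatch(
        solve(H + lambda * diag(diag(H) + 1e-12), -g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        cand_res <- tryCatch(
          reprojection_residuals(cand[1:3], cand[4:6], object_points,
                                 image_points, intrinsics),
          error = function(e) NULL
        )
        if (!is.null(cand_res) && sum(cand_res^2) <= cost) {
          rel <- (cost - sum(cand_res^2)) / max(cost, 1e-300)
          theta <- cand
          res <- cand_res
          cost <- sum(cand_res^2)
          lambda <- max(lambda / 10, 1e-12)
          step_ok <- TRUE
          if (rel < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- TRUE }  # no descent direction: at a minimum
    if (converged) break
  }
  if (!converged)
    warning(sprintf("pose refinement did not converge in %d iterations (residual %.3g)",
                    max_iterations, sqrt(cost / n / 2)))
  R <- rodrigues_to_rotation(theta[1:3])
  structure(
    list(rotation = R, rvec = theta[1:3], translation = theta[4:6],
         euler = rotation_to_euler(R),
         rms = sqrt(cost / (2 * n)),
         iterations = iter, converged = converged),
    class = "head_pose"
  )
}

#' @export
print.head_pose <- function(x, ...) {
  cat(sprintf("<head_pose pitch=%.2f yaw=%.2f roll=%.2f rms=%.3g px>\n",
              x$euler["pitch"], x$euler["yaw"], x$euler["roll"], x$rms))
  invisible(x)
}

#' Classify head normality from an Euler triple
#'
#' The head is in the normal state (`H = 1`) when all three Euler angles lie
#' inside the symmetric band `[-threshold, threshold]`, and abnormal
#' (`H = 0`) as soon as any channel leaves it. Abnormal behaviour covers both
#' dozing (pitch/roll) and sight deviation (yaw).
#'
#' @param euler numeric triple `(pitch, yaw, roll)` in degrees.
#' @param threshold angular band half-width in degrees; default 15.
#' @return Integer code `H`: 1 = normal, 0 = abnormal.
#' @export
classify_head <- function(euler, threshold = 15) {
  euler <- as.numeric(euler)
  stopifnot(length(euler) == 3L, all(is.finite(euler)), threshold >= 0)
  as.integer(all(abs(euler) <= threshold))
}

#' Create a fresh head-pose counter state
#'
#' Holds the three per-channel consecutive out-of-range frame counters
#' (PCOUNTER for pitch, YCOUNTER for yaw, RCOUNTER for roll).
#'
#' @return An object of class `head_state` with counters at zero.
#' @export
head_state <- function() {
  structure(list(pcounter = 0L, ycounter = 0L, rcounter = 0L),
            class = "head_state")
}

#' Update the per-channel head counters with one frame's Euler angles
#'
#' Each channel's counter increments while that channel is outside
#' `[-threshold, threshold]` and resets to zero the moment it re-enters the
#' band, so each counter always equals the length of the current trailing
#' out-of-range run of its channel.
#'
#' @param state a [head_state()].
#' @param euler numeric triple `(pitch, yaw, roll)` in degrees for the
#'   current frame.
#' @param threshold angular band half-width in degrees; default 15.
#' @return The updated `head_state`.
#' @export
update_head_counters <- function(state, euler, threshold = 15) {
  stopifnot(inherits(state, "head_state"))
  euler <- as.numeric(euler)
  stopifnot(length(euler) == 3L, all(is.finite(euler)))
  out <- abs(euler) > threshold
  state$pcounter <- if (out[1]) state$pcounter + 1L else 0L
  state$ycounter <- if (out[2]) state$ycounter + 1L else 0L
  state$rcounter <- if (out[3]) state$rcounter + 1L else 0L
  state
}

#' Classify the head event from the counter state
#'
#' A sustained pitch or roll excursion (counter above `frame_threshold`)
#' signals fatigue (`P = 1`, nodding off or head sagging sideways); a
#' sustained yaw excursion signals sight deviation (`P = 2`, looking away
#' from the screen). When both conditions hold simultaneously, both flags are
#' reported and the scalar code prefers 1, fatigue being the safety-critical
#' state.
#'
#' @param state a [head_state()] with current counters.
#' @param frame_threshold consecutive-frame threshold; default 60.
#' @return A list with integer `code` (`P` in `{0, 1, 2}`) and logical flags
#'   `fatigue` and `sight_deviation`.
#' @export
classify_head_event <- function(state, frame_threshold = 60L) {
  stopifnot(inherits(state, "head_state"))
  fatigue <- state$pcounter > frame_threshold || state$rcounter > frame_threshold
  sight <- state$ycounter > frame_threshold
  code <- if (fatigue) 1L else if (sight) 2L else 0L
  list(code = code, fatigue = fatigue, sight_deviation = sight)
}
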