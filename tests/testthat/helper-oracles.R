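# Shared fixtures and independent oracles for the test suite.

template_frame <- function(shape = face_shape(), frame_index = 0) {
  tpl <- neutral_template(shape)
  landmark_frame(frame_index, frame_index / 25, TRUE, tpl$points2d)
}

# random similarity transform of a point set (rotation + uniform scale +
# translation), used for the EAR/MAR invariance properties
similarity_transform <- function(points, angle, scale, shift) {
  Rot <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2)
  sweep(points %*% t(Rot) * scale, 2, shift, "+")
}

# brute-force blink counter: explicit scan for 1 -> 0-run -> 1 patterns
oracle_count_blinks <- function(states, min_closed = 1L) {
  n <- length(states)
  count <- 0L
  i <- 1L
  while (i <= n) {
    if (states[i] == 0L) {
      j <- i
      while (j < n && states[j + 1L] == 0L) j <- j + 1L
      if (i > 1L && j < n && states[i - 1L] == 1L && states[j + 1L] == 1L &&
          (j - i + 1L) >= min_closed) {
        count <- count + 1L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  count
}

# brute-force mouth-episode extraction: explicit scan over open runs
oracle_episodes <- function(states) {
  runs <- list()
  i <- 1L
  n <- length(states)
  while (i <= n) {
    if (states[i] == 1L) {
      j <- i
      while (j < n && states[j + 1L] == 1L) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(start = i - 1L, end = j - 1L,
                                     len = j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  runs
}

# trailing out-of-range run length of one angle channel
oracle_trailing_run <- function(values, threshold = 15) {
  run <- 0L
  for (v in values) run <- if (abs(v) > threshold) run + 1L else 0L
  run
}

# Independent reference PnP solver: weak-perspective (POS) initialisation
# followed by general-purpose BFGS minimisation of the reprojection error
# via stats::optim. Shares no code with facevigil::solve_pose (which uses
# DLT + damped Gauss-Newton).
reference_pnp <- function(object_points, image_points, intrinsics) {
  x <- (image_points[, 1] - intrinsics$cx) / intrinsics$fx
  y <- (image_points[, 2] - intrinsics$cy) / intrinsics$fy
  U0 <- colMeans(object_points)
  A <- sweep(object_points, 2, U0)
  m1 <- qr.solve(A, x - mean(x))
  m2 <- qr.solve(A, y - mean(y))
  s <- (sqrt(sum(m1^2)) + sqrt(sum(m2^2))) / 2
  r1 <- m1 / sqrt(sum(m1^2))
  r2 <- m2 - sum(r1 * m2) * r1
  r2 <- r2 / sqrt(sum(r2^2))
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  R0 <- rbind(r1, r2, r3)
  sv <- svd(R0)
  R0 <- sv$u %*% t(sv$v)
  if (det(R0) < 0) R0 <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  tz <- 1 / s
  T0 <- c(mean(x) * tz, mean(y) * tz, tz) - as.numeric(R0 %*% U0)
  sse <- function(par) {
    R <- rodrigues_to_rotation(par[1:3])
    Xc <- object_points %*% t(R) + matrix(par[4:6], nrow(object_points), 3,
                                          byrow = TRUE)
    if (any(Xc[, 3] <= 0)) return(1e12)
    px <- intrinsics$fx * Xc[, 1] / Xc[, 3] + intrinsics$cx
    py <- intrinsics$fy * Xc[, 2] / Xc[, 3] + intrinsics$cy
    sum((px - image_points[, 1])^2 + (py - image_points[, 2])^2)
  }
  fit <- stats::optim(c(rotation_to_rodrigues(R0), T0), sse, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  list(rotation = rodrigues_to_rotation(fit$par[1:3]),
       translation = fit$par[4:6],
       euler = rotation_to_euler(rodrigues_to_rotation(fit$par[1:3])))
}

random_pose_instance <- function(max_angle = 45) {
  e <- stats::runif(3, -max_angle, max_angle)
  R <- euler_to_rotation(e[1], e[2], e[3])
  tvec <- c(stats::runif(2, -40, 40), stats::runif(1, 400, 700))
  list(euler = e, rotation = R, translation = tvec)
}
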