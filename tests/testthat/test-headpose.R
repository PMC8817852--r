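test_that("projection obeys the pinhole geometry", {
  intr <- camera_intrinsics(fx = 600, fy = 620, cx = 320, cy = 240)
  # a point on the optical axis lands on the principal point
  expect_equal(unname(project_points(rbind(c(0, 0, 500)), diag(3), c(0, 0, 0),
                                     intr)[1, ]),
               c(320, 240))
  # general pinhole: x = fx X/Z + cx
  p <- rbind(c(30, -20, 400))
  expect_equal(unname(project_points(p, diag(3), c(0, 0, 0), intr)[1, ]),
               c(600 * 30 / 400 + 320, 620 * -20 / 400 + 240))
  expect_error(project_points(rbind(c(0, 0, -5)), diag(3), c(0, 0, 0), intr),
               "behind camera")
})

test_that("zero distortion reproduces the pure pinhole path exactly", {
  set.seed(41)
  intr0 <- camera_intrinsics(fx = 640, fy = 640, cx = 320, cy = 240)
  K <- rbind(c(640, 0, 320), c(0, 640, 240), c(0, 0, 1))
  for (i in 1:20) {
    inst <- random_pose_instance()
    pts <- face_model_3d()
    proj <- project_points(pts, inst$rotation, inst$translation, intr0)
    Xc <- pts %*% t(inst$rotation) +
      matrix(inst$translation, nrow(pts), 3, byrow = TRUE)
    hom <- Xc %*% t(K)
    expect_equal(unname(proj), unname(hom[, 1:2] / hom[, 3]))
  }
})

test_that("distortion is applied per the radial-tangential model and inverts", {
  intr <- camera_intrinsics(fx = 640, fy = 640, cx = 320, cy = 240,
                            k1 = -0.2, k2 = 0.05, k3 = -0.01,
                            p1 = 0.001, p2 = -0.002)
  p3 <- rbind(c(40, 25, 400))
  proj <- project_points(p3, diag(3), c(0, 0, 0), intr)
  # independent evaluation of the distortion polynomial
  u <- 40 / 400; v <- 25 / 400; r2 <- u^2 + v^2
  rad <- 1 + intr$k1 * r2 + intr$k2 * r2^2 + intr$k3 * r2^3
  ud <- u * rad + 2 * intr$p1 * u * v + intr$p2 * (r2 + 2 * u^2)
  vd <- v * rad + 2 * intr$p2 * u * v + intr$p1 * (r2 + 2 * v^2)
  expect_equal(unname(proj[1, ]), c(640 * ud + 320, 640 * vd + 240))
  # a distortion-aware solve still recovers the pose
  set.seed(42)
  inst <- random_pose_instance(max_angle = 30)
  img <- project_points(face_model_3d(), inst$rotation, inst$translation, intr)
  pose <- solve_pose(face_model_3d(), img, intr)
  expect_lt(max(abs(pose$euler - c(pitch = inst$euler[1], yaw = inst$euler[2],
                                   roll = inst$euler[3]))), 0.01)
  expect_lt(pose$rms, 1e-6)
})

test_that("solve_pose recovers synthetic poses exactly at zero noise", {
  intr <- default_intrinsics()
  set.seed(43)
  for (i in 1:25) {
    inst <- random_pose_instance(max_angle = 45)
    img <- project_points(face_model_3d(), inst$rotation, inst$translation,
                          intr)
    pose <- solve_pose(face_model_3d(), img, intr)
    expect_lt(max(abs(pose$euler - inst$euler)), 0.01)
    expect_lt(pose$rms, 1e-6)
    expect_lt(max(abs(crossprod(pose$rotation) - diag(3))), 1e-9)
    expect_lt(abs(det(pose$rotation) - 1), 1e-9)
    expect_lt(max(abs(pose$translation - inst$translation)), 0.01)
  }
  # neutral pose
  img <- project_points(face_model_3d(), diag(3), c(0, 0, 500), intr)
  pose <- solve_pose(face_model_3d(), img, intr)
  expect_lt(max(abs(pose$euler)), 1e-6)
})

test_that("solve_pose stays accurate under pixel noise (regression)", {
  intr <- default_intrinsics()
  set.seed(44)
  errs <- replicate(20, {
    inst <- random_pose_instance(max_angle = 35)
    img <- project_points(face_model_3d(), inst$rotation, inst$translation,
                          intr)
    img <- img + matrix(rnorm(length(img), sd = 1), nrow(img), 2)
    pose <- solve_pose(face_model_3d(), img, intr)
    max(abs(pose$euler - inst$euler))
  })
  expect_lt(median(errs), 2)
})

test_that("degenerate correspondence sets are rejected", {
  intr <- default_intrinsics()
  line <- cbind(seq(-50, 50, length.out = 14), 0, 0)  # collinear model
  img <- project_points(line, diag(3), c(0, 0, 500), intr)
  expect_error(solve_pose(line, img, intr), "singular|degenerate")
  expect_error(solve_pose(face_model_3d()[1:5, ],
                          matrix(0, 5, 2), intr), "at least 6")
})

test_that("Rodrigues conversion is exact on closed forms and round trips", {
  expect_equal(rotation_to_rodrigues(diag(3)), c(0, 0, 0))
  expect_equal(rotation_to_rodrigues(euler_to_rotation(0, 0, 90)),
               c(0, 0, pi / 2))
  expect_equal(rodrigues_to_rotation(c(0, 0, pi / 2)),
               euler_to_rotation(0, 0, 90))
  set.seed(45)
  for (i in 1:200) {
    v <- rnorm(3) * runif(1, 0.01, 1)
    R <- rodrigues_to_rotation(v * (pi * 0.99) / max(1e-9, sqrt(sum(v^2))) *
                                 runif(1))
    expect_lt(max(abs(rodrigues_to_rotation(rotation_to_rodrigues(R)) - R)),
              1e-10)
  }
  expect_error(rotation_to_rodrigues(matrix(1, 3, 3)), "not a rotation")
})

test_that("Euler decomposition round trips within the working range", {
  expect_equal(unname(rotation_to_euler(diag(3))), c(0, 0, 0))
  expect_equal(unname(rotation_to_euler(euler_to_rotation(0, 10, 0))),
               c(0, 10, 0))
  set.seed(46)
  for (i in 1:300) {
    e <- c(runif(1, -179, 179), runif(1, -89, 89), runif(1, -179, 179))
    back <- rotation_to_euler(euler_to_rotation(e[1], e[2], e[3]))
    expect_lt(max(abs(unname(back) - e)), 1e-8)
  }
})

test_that("head normality requires every channel inside the band", {
  expect_equal(classify_head(c(0, 0, 0)), 1L)
  expect_equal(classify_head(c(-19.13, 2, 1)), 0L)
  expect_equal(classify_head(c(15, 15, 15)), 1L)
  expect_equal(classify_head(c(0, 15.01, 0)), 0L)
  expect_equal(classify_head(c(20, 20, 20), threshold = 25), 1L)
})

test_that("per-channel counters track the trailing out-of-range run", {
  st <- head_state()
  for (i in 1:70) st <- update_head_counters(st, c(0, 30, 0))
  expect_equal(st$ycounter, 70L)
  expect_equal(st$pcounter, 0L)
  st <- update_head_counters(st, c(0, 3, 0))
  expect_equal(st$ycounter, 0L)
  st2 <- head_state()
  for (i in 1:50) st2 <- update_head_counters(st2, c(1, -2, 3))
  expect_equal(unlist(st2[c("pcounter", "ycounter", "rcounter")]),
               c(pcounter = 0L, ycounter = 0L, rcounter = 0L))
  set.seed(47)
  for (rep in 1:10) {
    angles <- matrix(runif(3 * 120, -40, 40), ncol = 3)
    st <- head_state()
    for (i in seq_len(nrow(angles))) st <- update_head_counters(st, angles[i, ])
    expect_equal(st$pcounter, oracle_trailing_run(angles[, 1]))
    expect_equal(st$ycounter, oracle_trailing_run(angles[, 2]))
    expect_equal(st$rcounter, oracle_trailing_run(angles[, 3]))
  }
})

test_that("head events distinguish fatigue from sight deviation", {
  mk <- function(p, y, r) {
    st <- head_state(); st$pcounter <- p; st$ycounter <- y; st$rcounter <- r
    st
  }
  expect_equal(classify_head_event(mk(70L, 0L, 0L))$code, 1L)
  expect_equal(classify_head_event(mk(0L, 70L, 0L))$code, 2L)
  expect_equal(classify_head_event(mk(0L, 0L, 70L))$code, 1L)
  expect_equal(classify_head_event(mk(60L, 60L, 60L))$code, 0L)
  both <- classify_head_event(mk(70L, 70L, 0L))
  expect_equal(both$code, 1L)  # fatigue takes precedence
  expect_true(both$fatigue)
  expect_true(both$sight_deviation)
})
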