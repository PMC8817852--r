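test_that("evaluate_record reproduces the bundled session-record alerts", {
  records <- example_session_records()
  expect_equal(nrow(records), 10L)
  for (i in seq_len(nrow(records))) {
    res <- evaluate_record(records[i, ])
    expect_equal(res$alert, records$alert[i] == "Y",
                 label = sprintf("record %d alert", i))
  }
  # spot-check the reasons on characteristic records
  expect_equal(evaluate_record(records[1, ])$reasons, "CLOSING_RATE")
  expect_equal(evaluate_record(records[2, ])$reasons, "DEEP_YAWN")
  expect_equal(evaluate_record(records[3, ])$reasons, "NO_FACE")
  expect_equal(evaluate_record(records[4, ])$reasons, "YAWN")
  expect_equal(evaluate_record(records[5, ])$reasons, "HEAD_YAW")
  expect_equal(evaluate_record(records[10, ])$reasons, "HEAD_ROLL")
})

test_that("evaluate_record validates its input", {
  expect_error(evaluate_record(list(eye_closing_rate = 0.1)), "face")
  expect_error(evaluate_record(list(face = 1, eye_closing_rate = 0.1)),
               "missing required field")
  # a faceless record needs nothing else
  expect_false(evaluate_record(list(face = 0))$alert)
})

test_that("alert clauses fire at their documented boundaries", {
  base <- list(face = 1, eye_closing_rate = 0.1, yawn = 0, deep_yawn = 0,
               yaw_frames = 0, pitch_frames = 0, roll_frames = 0)
  expect_false(evaluate_record(base)$alert)
  # closing rate is strictly greater-than
  at <- base; at$eye_closing_rate <- 0.20
  expect_false(evaluate_record(at)$alert)
  above <- base; above$eye_closing_rate <- 0.2001
  expect_true(evaluate_record(above)$alert)
  # head clause is strictly greater-than 120 frames
  h <- base; h$pitch_frames <- 120
  expect_false(evaluate_record(h)$alert)
  h$pitch_frames <- 121
  expect_true(evaluate_record(h)$alert)
  # one yawn is tolerated, two alert; one deep yawn alerts
  y <- base; y$yawn <- 1
  expect_false(evaluate_record(y)$alert)
  y$yawn <- 2
  expect_true(evaluate_record(y)$alert)
  d <- base; d$deep_yawn <- 1
  expect_true(evaluate_record(d)$alert)
})

test_that("raising any severity never withdraws an alert (monotonicity)", {
  set.seed(51)
  for (i in 1:50) {
    rec <- list(face = 1,
                eye_closing_rate = runif(1, 0, 0.4),
                yawn = sample(0:3, 1), deep_yawn = sample(0:2, 1),
                yaw_frames = sample(0:200, 1),
                pitch_frames = sample(0:200, 1),
                roll_frames = sample(0:200, 1))
    before <- evaluate_record(rec)$alert
    worse <- rec
    field <- sample(c("eye_closing_rate", "yawn", "deep_yawn", "yaw_frames",
                      "pitch_frames", "roll_frames"), 1)
    worse[[field]] <- worse[[field]] + if (field == "eye_closing_rate") 0.1 else 50L
    after <- evaluate_record(worse)$alert
    expect_true(!before || after)
  }
})

test_that("assess_window agrees with evaluate_record on the same aggregates", {
  script <- random_scenario(seed = 99, n_windows = 2L, window_seconds = 12)
  cfg <- assess_config(fps = 25, window_seconds = 12)
  res <- render_stream(script, config = cfg)
  out <- run_pipeline(res$stream, cfg)
  for (i in seq_len(nrow(out$windows))) {
    w <- out$windows[i, ]
    rec <- list(face = as.integer(w$face_coverage > 0),
                eye_closing_rate = w$eye_closing_rate,
                yawn = w$yawn_count, deep_yawn = w$deep_yawn_count,
                yaw_frames = w$yaw_frames, pitch_frames = w$pitch_frames,
                roll_frames = w$roll_frames)
    res2 <- evaluate_record(rec, cfg)
    expect_equal(w$alert, res2$alert)
    expect_equal(w$reasons, paste(res2$reasons, collapse = ";"))
  }
})

test_that("a faceless window yields NO_FACE and no alert", {
  script <- scenario_script(
    fps = 25, duration = 4,
    events = list(scenario_event("no_face", start = 0, duration = 4)))
  cfg <- assess_config(fps = 25, window_seconds = 4)
  res <- render_stream(script, config = cfg)
  out <- run_pipeline(res$stream, cfg)
  expect_equal(nrow(out$windows), 1L)
  expect_false(out$windows$alert)
  expect_equal(out$windows$reasons, "NO_FACE")
  expect_equal(out$windows$face_coverage, 0)
  expect_error(assess_window(out$frames[0, ], cfg), "empty window")
})

test_that("episodes spanning a window boundary keep their global counter", {
  # 60 open-mouth frames straddling the boundary between 100-frame windows:
  # classified as one deep yawn, attributed to the window where it ends
  script <- scenario_script(
    fps = 25, duration = 8,
    events = list(scenario_event("yawn", start = 70 / 25, frames = 60)))
  cfg <- assess_config(fps = 25, window_seconds = 4)
  res <- render_stream(script, config = cfg)
  out <- run_pipeline(res$stream, cfg)
  expect_equal(nrow(out$episodes), 1L)
  expect_equal(out$episodes$counter, 60L)
  expect_equal(out$episodes$yawn_class, 2L)
  expect_equal(out$episodes$window, 1L)
  expect_equal(out$windows$deep_yawn_count, c(0L, 1L))
  expect_true(out$windows$alert[2])
  expect_false(out$windows$alert[1])
})

test_that("the pipeline is deterministic and alerts match scripted causes", {
  script <- scenario_script(
    fps = 25, duration = 12,
    events = list(
      scenario_event("blink", start = 1, frames = 6),
      scenario_event("yawn", start = 4, frames = 40),
      scenario_event("yawn", start = 7, frames = 30)),
    seed = 5)
  cfg <- assess_config(fps = 25, window_seconds = 12)
  out1 <- run_pipeline(render_stream(script, config = cfg)$stream, cfg)
  out2 <- run_pipeline(render_stream(script, config = cfg)$stream, cfg)
  expect_identical(out1$windows, out2$windows)
  expect_equal(out1$windows$yawn_count, 2L)
  expect_equal(out1$windows$blink_count, 1L)
  expect_true(out1$windows$alert)
  expect_match(out1$windows$reasons, "YAWN")
})

test_that("window reports round trip through CSV", {
  script <- scenario_script(
    fps = 25, duration = 4,
    events = list(scenario_event("blink", start = 1, frames = 6)))
  cfg <- assess_config(fps = 25, window_seconds = 4)
  out <- run_pipeline(render_stream(script, config = cfg)$stream, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(out$windows, path)
  back <- utils::read.csv(path)
  expect_equal(back$eye_closing_rate, out$windows$eye_closing_rate)
  expect_equal(back$alert, out$windows$alert)
})
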