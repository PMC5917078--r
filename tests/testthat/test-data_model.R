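test_that("posture series round-trips losslessly through CSV", {
  s <- make_series(list("sitting", 10), list("standing", 2),
                   list("stepping", 3, 15L), list("not_worn", 5),
                   list("lying", 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_posture_series(s, path)
  back <- read_posture_series(path, patient_id = "T1",
                              discharge_date = attr(s, "discharge_date"))
  expect_equal(back$timestamp, s$timestamp)
  expect_equal(back$posture, s$posture)
  expect_equal(back$steps, s$steps)
  expect_equal(back$device_status, s$device_status)
})

test_that("grid gaps are filled with not-worn epochs without touching input rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,posture,steps,device_status",
               "2016-03-10T09:00:00,sitting,0,worn",
               "2016-03-10T09:01:00,sitting,0,worn",
               "2016-03-10T09:07:00,standing,0,worn"), path)
  s <- read_posture_series(path)
  expect_equal(nrow(s), 8)
  gap <- s[s$timestamp > ts_at("09:01") & s$timestamp < ts_at("09:07"), ]
  expect_equal(nrow(gap), 5)
  expect_true(all(gap$device_status == "not_worn"))
  expect_true(all(is.na(gap$posture)))
  kept <- s[s$timestamp <= ts_at("09:01") | s$timestamp >= ts_at("09:07"), ]
  expect_equal(kept$posture, c("sitting", "sitting", "standing"))
})

test_that("malformed rows raise parse errors naming the line", {
  write_rows <- function(...) {
    p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    writeLines(c("timestamp,posture,steps,device_status", ...), p)
    p
  }
  expect_error(read_posture_series(write_rows("not-a-time,sitting,0,worn")),
               "line 2.*malformed timestamp")
  expect_error(read_posture_series(write_rows(
    "2016-03-10T09:00:00,sitting,0,worn",
    "2016-03-10T09:01:00,slouching,0,worn")), "line 3.*posture")
  expect_error(read_posture_series(write_rows(
    "2016-03-10T09:01:00,sitting,0,worn",
    "2016-03-10T09:00:00,sitting,0,worn")), "line 3.*monotone")
  expect_error(read_posture_series(write_rows(
    "2016-03-10T09:00:00,sitting,4,worn")), "line 2.*steps")
})

test_that("event tables round-trip and reject non-scalar fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  prompts <- data.frame(timestamp = ts_at("09:30") + (0:9) * 1800,
                        interval = 30, day_index = 1L)
  write_events(prompts, path)
  expect_equal(read_events(path)$timestamp, prompts$timestamp)
  expect_equal(read_events(path)$day_index, prompts$day_index)

  write_events(prompts[0, ], path)
  expect_equal(nrow(read_events(path)), 0)
  expect_equal(names(read_events(path)), names(prompts))

  bad <- data.frame(x = 1:2)
  bad$y <- list(1, "a")
  expect_error(write_events(bad, path), "mixed-type")
})

test_that("series constructor enforces the epoch invariants", {
  ts <- ts_at("09:00") + (0:4) * 60
  expect_error(posture_series(ts, rep("sitting", 5), c(0, 0, 3, 0, 0),
                              rep("worn", 5)), "non-stepping")
  expect_error(posture_series(ts, c("sitting", NA, "sitting", "sitting", "sitting"),
                              0L, rep("worn", 5)), "missing posture")
  expect_error(posture_series(ts[c(1, 2, 4, 5, 3)], rep("sitting", 5), 0L,
                              rep("worn", 5)), "grid")
})

test_that("manifest and flow-log readers validate their invariants", {
  mpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,group,prompt_interval,discharge_date",
               "P1,education_feedback,30,2016-03-01",
               "P2,control,,2016-03-02"), mpath)
  m <- read_manifest(mpath)
  expect_equal(m$prompt_interval, c(30, NA))
  writeLines(c("patient_id,group,prompt_interval,discharge_date",
               "P1,control,30,2016-03-01"), mpath)
  expect_error(read_manifest(mpath), "non-feedback")

  log <- make_flow_log(10, 8, 6, 4, 4, 2)
  expect_silent(validate_flow_log(log))
  log$consented[10] <- TRUE  # consented but never approached
  expect_error(flow_metrics(log), "S010")
})

test_that("sit-to-stand transitions are counted over worn posture changes", {
  s <- make_series(list("sitting", 5), list("standing", 2), list("sitting", 3),
                   list("stepping", 1, 10L), list("not_worn", 3),
                   list("standing", 2))
  expect_equal(count_transitions(s), 2L)
})
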