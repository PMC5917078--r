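test_that("the same seed reproduces the cohort exactly", {
  cfg <- synthetic_config(n_patients = 2, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$counts, b$counts)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- generate_cohort(synthetic_config(n_patients = 2, seed = 124))
  expect_false(identical(a$ground_truth$prompts, c2$ground_truth$prompts))
})

test_that("zero response probability yields zero responded prompts", {
  co <- generate_cohort(synthetic_config(n_patients = 2, seed = 5, p_respond = 0))
  expect_gt(nrow(co$ground_truth$prompts), 0)
  expect_false(any(co$ground_truth$prompts$responded))
})

test_that("a 12-patient cohort reproduces the 6/1/5 setting split", {
  co <- generate_cohort(synthetic_config(n_patients = 12, seed = 9))
  expect_equal(as.vector(table(factor(co$manifest$prompt_interval,
                                      levels = c(30, 45, 60)))),
               c(6L, 1L, 5L))
  expect_true(all(co$manifest$group == "education_feedback"))
})

test_that("generated series satisfy the container invariants", {
  co <- generate_cohort(synthetic_config(n_patients = 2, seed = 17))
  for (s in co$series) {
    expect_equal(nrow(s), 14 * 1440)
    expect_true(all(diff(as.numeric(s$timestamp)) == 60))
    expect_true(all(is.na(s$posture) | s$posture %in% POSTURES))
    expect_true(all(s$steps == 0 | s$posture == "stepping"))
    expect_true(all(!is.na(s$posture[s$device_status == "worn"])))
  }
})

test_that("detected prompts equal the ground-truth prompt list", {
  for (seed in c(2, 31, 77)) {
    co <- generate_cohort(synthetic_config(n_patients = 2, seed = seed))
    for (pid in co$manifest$patient_id) {
      det <- detect_prompts(
        co$series[[pid]],
        co$manifest$prompt_interval[co$manifest$patient_id == pid])
      gt <- co$ground_truth$prompts
      expect_identical(det$timestamp, gt$prompt_time[gt$patient_id == pid],
                       info = sprintf("seed %d patient %s", seed, pid))
    }
  }
})

test_that("ground-truth responses respect the latency support", {
  co <- generate_cohort(synthetic_config(n_patients = 3, seed = 41))
  gt <- co$ground_truth$prompts
  resp <- gt[gt$responded, ]
  expect_true(all(resp$latency_min >= 1 & resp$latency_min <= 15))
  expect_true(all(resp$stand_min + resp$walk_min >= 1))
  expect_true(all(resp$steps[resp$walk_min == 0] == 0))
})

test_that("counts map postures onto the count scale by construction", {
  cfg <- synthetic_config(seed = 1)
  s <- make_series(list("sitting", 60), list("standing", 10),
                   list("stepping", 10, 15L), list("not_worn", 30),
                   list("off", 10))
  set.seed(2)
  cts <- generate_counts(s, cfg)
  sed <- s$device_status == "worn" & s$posture %in% c("sitting", "lying", "standing")
  expect_true(all(cts$counts[sed] < 100))
  expect_true(all(cts$counts[s$posture == "stepping" & !is.na(s$posture)] >=
                    cfg$ambulation_cut))
  expect_true(all(cts$counts[s$device_status != "worn"] == 0))
  expect_equal(cts$steps, s$steps)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(sedentary_fraction = 0), "infeasible")
  expect_error(synthetic_config(p_respond = 1.2), "probabilities")
  expect_error(synthetic_config(prompt_interval_mix = c("30" = 0.5, "45" = 0.6, "60" = -0.1)),
               "non-negative proportions")
  expect_error(synthetic_config(prompt_interval_mix = c("30" = 0.5, "45" = 0.2, "60" = 0.2)),
               "sum to 1")
  expect_error(synthetic_config(battery_life_days = 0), "battery")
})

test_that("battery depletion and manual power-off appear in the day log", {
  co <- generate_cohort(synthetic_config(n_patients = 6, seed = 13,
                                         p_charge_nightly = 0.2,
                                         p_manual_off_day = 0.3))
  days <- co$ground_truth$days
  expect_gt(sum(days$battery_dead), 0)
  expect_gt(sum(days$manual_off), 0)
  # manual-off days with no charge block have no worn epochs and attribute off
  for (pid in unique(days$patient_id)[1:2]) {
    att <- attribute_missing(co$series[[pid]])
    off_days <- days$day_index[days$patient_id == pid & days$manual_off]
    if (length(off_days))
      expect_true(all(att$attribution[att$day_index %in% off_days] %in%
                        c("switched_off", "not_worn")))
  }
})

test_that("the worked-example day thins under a longer interval", {
  fx <- build_figure1_fixture()
  p30 <- detect_prompts(fx$series, 30)
  p60 <- detect_prompts(fx$series, 60)
  expect_equal(nrow(p30), 9)
  expect_lt(nrow(p60), nrow(p30))
})
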