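test_that("a prompt followed by unbroken sitting is a non-response", {
  s <- make_series(list("sitting", 30), list("sitting", 20))
  pr <- detect_prompts(s, 30)
  cls <- classify_response(s, pr[1, ])
  expect_false(cls$responded)
  expect_true(is.na(cls$latency_min))
  expect_false(cls$within_5min)
  expect_equal(cls$stand_min + cls$walk_min, 0)
})

test_that("movement within the window sets latency and 5-min magnitudes", {
  # prompt at 09:30; sitting 1 min; standing 2 min; stepping 1 min (20 steps)
  s <- make_series(list("sitting", 31), list("standing", 2),
                   list("stepping", 1, 20L), list("sitting", 15))
  pr <- detect_prompts(s, 30)
  cls <- classify_response(s, pr[1, ])
  expect_true(cls$responded)
  expect_equal(cls$latency_min, 2)  # first movement epoch completes 2 min after prompt
  expect_true(cls$within_5min)
  expect_equal(cls$stand_min, 2)
  expect_equal(cls$walk_min, 1)
  expect_equal(cls$steps, 20L)
})

test_that("movement after 5 minutes responds without the within-5 flag", {
  s <- make_series(list("sitting", 30), list("sitting", 7),
                   list("standing", 2), list("sitting", 10))
  pr <- detect_prompts(s, 30)
  cls <- classify_response(s, pr[1, ])
  expect_true(cls$responded)
  expect_equal(cls$latency_min, 8)
  expect_false(cls$within_5min)
  expect_equal(cls$stand_min, 0)  # outside the 5-min magnitude frame
})

test_that("windows are truncated at the next prompt and at non-wear", {
  # 10-min interval: consecutive prompts cut each other's 15-min windows
  s <- make_series(list("sitting", 20), list("standing", 2))
  pr <- detect_prompts(s, 10)
  cls <- classify_responses(s, pr)
  expect_equal(nrow(pr), 2)
  expect_true(cls$window_truncated[1])
  expect_false(cls$responded[1])   # movement lies beyond the second prompt
  expect_true(cls$responded[2])

  s <- make_series(list("sitting", 30), list("not_worn", 15))
  cls <- classify_response(s, detect_prompts(s, 30)[1, ])
  expect_false(cls$responded)
  expect_true(cls$window_truncated)
  expect_equal(cls$window_worn_min, 0)

  expect_error(classify_response(s, ts_at("23:00")), "outside the series span")
})

test_that("truncating the window can only remove responses, never add them", {
  set.seed(11)
  for (i in 1:30) {
    s <- random_series()
    pr <- detect_prompts(s, 15)
    if (!nrow(pr)) next
    full <- classify_responses(s, pr, response_window = 15)
    short <- classify_responses(s, pr, response_window = 5)
    expect_true(all(full$responded[short$responded]))
  }
})

test_that("prompt summary reproduces the trial's response-rate arithmetic", {
  n <- 325; n_resp <- 106
  cls <- data.frame(responded = rep(c(TRUE, FALSE), c(n_resp, n - n_resp)),
                    within_5min = rep(c(TRUE, FALSE), c(43, n - 43)),
                    stand_min = 1.5, walk_min = 0.5, steps = 21L,
                    window_worn_min = 15, day_index = rep(1:14, length.out = n))
  sm <- summarize_prompts(cls, n_days_observed = 98)
  expect_equal(sm$response_rate_pct, 32.62)
  expect_equal(sm$pct_nonresponse, 67.38)
  expect_equal(sm$n_prompts, 325)
  expect_equal(sm$prompts_per_day, 325 / 98)
  # partition: non-responses + within-5 + later responses add to the total
  expect_equal((sm$n_prompts - sm$n_responded) +
                 sm$n_within5 + (sm$n_responded - sm$n_within5), sm$n_prompts)
})

test_that("empty classifications summarise to zero prompts with NA rates", {
  cls <- data.frame(responded = logical(), within_5min = logical(),
                    stand_min = numeric(), walk_min = numeric(),
                    steps = integer(), window_worn_min = numeric(),
                    day_index = integer())
  sm <- summarize_prompts(cls, 14)
  expect_equal(sm$n_prompts, 0)
  expect_true(is.na(sm$response_rate_pct))
  expect_true(is.na(sm$mean_stand_min))
  expect_error(summarize_prompts(cls, 0), "positive")
})

test_that("summary is invariant to prompt ordering", {
  set.seed(3)
  cls <- data.frame(responded = sample(c(TRUE, FALSE), 60, TRUE),
                    stand_min = runif(60, 0, 3), walk_min = runif(60, 0, 1),
                    steps = rpois(60, 20), window_worn_min = 15,
                    day_index = sample(1:14, 60, TRUE))
  cls$within_5min <- cls$responded & runif(60) < 0.5
  a <- summarize_prompts(cls, 14)
  b <- summarize_prompts(cls[sample(60), ], 14)
  expect_equal(a[names(a) != "call"], b[names(b) != "call"])
})

test_that("stratification by setting scales prompts/day with the interval", {
  # identical sedentary profiles: 4 h unbroken sitting per day, two patients
  mk <- function(pid) make_series(list("sitting", 240), patient_id = pid)
  s30 <- mk("A"); s60 <- mk("B")
  manifest <- data.frame(patient_id = c("A", "B"), group = "education_feedback",
                         prompt_interval = c(30, 60))
  cls <- rbind(
    cbind(patient_id = "A", classify_responses(s30, detect_prompts(s30, 30))),
    cbind(patient_id = "B", classify_responses(s60, detect_prompts(s60, 60))))
  tab <- stratify_by_setting(cls, manifest, c(A = 1, B = 1))
  expect_equal(tab$prompts_per_day[tab$interval == 30],
               2 * tab$prompts_per_day[tab$interval == 60])
  expect_equal(tab$n_prompts, c(8L, 4L))

  single <- stratify_by_setting(cls[cls$patient_id == "A", ],
                                manifest, c(A = 1))
  expect_equal(nrow(single), 1)
  empty <- stratify_by_setting(cls[0, ], manifest, numeric())
  expect_equal(nrow(empty), 0)
  expect_error(stratify_by_setting(cls, manifest[1, ], c(A = 1, B = 1)),
               "not in manifest")
})

test_that("non-wear-window prompts can be excluded from the denominator", {
  cls <- data.frame(responded = c(TRUE, FALSE, FALSE),
                    within_5min = c(TRUE, FALSE, FALSE),
                    stand_min = c(2, 0, 0), walk_min = c(1, 0, 0),
                    steps = c(20L, 0L, 0L),
                    window_worn_min = c(15, 15, 0), day_index = c(1, 1, 2))
  inc <- summarize_prompts(cls, 14, nonwear_windows = "include")
  exc <- summarize_prompts(cls, 14, nonwear_windows = "exclude")
  expect_equal(inc$n_prompts, 3)
  expect_equal(exc$n_prompts, 2)
  expect_equal(exc$response_rate_pct, 50)
})
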