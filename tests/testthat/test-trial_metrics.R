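test_that("flow percentages reproduce the trial's funnel arithmetic", {
  log <- make_flow_log(screened = 300, eligible = 212, approached = 111,
                       consented = 35, enrolled = 33, completed = 17,
                       groups = c("control", "education", "education_feedback"))
  fm <- flow_metrics(log)
  expect_equal(fm$pct_eligible, 70.7)
  expect_equal(fm$pct_approached, 52.4)
  expect_equal(fm$pct_uptake, 31.5)
  expect_equal(fm$pct_retention, 51.5)
  expect_equal(fm$n_enrolled, 33)
  expect_equal(sum(fm$completed_by_group), 17)
})

test_that("flow percentages handle empty denominators and scale invariance", {
  none <- make_flow_log(10, 5, 0, 0, 0, 0)
  fm <- flow_metrics(none)
  expect_true(is.na(fm$pct_uptake))
  expect_equal(fm$pct_eligible, 50)

  base <- make_flow_log(40, 20, 10, 8, 8, 4)
  tripled <- make_flow_log(120, 60, 30, 24, 24, 12)
  a <- flow_metrics(base); b <- flow_metrics(tripled)
  for (f in c("pct_eligible", "pct_approached", "pct_uptake", "pct_retention"))
    expect_equal(a[[f]], b[[f]], info = f)
})

test_that("test selection follows the small-cell rule", {
  even <- matrix(c(10, 10, 10, 10), 2)
  res <- select_categorical_test(even)
  expect_equal(res$test, "chi_square")
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)

  small <- matrix(c(2, 7, 8, 3), 2)
  expect_equal(select_categorical_test(small)$test, "fisher_exact")
  # expected-count mode can differ from observed-count mode
  tab <- matrix(c(5, 5, 5, 1), 2)
  expect_equal(select_categorical_test(tab, rule = "observed")$test, "fisher_exact")
  expect_error(select_categorical_test(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Fisher p matches exhaustive hypergeometric enumeration", {
  tab <- matrix(c(1, 9, 9, 1), 2)
  res <- select_categorical_test(tab)
  expect_equal(res$test, "fisher_exact")
  expect_equal(res$p_value, fisher_p_enum(tab), tolerance = 1e-10)
})

test_that("group comparison uses t for two groups with the F = t^2 identity", {
  same <- c(1, 2, 3, 4); g2 <- rep(c("a", "b"), each = 4)
  res <- compare_groups(c(same, same), g2)
  expect_equal(res$test, "t_test")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(21)
  x <- c(rnorm(12, 0), rnorm(12, 1.5))
  tt <- compare_groups(x, g2 <- rep(c("a", "b"), each = 12))
  ft <- stats::oneway.test(x ~ factor(g2), var.equal = TRUE)
  expect_equal(unname(ft$statistic), tt$statistic^2, tolerance = 1e-10)
  expect_equal(ft$p.value, tt$p_value, tolerance = 1e-10)

  y <- c(rnorm(10, 0), rnorm(10, 2), rnorm(10, 4))
  res3 <- compare_groups(y, rep(letters[1:3], each = 10))
  expect_equal(res3$test, "anova")
  expect_lt(res3$p_value, 0.05)
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), "insufficient")
})

test_that("shifted normals are detected with high power at large n", {
  set.seed(31)
  hits <- 0
  for (i in 1:40) {
    x <- c(rnorm(60, 0), rnorm(60, 0.8))
    if (compare_groups(x, rep(1:2, each = 60))$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 40, 0.9)
})

test_that("descriptor bands follow the instrument thresholds", {
  expect_equal(as.character(hads_band(c(0, 7, 8, 10, 11, 21))),
               c("normal", "normal", "borderline", "borderline",
                 "abnormal", "abnormal"))
  expect_true(fatigue_severe(29))
  expect_false(fatigue_severe(30))
  expect_true(sppb_limited(9))
  expect_false(sppb_limited(10))
  expect_equal(as.character(bmi_class(c(18.4, 18.5, 24.9, 25, 30, 30.1))),
               c("underweight", "normal", "normal", "overweight",
                 "overweight", "obese"))
  expect_error(hads_band(22), "out of range")
  expect_error(fatigue_severe(-1), "out of range")
  expect_error(sppb_limited(13), "out of range")

  d <- classify_descriptors(hads_anxiety = 11, fatigue = 25, sppb = 9, bmi = 27)
  expect_equal(as.character(d$hads_anxiety), "abnormal")
  expect_true(d$fatigue_severe)
  expect_true(d$sppb_limited)
  expect_equal(as.character(d$bmi_class), "overweight")
})

test_that("band classification is total over each instrument's range", {
  expect_false(anyNA(hads_band(0:21)))
  expect_false(anyNA(bmi_class(seq(10, 60, by = 0.1))))
  expect_false(anyNA(fatigue_severe(0:52)))
  expect_false(anyNA(sppb_limited(0:12)))
})
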