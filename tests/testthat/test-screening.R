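# Threshold classification, confusion metrics, summary statistics.

test_that("classify applies the strict 30 mm rule", {
  expect_equal(classify(31.9), "AAA")
  expect_equal(classify(29.0), "control")
  expect_equal(classify(30.0), "control") # strictly greater than
  expect_equal(classify(45, threshold_mm = 45), "control")
  expect_equal(classify(45.01, threshold_mm = 45), "AAA")
  expect_error(classify(-1), "diameter")
})

test_that("classify is monotone in the diameter", {
  set.seed(6)
  d <- sort(runif(50, 0, 60))
  cls <- classify(d)
  aaa_started <- FALSE
  for (c2 in cls) {
    if (c2 == "AAA") aaa_started <- TRUE
    if (aaa_started) expect_equal(c2, "AAA")
  }
})

test_that("cohort_metrics reproduces the worked screening example", {
  predicted <- c(rep("AAA", 47), "control", rep("control", 24), "AAA")
  truth <- c(rep("AAA", 48), rep("control", 25))
  m <- cohort_metrics(predicted, truth)
  expect_equal(m$tp, 47); expect_equal(m$fn, 1)
  expect_equal(m$tn, 24); expect_equal(m$fp, 1)
  expect_equal(m$accuracy, 97)
  expect_equal(m$sensitivity, 98)
  expect_equal(m$specificity, 96)
  # invariance to case ordering
  perm <- sample(length(truth))
  m2 <- cohort_metrics(predicted[perm], truth[perm])
  expect_equal(m2[c("tp", "fp", "tn", "fn")], m[c("tp", "fp", "tn", "fn")])
})

test_that("cohort_metrics handles perfect, inverted and degenerate inputs", {
  p <- c("AAA", "AAA", "control")
  m <- cohort_metrics(p, p)
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(100, 100, 100))
  inv <- ifelse(p == "AAA", "control", "AAA")
  mi <- cohort_metrics(inv, p)
  expect_equal(mi$sensitivity, 0)
  expect_equal(mi$specificity, 0)
  # zero denominator -> NA, not 0
  mz <- cohort_metrics(c("AAA", "AAA"), c("AAA", "AAA"))
  expect_true(is.na(mz$specificity))
  expect_error(cohort_metrics("AAA", c("AAA", "AAA")), "length")
  expect_error(cohort_metrics("AAA", "bad"), "classes")
})

test_that("summarize_values matches closed-form statistics", {
  s <- summarize_values(c(10, 10, 10))
  expect_equal(s$mean, 10); expect_equal(s$sd, 0); expect_equal(s$iqr, 0)
  s2 <- summarize_values(1:100)
  expect_equal(s2$median, 50.5)
  expect_equal(s2$iqr, 49.5) # linear-interpolation percentiles
  expect_equal(s2$p5, quantile(1:100, 0.05, names = FALSE))
  # permutation invariance
  set.seed(7)
  x <- rnorm(31)
  expect_equal(summarize_values(x), summarize_values(sample(x)))
  expect_error(summarize_values(numeric(0)), "non-empty")
})

test_that("error_stats summarizes absolute errors per class", {
  es <- error_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(es$overall$mean, 0)
  es2 <- error_stats(c(3, 4, 5), c(1, 2, 3))
  expect_equal(es2$overall$mean, 2); expect_equal(es2$overall$sd, 0)
  # stratified equals unstratified when all cases share a class
  es3 <- error_stats(c(3, 4, 5), c(1, 2, 3), truth = rep("AAA", 3))
  expect_equal(es3$AAA, es3$overall)
  expect_error(error_stats(1:3, 1:2), "length")
})

test_that("bland_altman_table computes per-case mean and difference", {
  rep <- list(cases = data.frame(case_id = c("a", "b"),
                                 predicted_diameter_mm = c(32, 20),
                                 manual_diameter_mm = c(30, 22)))
  ba <- bland_altman_table(rep)
  expect_equal(ba$mean_mm, c(31, 21))
  expect_equal(ba$diff_mm, c(2, -2))
})

test_that("screen_config validates and collects defaults", {
  cfg <- screen_config()
  expect_equal(cfg$threshold_mm, 30)
  expect_equal(cfg$resampling_step_mm, 2.5)
  expect_equal(cfg$smooth_factor, 0.5)
  expect_error(screen_config(threshold_mm = -1), "threshold")
})
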