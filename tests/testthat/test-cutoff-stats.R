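test_that("the Youden index reproduces the reported operating points", {
  expect_equal(youdenIndex(0.94, 0.87), 0.81)
  expect_equal(youdenIndex(0.97, 1.00), 0.97)
  expect_equal(youdenIndex(1, 1), 1)
  expect_error(youdenIndex(1.2, 0.5), "sensitivity")
  expect_error(youdenIndex(0.5, -0.1), "specificity")
})

test_that("separated classes yield the midpoint threshold with J = 1", {
  res <- optimalCutoff(c(40, 50, 60, 80, 90, 100),
                       rep(c("ischemic", "well"), each = 3))
  expect_equal(threshold(res), 70)
  expect_equal(sensitivity(res), 1)
  expect_equal(specificity(res), 1)
  expect_equal(youdenJ(res), 1)
})

test_that("ties on J break toward the smallest threshold", {
  res <- optimalCutoff(c(50, 60, 80, 70, 90, 100),
                       rep(c("ischemic", "well"), each = 3))
  expect_equal(threshold(res), 65)
  expect_equal(youdenJ(res), 2 / 3, tolerance = 1e-12)
})

test_that("above-positive direction mirrors the inequalities", {
  res <- optimalCutoff(c(2, 2, 2, 8, 8, 8),
                       rep(c("well", "ischemic"), each = 3),
                       direction = "above_positive")
  expect_equal(threshold(res), 5)
  expect_equal(sensitivity(res), 1)
  expect_equal(specificity(res), 1)
})

test_that("degenerate label sets are usage errors", {
  expect_error(optimalCutoff(1:4, rep("ischemic", 4)), "both classes")
  expect_error(optimalCutoff(c(2, 2), c("ischemic", "well")),
               "distinct")
})

test_that("optimal cut-off equals the exhaustive scan on random data", {
  set.seed(123)
  for (rep in 1:40) {
    n <- sample(4:30, 1)
    values <- sample(0:40, n, replace = TRUE)
    labels <- sample(c("ischemic", "well"), n, replace = TRUE)
    if (length(unique(labels)) < 2 || length(unique(values)) < 2) next
    for (dir in c("below_positive", "above_positive")) {
      res <- optimalCutoff(values, labels, dir)
      ref <- bruteCutoff(values, labels, dir)
      expect_equal(threshold(res), ref$threshold, info = dir)
      expect_equal(youdenJ(res), ref$j, tolerance = 1e-12)
      ## the returned J dominates every candidate on the ROC
      roc <- rocPoints(res)
      expect_true(all(youdenJ(res) >=
                        roc$sensitivity + roc$specificity - 1 - 1e-12))
    }
  }
})

test_that("ROC sensitivity rises and specificity falls with threshold", {
  set.seed(9)
  values <- c(rnorm(40, 50, 12), rnorm(40, 90, 15))
  labels <- rep(c("ischemic", "well"), each = 40)
  roc <- rocPoints(optimalCutoff(values, labels, "below_positive"))
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$specificity) <= 0))
})

test_that("classification honors the strict-below rule at the cut-off", {
  expect_equal(classifyTissue(68, 69), "ischemic")
  expect_equal(classifyTissue(69, 69), "well")   # boundary -> well
  expect_equal(classifyTissue(c(70, 100), 69), c("well", "well"))
  expect_equal(classifyTissue(4.0, 3.8, "above_positive"), "ischemic")
  expect_equal(classifyTissue(3.8, 3.8, "above_positive"), "well")
})

test_that("logarithmic estimation recovers exact fits", {
  x <- c(1, 2, 4, 8)
  fit <- logCurveFit(x, log(x))
  expect_equal(fit@b0, 0, tolerance = 1e-12)
  expect_equal(fit@b1, 1, tolerance = 1e-12)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  fit2 <- logCurveFit(c(1, exp(1), exp(2)), c(2, 3, 4))
  expect_equal(fit2@b0, 2, tolerance = 1e-10)
  expect_equal(fit2@b1, 1, tolerance = 1e-10)
  expect_equal(fit2@rSquared, 1)
})

test_that("degenerate and invalid inputs are flagged", {
  expect_warning(fit <- logCurveFit(c(1, 2, 4), c(3, 3, 3)),
                 "zero-variance")
  expect_equal(fit@b1, 0)
  expect_true(is.na(fit@rSquared))
  expect_true(fit@degenerate)
  expect_error(logCurveFit(c(-1, 2, 3), 1:3), "x > 0")
  expect_error(logCurveFit(1:2, 1:2), "3")
})
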