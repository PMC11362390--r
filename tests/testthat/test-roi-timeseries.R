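mkMap <- function(val, n = 80) {
  new("PerfusionMap", lspu = matrix(val, n, n),
      validMask = matrix(TRUE, n, n),
      mapping = list(form = "inverse_square", cap = 1e6))
}
roi1 <-data.frame(roi_id = "r1", zone = "well", row = 5, col = 5,
                   height = 60, width = 60, stringsAsFactors = FALSE)

test_that("middle-frame selection follows floor((N - n)/2)", {
  expect_equal(middleFrameIndices(96, 96), 1:96)
  expect_equal(middleFrameIndices(100, 96), 3:98)   # starts at frame 3
  expect_equal(middleFrameIndices(97, 96), 1:96)    # odd surplus: earlier
  expect_error(selectMiddleFrames(as.list(1:90), 96, id = "rec7"),
               "rec7")
})

test_that("frame selection is deterministic and order-preserving", {
  x <- as.list(101:200)
  s1 <- selectMiddleFrames(x, 96)
  s2 <- selectMiddleFrames(x, 96)
  expect_identical(s1, s2)
  expect_equal(unlist(s1), 103:198)
  ph <- uniformPhantom(48, 1)
  st <- generateSpeckleStack(ph, nFrames = 5, seed = 1)
  sub <- selectMiddleFrames(st, 3)
  expect_equal(frames(sub), frames(st)[, , 2:4, drop = FALSE])
})

test_that("ROI means of constant maps are exact", {
  rs <- roiSeries(list(mkMap(70), mkMap(70)), roi1,
                  loopId = "L1", timepoint = "T60")
  expect_equal(rs$summary$mean, 70)
  expect_equal(rs$summary$sd, 0)
  expect_equal(rs$summary$n_frames, 2)
  expect_equal(rs$perFrame$mean, c(70, 70))
  expect_equal(rs$perFrame$timepoint, c("T60", "T60"))
})

test_that("summary SD is the sample SD across frame means", {
  rs <- roiSeries(list(mkMap(60), mkMap(80)), roi1)
  expect_equal(rs$summary$mean, 70)
  expect_equal(rs$summary$sd, sd(c(60, 80)))
  expect_equal(rs$summary$sd, 14.142, tolerance = 1e-4)
})

test_that("frame exclusion lists drop the named frames", {
  rs <- roiSeries(list(mkMap(60), mkMap(999), mkMap(80)), roi1,
                  excludeFrames = 2L)
  expect_equal(rs$summary$mean, 70)
  expect_equal(rs$perFrame$frame, c(1L, 3L))
})

test_that("ROIs overrunning the valid region are data errors", {
  bad <- data.frame(roi_id = "r2", zone = "well", row = 30, col = 30,
                    height = 60, width = 60)
  expect_error(roiSeries(list(mkMap(70)), bad), "fit inside")
  ## ROI covering masked pixels
  m <- mkMap(70)
  m@validMask[10, 10] <- FALSE
  m@lspu[10, 10] <- NA
  expect_error(roiSeries(list(m), roi1), "invalid")
})

test_that("normality-driven test choice picks t or Mann-Whitney", {
  set.seed(31)
  a <- rnorm(50); b <- rnorm(50, 3)
  res <- compareGroups(a, b)
  expect_equal(res@testUsed, "t")
  expect_lt(res@pValue, 0.001)
  skewA <- exp(rnorm(40)); skewB <- exp(rnorm(40, 1.5))
  res2 <- compareGroups(skewA, skewB)
  expect_equal(res2@testUsed, "mann_whitney")
  expect_lt(res2@pValue, 0.001)
})

test_that("identical samples give U = n^2/2 and p near 1", {
  res <- compareGroups(1:5, 1:5, test = "mann_whitney")
  expect_equal(res@statistic, 12.5)
  expect_gt(res@pValue, 0.99)
})

test_that("degenerate equal-constant groups return p = 1 with warning", {
  expect_warning(res <- compareGroups(rep(5, 6), rep(5, 6)),
                 "constant")
  expect_equal(res@pValue, 1)
  expect_equal(res@testUsed, "degenerate")
})

test_that("the Mann-Whitney statistic equals brute-force pair counting", {
  set.seed(77)
  for (rep in 1:20) {
    a <- sample(0:6, sample(3:6, 1), replace = TRUE)
    b <- sample(0:6, sample(3:6, 1), replace = TRUE)
    if (sd(a) == 0 && sd(b) == 0 && a[1] == b[1]) next
    res <- compareGroups(a, b, test = "mann_whitney")
    expect_equal(res@statistic, bruteU(a, b))
  }
})

test_that("undersized groups are rejected", {
  expect_error(compareGroups(1:2, 1:5), "at least 3")
})
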