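test_that("the default lactate schedule books 167 records", {
  expect_equal(designRecordCount(studyDesign()), 167L)
})

test_that("alternative schedules count analytically", {
  rois <- c("well", "watershed_left", "watershed_right", "ischemic")
  full <- expand.grid(timepoint = c("T0", "T60", "T120"), zone = rois,
                      stringsAsFactors = FALSE)
  full$n_loops <- 18L
  expect_equal(designRecordCount(studyDesign(lactateSchedule = full)),
               216L)
  one <- data.frame(timepoint = "T60", zone = rois, n_loops = 1L)
  expect_equal(designRecordCount(
    studyDesign(loopsPerAnimal = 1L, lactateSchedule = one)), 4L)
})

test_that("inconsistent schedules are configuration errors", {
  bad <- data.frame(timepoint = "T99", zone = "well", n_loops = 3L)
  expect_error(studyDesign(lactateSchedule = bad), "timepoints")
  bad2 <- data.frame(timepoint = "T60", zone = "well", n_loops = 99L)
  expect_error(studyDesign(lactateSchedule = bad2), "n_loops")
})

test_that("the emulated tables follow the schedule exactly", {
  tabs <- generateStudy(seed = 4)
  expect_equal(nrow(tabs$lactate), 167L)
  expect_equal(nrow(tabs$lspu), 4L * 18L * 4L)
  expect_true(all(tabs$lspu$lspu >= 0))
  expect_true(all(tabs$lactate$lactate >= 0))
  ## one loop missing at T120: the last loop
  t120 <- tabs$lactate[tabs$lactate$timepoint == "T120", ]
  expect_equal(sort(unique(t120$loop)), 1:17)
  ## T0 watershed/ischemic lactate restricted to loops 1-3
  t0 <- tabs$lactate[tabs$lactate$timepoint == "T0", ]
  expect_equal(sort(unique(t0$loop[t0$zone != "well"])), 1:3)
  expect_equal(sort(unique(t0$loop[t0$zone == "well"])), 1:18)
})

test_that("the emulator is deterministic given the seed", {
  a <- generateStudy(seed = 10)
  b <- generateStudy(seed = 10)
  c <- generateStudy(seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$lspu$lspu, c$lspu$lspu))
})

test_that("amplified cells recover the configured moments", {
  coh <- amplifiedCohort(nPerCell = 1500, seed = 21)
  isch60 <- coh$lspu$value[coh$lspu$zone == "ischemic" &
                             coh$lspu$timepoint == "T60"]
  expect_length(isch60, 1500)
  se <- 12.6 / sqrt(1500)
  expect_lt(abs(mean(isch60) - 52.2), 3 * se)
  expect_lt(abs(sd(isch60) - 12.6), 3 * se)
  well0 <- coh$lactate$value[coh$lactate$zone == "well" &
                               coh$lactate$timepoint == "T0"]
  expect_lt(abs(mean(well0) - 2.2), 3 * 0.6 / sqrt(1500) + 0.02)
})

test_that("linked mode ties lactate to perfusion through the log link", {
  tabs <- generateStudy(seed = 2, linkMode = "linked", linkNoiseSD = 0)
  pred <- tabs$link$b0 + tabs$link$b1 * log(tabs$lactate$lspu)
  expect_equal(tabs$lactate$lactate, pmax(pred, 0.1), tolerance = 1e-12)
  ## anchors reproduce the configured cell means
  expect_equal(tabs$link$b0 + tabs$link$b1 * log(94.7), 2.2,
               tolerance = 1e-9)
  expect_equal(tabs$link$b0 + tabs$link$b1 * log(52.2), 10.3,
               tolerance = 1e-9)
})

test_that("fit quality degrades monotonically with link noise", {
  r2 <- vapply(c(2, 3.8, 6), function(sdv) {
    tabs <- generateStudy(seed = 42, linkMode = "linked",
                          linkNoiseSD = sdv)
    logCurveFit(tabs$lactate$lspu, tabs$lactate$lactate)@rSquared
  }, numeric(1))
  expect_true(all(diff(r2) < 0))
})

test_that("non-printed distribution cells are flagged", {
  d <- zoneDistributions()
  ws0 <- d[d$zone == "watershed" & d$timepoint == "T0", ]
  expect_true(ws0$lactate_non_paper)
  expect_false(ws0$lspu_non_paper)
  expect_true(d$lspu_non_paper[d$zone == "watershed" &
                                 d$timepoint == "T60"])
  expect_true(all(stats::na.omit(d$lspu_sd) > 0))
})
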