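test_that("identical seeds give bit-identical stacks", {
  ph <- uniformPhantom(48, 5)
  a <- generateSpeckleStack(ph, nFrames = 3, seed = 7)
  b <- generateSpeckleStack(ph, nFrames = 3, seed = 7)
  c <- generateSpeckleStack(ph, nFrames = 3, seed = 8)
  expect_identical(frames(a), frames(b))
  expect_false(identical(frames(a), frames(c)))
})

test_that("static fully developed speckle has unit contrast", {
  st <- generateSpeckleStack(uniformPhantom(128, 0), nFrames = 1,
                             seed = 2)
  expect_equal(measuredContrast(st), 1, tolerance = 0.10)
})

test_that("integrated speckle contrast follows the closed form", {
  for (x in c(0.5, 5, 20)) {
    st <- generateSpeckleStack(uniformPhantom(128, x), nFrames = 1,
                               seed = 11)
    expect_equal(measuredContrast(st), expectedContrast(x),
                 tolerance = 0.10, label = sprintf("K at T/tau = %g", x))
  }
})

test_that("frame mean intensity tracks the configured level", {
  for (x in c(0, 1, 20)) {
    st <- generateSpeckleStack(uniformPhantom(96, x), nFrames = 2,
                               seed = 5)
    for (f in 1:2)
      expect_equal(mean(frames(st)[, , f]), 100, tolerance = 0.05)
  }
})

test_that("coherence factor scales measured contrast by sqrt(beta)", {
  cfg <- simulationConfig(beta = 0.25)
  st <- generateSpeckleStack(uniformPhantom(128, 0), nFrames = 1,
                             seed = 3, config = cfg)
  expect_equal(measuredContrast(st), 0.5, tolerance = 0.10)
})

test_that("stack geometry and metadata are consistent", {
  ph <- makeLoopPhantom(120, 320, zoneTargets = c(well = 20,
                                                  ischemic = 5),
                        bandHeight = 60)
  st <- generateSpeckleStack(ph, nFrames = 2, seed = 1)
  expect_equal(dim(frames(st)), c(120, 320, 2))
  expect_equal(exposure(st), 5)
  expect_equal(nFrames(st), 2L)
  expect_true(all(frames(st) >= 0) &&
                all(frames(st) <= 2^16 - 1))
})

test_that("invalid configurations are rejected", {
  ph <- uniformPhantom(48, 1)
  expect_error(generateSpeckleStack(ph, nFrames = 2, seed = 1,
                                    exposure = 0), "exposure")
  expect_error(generateSpeckleStack(ph, nFrames = 0, seed = 1),
               "nFrames")
  expect_error(generateSpeckleStack(ph, nFrames = 1), "seed")
  expect_error(simulationConfig(subSteps = 0), "subSteps")
  expect_error(simulationConfig(beta = 1.5), "beta")
  expect_error(simulationConfig(staticFraction = 1), "staticFraction")
})
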