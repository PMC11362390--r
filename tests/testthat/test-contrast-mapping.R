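test_that("a constant frame has zero contrast and a masked border", {
  km <- contrastMap(matrix(50, 20, 20), 7)
  k <- kValues(km); v <- validMask(km)
  expect_true(all(k[v] == 0))
  expect_false(any(v[1:3, ]))
  expect_false(any(v[, 1:3]))
  expect_false(any(v[18:20, ]))
  expect_true(all(v[4:17, 4:17]))
})

test_that("7x7 checkerboard reproduces the hand-computed K", {
  f <- matrix(0, 7, 7)
  f[(row(f) + col(f)) %% 2 == 1] <- 2   # 25 zeros, 24 twos
  expect_equal(sum(f == 0), 25)
  km <- contrastMap(f, 7)
  expect_equal(sum(validMask(km)), 1L)
  mu <- 48 / 49
  sdev <- sqrt(mean((f - mu)^2))
  expect_equal(kValues(km)[4, 4], sdev / mu, tolerance = 1e-12)
  expect_equal(kValues(km)[4, 4], 1.0206, tolerance = 1e-4)
})

test_that("contrast is invariant to intensity gain", {
  set.seed(41)
  f <- matrix(runif(900, 1, 200), 30, 30)
  k1 <- kValues(contrastMap(f, 5))
  k2 <- kValues(contrastMap(f * 3.7, 5))
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("sliding-window contrast matches the naive double loop", {
  set.seed(99)
  for (w in c(3L, 5L, 7L)) {
    f <- matrix(runif(32 * 32, 0, 100), 32, 32)
    fast <- kValues(contrastMap(f, w))
    slow <- naiveContrastMap(f, w)
    expect_lt(max(abs(fast - slow), na.rm = TRUE), 1e-10)
    expect_identical(is.na(fast), is.na(slow))
  }
})

test_that("zero-mean windows are marked invalid", {
  f <- matrix(1, 12, 12)
  f[1:9, 1:9] <- 0
  km <- contrastMap(f, 3)
  expect_false(validMask(km)[3, 3])   # window all zeros
  expect_true(validMask(km)[10, 10])
})

test_that("bad window specifications are rejected", {
  f <- matrix(1, 10, 10)
  expect_error(contrastMap(f, 4), "odd")
  expect_error(contrastMap(f, 11), "larger")
  expect_error(contrastMap(matrix(c(1, NA, 1, 1), 2, 2), 3))
})

test_that("inverse-square mapping follows 1/K^2 with a cap", {
  k <- matrix(c(0.1, 0, 0.05, 0.5), 2, 2)
  km <- new("ContrastMap", k = k,
            validMask = matrix(TRUE, 2, 2), window = 3L)
  pm <- lspuMap(km, cap = 200)
  expect_equal(lspuValues(pm)[1, 1], 100)   # 1 / 0.01
  expect_equal(lspuValues(pm)[2, 1], 200)   # K = 0 -> cap
  expect_equal(lspuValues(pm)[1, 2], 200)   # 1/0.0025 = 400, capped
  expect_equal(lspuValues(pm)[2, 2], 4)
  expect_error(lspuMap(km, cap = 0), "cap")
})

test_that("perfusion is monotone non-increasing in contrast", {
  set.seed(5)
  k <- matrix(sort(runif(64, 0, 1)), 8, 8)
  km <- new("ContrastMap", k = k, validMask = matrix(TRUE, 8, 8),
            window = 3L)
  v <- lspuValues(lspuMap(km, cap = 500))
  expect_true(all(diff(as.vector(v)) <= 1e-9))
  ## raw mode passes K through
  expect_equal(lspuValues(lspuMap(km, form = "raw_contrast")), k)
})

test_that("mean perfusion map averages pixel-wise with mask conjunction", {
  mk <- function(val, maskOff = NULL) {
    m <- matrix(val, 6, 6); msk <- matrix(TRUE, 6, 6)
    if (!is.null(maskOff)) { msk[maskOff] <- FALSE; m[maskOff] <- NA }
    new("PerfusionMap", lspu = m, validMask = msk,
        mapping = list(form = "inverse_square", cap = 200))
  }
  one <- meanPerfusionMap(list(mk(40)))
  expect_equal(lspuValues(one), matrix(40, 6, 6))
  two <- meanPerfusionMap(list(mk(40), mk(60, maskOff = 1)))
  expect_equal(lspuValues(two)[2, 1], 50)
  expect_false(validMask(two)[1, 1])
  many <- meanPerfusionMap(rep(list(mk(70)), 96))
  expect_equal(lspuValues(many), matrix(70, 6, 6))
  expect_error(meanPerfusionMap(list()), "non-empty")
  bad <- new("PerfusionMap", lspu = matrix(1, 3, 3),
             validMask = matrix(TRUE, 3, 3),
             mapping = list(form = "inverse_square", cap = 200))
  expect_error(meanPerfusionMap(list(mk(40), bad)), "dimensions")
})
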